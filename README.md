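# mutland

Alignment-based mutational landscapes for proteins.

`mutland` predicts the functional effect of every possible single
amino-acid substitution in a protein from a single multiple sequence
alignment (MSA) of its homologs — no structure, no supervised training,
no external databases. Substitutions the family has tolerated over
evolutionary time are scored as benign; substitutions never observed at
constrained sites are scored as deleterious. Predictions are an L × 20
matrix (the *mutational landscape*) that can be evaluated directly
against deep mutational scanning (DMS) experiments.

## The model

Three quantities, all computed from the same alignment, are combined:

1. **Depth.** Each sequence *s* is weighted by
   π<sub>s</sub> = 1 / #{t : D<sub>H</sub>(s,t) < θ<sub>ID</sub>} with
   D<sub>H</sub> the normalized Hamming distance, and
   N<sub>eff</sub> = Σ π<sub>s</sub> is the effective number of
   sequences (θ<sub>ID</sub> = 0.2, or 0.01 for viral families). The
   ratio N<sub>eff</sub>/L<sub>cov</sub>, with L<sub>cov</sub> the
   number of columns under 30% gaps, classifies the alignment as
   low (< 1), medium, or high (> 100) depth.

2. **Conservation.** Sequences are clustered by UPGMA on Hamming
   distances. A position's conservation c<sub>i</sub> is primarily the
   normalized tree height of the deepest partition at which at least
   two sizable subtrees are each homogeneous for that position — sites
   that segregate along ancient splits are conserved within clades even
   when variable overall — refined by a subordinate composition term
   that grades the positions the scan cannot separate.

3. **Evolutionary distances.** δ(i, b) is the minimal
   conservation-weighted Hamming distance from the query to any
   sequence displaying residue *b* at position *i*; unobserved
   substitutions fall back to their reduced-alphabet class (11
   physicochemical groups) plus a penalty.

The landscape is S(i, b) = −c<sub>i</sub> · δ<sup>raw</sup>(i, b),
rescaled so the minimum is exactly −1 and wild-type cells are exactly
0. Multi-substitution variants (`"A12G:H33Y"`) are scored additively.
Evaluation uses tie-aware Spearman ρ against DMS tables, with region
restriction, two-stage aggregation (experiments within target, then
targets within group), paired protocol differences Δρ̄, and a
redundancy filter with the short-alignment/long-sequence exemption.

A sequence-evolution simulator with known per-site constraint κ
(pure-birth tree, per-site substitution rejection) provides ground
truth for end-to-end validation, including matched synthetic DMS
tables.

The full method, every default parameter and its rationale, and known
limitations are documented in the vignette:
`vignettes/mutational-landscapes.Rmd`.

## Worked example

```r
library(mutland)

spec <- synthetic_spec(n_sequences = 200, length = 50, seed = 1)
sim <- simulate_msa(spec)            # alignment + true constraint sim$kappa

depth_report(sim$alignment)
#> DepthReport: Neff = 153.00 over N = 201 sequences (theta_id = 0.2)
#>   L = 50, Lcov = 50, Neff/L = 3.060, Neff/Lcov = 3.060
#>   depth class: medium (by Neff/Lcov)

cons <- conservation_profile(sim$alignment)
cons
#> ConservationProfile: 50 positions, mean level 0.316 (min 0.045, max 1.000)

scape <- single_landscape(sim$alignment, cons = cons)
scape
#> Landscape: 50 positions x 20 residues (min -1.000)
round(scape$scores[1:4, 1:8], 3)
#>         A      C      D      E      F      G      H      I
#> 1G -0.034 -0.040 -0.031 -0.037 -0.025  0.000 -0.033 -0.022
#> 2I -0.030 -0.041 -0.027 -0.030 -0.050 -0.048 -0.043  0.000
#> 3N -0.083 -0.103 -0.089 -0.106 -0.106 -0.121 -0.117 -0.099
#> 4G -0.553 -0.526 -0.441 -0.751 -0.769  0.000 -0.566 -0.966

dms <- simulate_dms(sim, spec, n_variants = 300)
evaluate_landscape(scape, dms)
#> EvaluationResult [synthetic_dms]: rho = 0.837 over 300 variants (0 excluded)
```

Or end to end from files (FASTA/A3M/Stockholm alignment, CSV DMS
table), writing all artifacts — landscape TSV/CSV, conservation
profile, depth report, evaluation, resolved config — to a run
directory:

```r
report <- run_pipeline(run_config(msa = "family.a3m", dms = "scan.csv",
                                  out_dir = "run"))
```

A command-line entry point with subcommands (`preprocess`, `depth`,
`conserve`, `predict`, `evaluate`, `simulate`, `run`) is installed at
`inst/scripts/mutland`.

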