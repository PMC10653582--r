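---
title: "Methods: alignment-based mutational landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-based mutational landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mutland` predicts the effect of every possible single amino-acid
substitution in a protein from one input: a multiple sequence alignment
(MSA) of its homologs. The premise is classical molecular evolution —
substitutions that the family has tolerated over evolutionary time are
likely benign, substitutions never observed at strongly constrained
sites are likely deleterious — made quantitative through three
ingredients computed from the same alignment: per-position conservation
levels measured against a sequence tree, conservation-weighted
evolutionary distances to witness sequences, and reduced-alphabet
residue frequencies. No structure, no supervised training, no external
databases.

This vignette documents the model, every default parameter and the
reason for its value, the synthetic-data generator used for validation,
and the package's known limitations.

## 1. Input model and preprocessing

An `Alignment` is an N × L character matrix over the 20 canonical
amino acids and the gap symbol `-`, whose first row is the *query* — the
protein whose landscape is predicted. Readers are provided for FASTA,
A3M (lowercase letters mark insertions relative to the query and are
removed), and Stockholm (`.` is normalized to `-`). Columns where the
query has a gap are removed at read time, so position *i* of the
alignment is position *i* of the query throughout.

`preprocess_undefined()` resolves the ambiguity codes X, U, B and Z
before any computation:

* an undefined residue is replaced by the most frequent canonical
  residue in its column (alphabetical tie-break, so the operation is
  deterministic);
* a column whose query residue is undefined and whose other rows are all
  gaps carries no information and is removed;
* the operation is idempotent.

`check_query_length()` implements a hard policy gate: queries of 20
residues or fewer are skipped rather than scored. Landscapes on such
fragments are dominated by edge effects and a tree on near-trivial
sequences is not meaningful. The pipeline additionally attaches an
advisory when the MSA holds fewer than 200 sequences, because such
alignments typically bypass the search-stage redundancy filtering that
deeper alignments undergo, and depth statistics must then be read with
care.

## 2. Alignment depth

Redundancy makes raw sequence counts meaningless, so depth is measured
as the *effective* number of sequences. With DH the normalized Hamming
distance (gap-versus-residue counts as mismatch, gap-versus-gap as
match), each sequence *s* receives weight

$$\pi_s = \frac{1}{\#\{t : D_H(s,t) < \theta_{ID}\}}, \qquad
N_{\mathrm{eff}} = \sum_s \pi_s .$$

A cluster of near-identical sequences thus contributes approximately one
effective sequence. The divergence threshold `theta_id` defaults to
**0.2** for cellular organisms and **0.01** for viral proteins: viral
families are so densely sampled at high identity that the 0.2 radius
would collapse genuinely distinct variants into single clusters.

Depth is normalized by length before interpretation. Besides L itself,
the package computes the *covered* length `Lcov` — the number of columns
with strictly less than 30% gaps — because heavily gapped columns
contribute no usable signal. The ratio Neff/Lcov classifies the
alignment: **low** when the ratio is below 1, **high** when above 100,
**medium** otherwise (boundary values are medium; the inequalities are
strict). Both Neff/L and Neff/Lcov are reported, and `classify_depth()`
can use either.

## 3. Conservation along the sequence tree

Column-wise conservation scores ignore phylogeny: a site that is
perfectly conserved within each of two ancient clades but differs
between them is strongly constrained, yet looks variable when the column
is read as a bag of letters. `mutland` therefore measures conservation
against a tree.

`build_tree()` clusters the sequences by UPGMA (average-linkage
`stats::hclust`) on the pairwise normalized Hamming matrix. Average
linkage is the default because it resists the chaining that
near-duplicate-heavy alignments induce under single linkage. Leaves are
first put into a canonical order (lexicographic by sequence string, then
by identifier) so that the tree — and everything derived from it — is
invariant to the row order of the input even when pairwise distances
tie. Under tied distances the UPGMA tree itself is not unique, so this
canonicalization is what makes profiles reproducible.

The primary per-position signal is the *homogeneous-subtree scan*.
Walking the merge list from the root downwards enumerates partitions of
the sequences into subtrees, each labelled by the height of the merge
just above it. A subtree is *homogeneous* at position *i* when all its
non-gap symbols there are identical (and at least one is non-gap). The
scan value is

$$s_i = h^*_i / h_{\mathrm{root}},$$

where $h^*_i$ is the greatest partition height at which **at least two**
subtrees of size ≥ `m_min` are homogeneous at *i*; 0 when no partition
qualifies; 1 for fully conserved columns. The minimum subtree size
`m_min = max(2, ceil(0.05 N))` excludes small clades, which carry too
little evidence of ancient segregation.

The scan is deliberately conservative, and on families of moderate
depth it is *coarse*: many positions never produce two large homogeneous
subtrees and all collapse to exactly 0, which destroys the ranking the
predictor needs. A subordinate composition term grades those ties:

$$c_i = s_i + (1 - s_i)\, w_c \cdot m_i,$$

where $m_i$ is the modal non-gap residue fraction of column *i* and
`comp_weight` $w_c$ defaults to **0.5**. The value 0.5 is chosen so that
a fully monomorphic column can never reach more than half the scale on
composition alone — tree evidence always dominates — and
`comp_weight = 0` recovers the pure scan exactly. The blend is strictly
monotone in the scan value, keeps levels in [0, 1], leaves fully
conserved columns at exactly 1, and leaves columns with no residues
outside the query at 0.

One caveat is documented rather than hidden: because levels are
normalized by the root height, inserting exact duplicates of the query
shifts merge heights slightly and can *decrease* individual levels by
order 0.01–0.04 even though duplicates add no information. The test
suite asserts monotonicity up to this renormalization tolerance.

## 4. The landscape

For position *i* and residue *b*, the *evolutionary distance* δ(i, b) is
the minimal conservation-weighted Hamming distance between the query and
any alignment row displaying *b* at *i*:

$$\delta(i,b) = \min_{s:\, x_{si} = b} \;
\frac{\sum_j c_j \,[\,x_{sj} \ne q_j\,]}{\sum_j c_j}.$$

A substitution witnessed by a close homolog is cheap; one witnessed only
by remote homologs is expensive. If the conservation profile is
identically zero the weights are undefined and the package falls back to
uniform weights. When *b* is never observed at *i*, the cost falls back
to the cheapest observed member of *b*'s reduced-alphabet class plus a
penalty `kappa · δ_max`, or to `δ_max + kappa · δ_max` when no class
member is observed either. Here δ_max is the worst observed raw
distance; in the degenerate case where no substitution is observed at
all (e.g. an alignment of query duplicates) δ_max is set to 1, the
maximum possible normalized Hamming distance, so that every non-wild-type
cell shares the single worst score instead of collapsing to 0. The
wild-type residue never counts as class evidence — it witnesses itself
trivially (δ = 0 by definition) and says nothing about tolerance to
substitution. The penalty fraction `kappa` defaults to **0.2**: large
enough that unobserved substitutions are never ranked better than their
observed class relatives, small enough not to swamp the class signal.

Frequencies are computed over a reduced alphabet because 20-letter
frequencies are hopelessly sparse in one column of a modest alignment.
The default groups the amino acids into 11 physicochemical classes —
{A,S,T}, {I,L,V}, {M}, {F,W,Y}, {K,R}, {D,E}, {N,Q}, {G}, {P}, {C},
{H} — and is a configuration knob. Counts are sequence-weighted and
smoothed with a pseudocount `lambda = 1` (Laplace). The optional blend
weight `alpha` mixes `1 − f_class(i, class(b))` into the raw cost;
`alpha = 0` is the default, i.e. the landscape is distance-driven and
frequencies are reported alongside.

Scores are conservation-gated and normalized:

$$S(i,b) = -\,c_i\,\delta^{\mathrm{raw}}(i,b)
  \;\Big/\; \max_{j,a} c_j\,\delta^{\mathrm{raw}}(j,a),$$

so the landscape minimum is exactly −1, wild-type cells are exactly 0,
and more negative means more deleterious. Gating makes equal raw costs
hurt more at conserved sites, which is what lets scores be compared
across positions. Multi-substitution variants (ProteinGym-style
`"A12G:H33Y"` strings parsed by `parse_mutant()`) are scored additively
by `combined_score()`.

## 5. Evaluation against deep mutational scans

`evaluate_landscape()` correlates predicted scores with a DMS table
using Spearman's ρ with average ranks for ties (`spearman_rho()`; a
constant vector is an error, not an NA). Evaluation can be restricted to
a position region, in which case the number of excluded variants is
reported. `aggregate_results()` averages in two stages — experiments
within a target protein first, then targets within a group — so that
heavily scanned proteins do not dominate, and computes paired
score-differences Δρ̄ between two protocols evaluated on the same
experiments. `redundancy_filter()` drops one member of every pair above
an identity threshold, *except* pairs whose alignment spans fewer than
50 residues while both sequences have at least 180 residues — local
similarity between long proteins is not global redundancy.

## 6. The synthetic generator

Validation needs data where the truth is known, so the package ships a
generator with a *known per-site constraint*. `simulate_msa()` draws a
pure-birth tree (`ape::rphylo`), places the query at the root, and
evolves sequences along branches: each site proposes
Poisson(branch length × `branch_scale`) substitutions and each proposal
is *rejected* with probability κ_i, the site's constraint. κ_i = 1 is an
invariant site; κ_i = 0 evolves freely. A matched DMS table
(`simulate_dms()`) measures `−κ_i · effect_size` plus Gaussian noise
(`dms_noise_sd`, default 0.1), so a perfect predictor achieves ρ = 1 on
noise-free tables and the attenuation under noise can be predicted
independently. `depth_regimes()` provides three presets whose
simulated alignments realize the low / medium / high depth classes.

The generator is intentionally minimal: sites are independent (no
epistasis, no covariation), there are no indels, no alignment errors, no
rate heterogeneity beyond κ, and amino-acid exchange is uniform over the
19 alternatives rather than matrix-weighted. It validates the machinery
— recovery of the constraint gradient, depth bookkeeping, determinism —
and does not claim to emulate real protein families. Problem sizes used
in tests (N up to ~1500, L up to ~80) are the package's own choices,
selected to run in seconds while leaving each depth regime clearly
realized.

All simulation is seeded through the spec object and runs in a private
RNG scope (`with_seed`), so the caller's random stream is untouched and
a fixed seed yields byte-identical FASTA and landscape files.

## 7. Worked example

```{r, eval = FALSE}
library(mutland)

spec <- synthetic_spec(n_sequences = 200, length = 50, seed = 1)
sim <- simulate_msa(spec)

depth_report(sim$alignment)
cons <- conservation_profile(sim$alignment)
scape <- single_landscape(sim$alignment, cons = cons)

dms <- simulate_dms(sim, spec, n_variants = 300)
evaluate_landscape(scape, dms)
```

Or end to end from files, with every artifact written to a run
directory:

```{r, eval = FALSE}
cfg <- run_config(msa = "family.a3m", dms = "scan.csv", out_dir = "run")
report <- run_pipeline(cfg)
```

## 8. Limitations

* Conservation depends on UPGMA heights; the duplicate-query
  renormalization caveat of §3 applies.
* The predictor is single-MSA and unsupervised; it does not use
  structure, coevolution couplings, or fitted substitution matrices, and
  additive multi-substitution scores ignore epistasis.
* Depth classes are heuristics over Neff ratios, not calibrated error
  bars.
* The synthetic generator validates correctness, not biological realism
  (see §6).
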