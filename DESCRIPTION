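Package: mutland
Title: Alignment-Based Mutational Landscapes for Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts full single-site mutational landscapes of proteins
    from a single multiple sequence alignment. Computes per-sequence
    weights and the effective number of sequences (Neff), classifies
    alignment depth, derives per-position evolutionary conservation
    levels from segregation of sites along a sequence tree, combines
    conservation, reduced-alphabet frequencies and conservation-weighted
    evolutionary distances into an L x 20 substitution-effect matrix,
    and evaluates predictions against deep mutational scanning tables
    with Spearman rank correlation, common-position restriction and
    per-class aggregation. Includes a sequence-evolution simulator with
    known per-site constraint for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
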