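Package: cdr3delta
Title: CDR3delta Repertoire Deconstruction for Gamma-Delta T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotation, summarisation and comparison of T-cell receptor
    delta-chain (TRD) CDR3 repertoires from AIRR Rearrangement tables.
    Provides a packaged human TRD junction-proximal germline reference,
    V(D)J junction decomposition with N-insertion counting, annotation of
    the phosphoantigen-sensing determinants of the gamma9delta2 TCR (TRDJ1
    usage, the invariant-T nucleotide, hydrophobicity at CDR3 position 5),
    clonal expansion classes, clonotype publicity and convergent
    recombination statistics, diversity and evenness metrics (Shannon
    entropy, richness, D75), rank-based group comparisons, and a
    deterministic multi-donor V(D)J repertoire simulator with ground truth
    for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
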