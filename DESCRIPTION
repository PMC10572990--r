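Package: lfqmarkers
Title: Label-Free Proteomics Marker Discovery via Hi3 Quantification,
    Filter Cascades and Interactome Subnetworks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for label-free quantitative proteomics of
    multi-group, two-sex designs. Computes Hi3 (Top3) protein abundances
    from peptide intensities, aggregates technical replicates to
    biological pools, applies a presence/CV/fold-change/ANOVA
    differential-expression filter cascade to pairwise group comparisons,
    identifies exclusive comorbidity markers by Venn set algebra over a
    comparison lattice, summarizes marker sets by pathway frequency
    against offline annotations, and decomposes confidence-thresholded
    protein-protein interaction graphs into functional subnetworks with
    centrality rankings. A synthetic-data generator with planted effects
    and intensity-dependent missingness makes the whole chain testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
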