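Package: mixewas
Title: Reference-Free Cell-Mixture-Adjusted Epigenome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies (EWAS) of DNA
    methylation array data in heterogeneous tissues. Implements reference-free
    cell-mixture deconvolution by convex non-negative matrix factorization with
    bootstrap selection of the number of putative cell types, per-CpG moderated
    linear models of M values with and without cell-proportion adjustment and a
    delta-coefficient confounding diagnostic, permutation min-P tests of
    mixture-covariate association robust to the number of components,
    direction-stratified genomic region-set enrichment with matched-background
    resampling, and coefficient-table epigenetic clocks with age-acceleration
    analysis. A synthetic-cohort generator with full ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
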