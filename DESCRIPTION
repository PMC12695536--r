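Package: pitdeconv
Title: Cell-Type Deconvolution and Contamination Detection for Pituitary Tumor Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cellular composition of pituitary neuroendocrine tumor
    (PitNET) bulk RNA-seq samples against a single-nucleus reference. Builds
    marker-gene signature matrices (GES) from an annotated single-cell count
    matrix, provides two deconvolution engines (linear nu-support-vector
    regression against a signature, and cross-subject-variance-weighted
    non-negative least squares against multi-subject profiles), benchmarks
    them on pseudobulk mixtures with known ground truth, and quantifies
    residual normal pituitary tissue per bulk sample with clustering-based
    flagging of contaminated samples. Includes a seeded synthetic-data module
    emulating a normal-pituitary single-nucleus atlas and bulk tumor cohorts
    so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    Seurat,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
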