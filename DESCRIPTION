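Package: atacage
Title: Chromatin Accessibility Aging Clocks for Bulk ATAC-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to build and characterize epigenetic aging clocks from bulk
    ATAC-seq profiles of blood samples. Covers consensus open-chromatin-region
    (OCR) construction from per-sample peak calls, Tn5 cut-site counting and
    reads-in-peaks normalization, sample quality control with robust-PCA
    outlier removal, genome-wide age-association statistics with cross-modality
    integration (accessibility, expression, CpG methylation), preranked gene
    set enrichment, elastic-net age prediction with age-balanced nested
    cross-validation, cell-composition and sex correction, age-adjusted
    condition-effect testing, and a synthetic cohort generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
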