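Package: msewas
Title: Differential DNA Methylation Analysis of Multiple Sclerosis Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A pipeline for epigenome-wide association analysis of
    longitudinal multiple sclerosis (MS) severity from whole-blood DNA
    methylation arrays. Implements age-related MS severity (ARMSS)
    phenotyping from visit-level EDSS histories, EPIC-style probe and
    sample quality filtering, beta-mixture quantile (BMIQ) normalization,
    SVD batch-effect detection with empirical-Bayes correction,
    differential methylation at position, region and cell-type level,
    targeted methylation quantitative trait locus (mQTL) analysis,
    methylation-age acceleration, and three severity classification
    models (clinical elastic net, genome-wide methylation elastic net,
    and a weighted methylation risk score). A synthetic-cohort generator
    with machine-readable ground truth supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pracma,
    pROC,
    stats,
    sva,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR
VignetteBuilder: knitr
Config/testthat/edition: 3
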