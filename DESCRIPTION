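Package: ihcquant
Title: Quantification of DAB Immunohistochemistry and Antitumor Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible quantitative layer for antitumor-peptide studies that
    score DAB (3,3'-diaminobenzidine) immunostained tumor sections and the
    accompanying cell-based assays. Implements a brightfield stained-area
    segmentation pipeline (flat-field illumination correction, hue-sector
    suppression of non-specific signal, adaptive red-blue stain contrast,
    difference-of-Gaussians band-pass background removal, isodata automatic
    thresholding, and color-based artifact rejection), four-parameter logistic
    dose-response fitting with GI50 inversion, LDH-release percent cytotoxicity,
    caliper-based tumor volume and growth-inhibition summaries, and unpaired
    two-tailed t-tests with the conventional significance stars. A synthetic-data
    module generates ground-truthed immunohistochemistry fields and tabular assay
    datasets with known effect sizes so every analysis can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
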