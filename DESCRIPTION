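Package: graftsize
Title: Hamstring Graft Size Prediction and Agreement Analysis for ACL Reconstruction Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the diameter of a doubled semitendinosus-gracilis (four-strand)
    hamstring autograft for anterior cruciate ligament reconstruction from tendon
    cross-sectional diameters measured on routine knee MRI, and validates the
    prediction rule statistically. Implements the predicted graft diameter (PGD)
    rule (sum of per-tendon mean diameters, rounded up to the next full
    millimetre), predicted-versus-actual agreement with exact Clopper-Pearson
    confidence intervals and linearly weighted Cohen's kappa, Bland-Altman
    intra- and inter-reader reproducibility (bias and coefficient of
    repeatability), median/IQR summaries with the Wilcoxon signed-rank test,
    a seeded synthetic cohort generator emulating the measurement process
    (0.1-mm quantization, reader noise, two readers by two sessions), and a
    report pipeline producing JSON and markdown study summaries from cohort CSV
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
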