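Package: odiscreen
Title: Oxygen Desaturation Indices from Overnight Oximetry for Sleep Apnea Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to validate overnight pulse-oximetry screening of obstructive
    sleep apnea against polysomnography-derived reference standards. Simulates
    1-Hz SpO2 recordings with a prescribed apnea-hypopnea burden and realistic
    oximeter behaviour (beat-averaged response, measurement noise, spike and
    dropout artifacts), applies the standard automated artifact-elimination
    rules, computes the four oxyhemoglobin desaturation indices ODI2, ODI3,
    ODI4T and ODI4A with moving top-20 percent and all-night baselines, and
    evaluates cutoff-based and support-vector-machine diagnosis of severe
    (AHI >= 30) and moderate-to-severe (AHI >= 15) disease with confusion
    matrices, ROC/AUC, Bland-Altman agreement, chi-square tests, and one-way
    ANOVA with Scheffe post-hoc comparisons reconstructed from group summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
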