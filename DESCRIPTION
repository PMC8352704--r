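Package: copdfusion
Title: Multimodal CNN Fusion for COPD Image Recognition and Airway Quantification
Version: 0.1.0
Authors@R: person("copdfusion", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: From-scratch LeNet-5-style convolutional networks for paired
    CT / chest X-ray COPD classification, a seeded randomized-fusion operator
    that combines the two modalities' fully-connected features under a
    transferred-parameter classification head, recognition/sensitivity/
    specificity evaluation, iteration and batch-size sweep experiments, and
    phantom-validated airway lumen-area (LA) and wall-area-percentage (WA%)
    quantification. All stages run on seeded synthetic data generated by the
    package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
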