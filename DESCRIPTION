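Package: anchornorm
Title: Anchor-Based Batch Adjustment for Mass Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Batch-effect adjustment for multi-batch mass cytometry (CyTOF)
    experiments using technical-replicate anchor samples. Each barcode set
    (batch) carries an aliquot of one reference donor sample; per-channel
    scale factors (mean, median, standard deviation, or a user percentile)
    or quantile maps are calibrated on each batch anchor against a
    designated reference anchor and applied to every sample in the batch,
    in raw ion-count or arcsinh-transformed space. Includes FCS 3.1 file
    reading and writing, rolling per-batch processing with logs and
    graphical diagnostics, validation statistics (mean pairwise
    Kolmogorov-Smirnov replicate consistency, total variance of replicate
    feature matrices, and an exact pre/post permutation test), and a
    synthetic multi-batch generator with known injected batch effects for
    ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
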