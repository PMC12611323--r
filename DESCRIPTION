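Package: delphiclock
Title: Epigenetic Clock Construction and Evaluation for Common Dolphins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates DNA-methylation age clocks for the common
    dolphin (Delphinus delphis) from beta-value matrices and sample metadata.
    Implements sample quality control (detection p-value probe failure,
    failed-probe-fraction outliers, principal-component distance outliers), a
    log-linear age transformation anchored on age at sexual maturity and
    gestation length, elastic-net clock fitting with leave-one-out
    cross-validation, a hybrid age model that gates an all-samples clock and
    a mature-only clock by a random-forest maturity probability,
    methylation-based sex classification, subset construction, an
    error-metric suite, and decomposition/storage covariate tests. A
    synthetic-data generator reproduces the statistical structure the
    analysis assumes so the full pipeline is testable without tissue-archive
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
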