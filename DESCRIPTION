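Package: equiclock
Title: Equid Epigenetic Clocks and Methylation Association Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds elastic-net epigenetic aging clocks for horses and other
    equid species from CpG methylation beta values, with species-aware age
    transformations (relative age and a log-linear maturity-anchored
    transform), leave-one-sample-out, ten-fold, and leave-one-species-out
    cross-validation, epigenome-wide association screens of age with
    cross-tissue Stouffer meta-analysis, castration effect screening, and a
    cross-tissue DNA methylation to mRNA coupling analysis stratified by
    chromatin state. Includes a synthetic-data generator that emulates the
    statistical structure of multi-species blood and liver methylation
    cohorts and a two-animal multi-tissue atlas, so every stage of the
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
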