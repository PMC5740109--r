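Package: methfrail
Title: Epigenome-Wide Association and Methylation-Based Frailty Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for epigenome-wide association studies
    (EWAS) of array DNA methylation with control-probe principal-component
    adjustment, reference-based blood cell-type deconvolution, bump-hunting
    detection of differentially methylated regions with permutation FDR,
    fixed-effect inverse-variance and sample-size-weighted meta-analysis with
    heterogeneity statistics, cumulative methylation risk scores, and
    classifier-based discrimination of clinical frailty with permutation
    nulls. Ships a synthetic-cohort generator that emulates cell-type
    mixtures, batch effects carried by control probes, spiked case/control
    effects and a frailty index coupled to methylation burden, so the whole
    pipeline is testable without any external data.
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
    limma,
    pracma,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
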