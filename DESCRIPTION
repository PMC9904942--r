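Package: salmonsize
Title: Body-Size Trend Decomposition for Sockeye Salmon Returns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs complete age-length populations of returning sockeye
    salmon from age-length samples and brood tables by weighted resampling,
    computes mean size, size-at-age anomalies, mean ages, coefficients of
    variation, length-weight allometry and fishery selection differentials on
    the reconstructed populations, decomposes long-term mean-size change into
    size-at-age and age-structure contributions (including a rolling
    retrospective), and models annual size-at-age anomalies against
    competition and temperature covariates via collinearity-screened
    all-subsets AIC selection with variance partitioning. A synthetic-data
    generator with known ground truth makes the whole pipeline verifiable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr
Config/testthat/edition: 3
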