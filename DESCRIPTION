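Package: cropmapr
Title: Cross-Year Corn and Soybean Mapping from Phenology-Anchored
    Time-Series Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Rapid cross-year mapping of corn and soybean cover from
    coarse-resolution reflectance time series. Retrieves crop phenology by
    fitting an asymmetric double-sigmoid to per-pixel EVI profiles, derives
    phenological and phenology-anchored spectral features, trains fuzzy
    (sub-pixel coverage) or hard random-forest classifiers on a prior year
    chosen by crop-progress similarity (root-mean-square deviation of 50%
    progress dates), optionally applies linear or mean-shift phenological
    adjustment between years, and validates predicted coverage against
    reference labels at county level. Includes a synthetic-data generator
    emulating the statistical structure of the reflectance, crop-label and
    crop-progress inputs so the full workflow runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
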