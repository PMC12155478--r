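Package: aromarker
Title: Volatile Metabolomics and Odor-Activity Marker Screening for Tea
    Origin Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for volatile-compound profiling of green tea
    from multiple growing regions. Parses censored GC-MS concentration
    tables, performs internal-standard semi-quantification and linear
    retention index calculation, computes odor activity values (OAV) with
    threshold-based screening, derives composition profiles and
    region-presence Venn partitions, and discriminates origins with
    autoscaled PCA, hierarchical clustering, and NIPALS PLS-DA with
    variable-importance-in-projection (VIP) scores. Aroma markers are
    selected by the joint VIP > 1 and OAV > 1 screen; grade contrasts and
    Duncan's multiple range letters summarise batch differences.
    Electronic-nose time series are reduced to stable-phase sensor
    profiles. Seeded synthetic generators emulate the full data structure
    (region and grade effects, triplicate lognormal noise,
    detection-limit censoring) so every stage is testable.
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
    utils
Suggests:
    cluster,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
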