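Package: wormstate
Title: Sleep-State Analysis for Microfluidic C. elegans Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies Caenorhabditis elegans behavioral states from video
    recordings of animals confined in microfluidic chambers. Provides
    frame-by-frame subtraction activity traces, quiescent (sleep) bout
    detection with twitch tolerance and minimum-duration filtering, worm
    centerline extraction and dimensionless body-curvature measurement,
    calcium-imaging trace processing (running-minimum dF/F and ratiometric
    dR/R), stimulus-response classification with bootstrap and permutation
    statistics, and size-gated fluorescent puncta counting. A synthetic-data
    module generates videos, activity traces, fluorescence traces and puncta
    images with known ground truth for validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
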