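Package: coralniche
Title: Seafloor Up-Scaling and Maximum-Entropy Habitat Suitability Modelling
    for Cold-Water Corals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds continuous high-resolution seafloor environmental layers by
    draping depth-binned ocean climatologies over bathymetry (inverse-distance
    interpolation, nearest-neighbour resampling, depth-interval assignment),
    derives benthic terrain variables (slope, rugosity, bathymetric position
    index), and fits presence-only maximum-entropy habitat suitability models
    with logistic output, jack-knife variable importance, presence-background
    AUC, test gain, fixed-percentile thresholding and omission rates. Includes
    bottle-station validation of up-scaled layers (correlations, binned
    profiles, coarse error grids) and a synthetic-world generator with planted
    niche truth so the whole pipeline is testable end to end.
License: MIT
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
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
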