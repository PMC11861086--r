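Package: fuzzyplan
Title: Fuzzy-Controller-Guided Inverse Planning for Intensity-Modulated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated tuning of inverse treatment-plan parameters with a
    trainable Takagi-Sugeno fuzzy controller. Provides synthetic C-shape and
    mock-prostate phantom generators, a self-contained pencil-beam dose engine
    minimizing a quadratic dose-volume objective over nonnegative fluence, a
    five-layer adaptive neuro-fuzzy network (sigmoidal memberships, eight
    rules, first-order consequents) trained by Adam on planning trajectories,
    the guided inverse-planning loop that walks multi-level dose
    prescriptions, and dose-volume histogram analytics for plan evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
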