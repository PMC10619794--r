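Package: gaitstab
Title: Foot Placement Control and Local Dynamic Stability of Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mediolateral gait stability from marker-level
    treadmill walking kinematics. Detects heelstrikes from heel and trunk marker
    trajectories, builds tidy per-step stride tables, fits the step-to-step foot
    placement control model (mediolateral foot placement regressed on
    center-of-mass position and velocity at terminal swing) per 30-stride block,
    estimates local divergence exponents of mediolateral center-of-mass velocity
    by delay embedding and nearest-neighbour divergence tracking, and computes
    step width, stride time and ground-reaction-force moment scenarios. Includes
    a synthetic treadmill-gait generator with known ground truth so every
    pipeline stage can be validated without motion-capture recordings.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
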