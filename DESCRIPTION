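Package: skimotion
Title: Data-Driven Biomechanics of Cross-Country Skiing from Full-Body Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing over-ground cross-country skiing from wearable
    full-body motion capture. Segments propulsion cycles from left-toe
    displacement, time-normalizes them to 101 samples, assembles a structured
    cycle database, decomposes it by principal component analysis with
    variance-based retention, classifies sub-techniques (double pole, kick
    double pole, diagonal stride, glides, skating) with a quadratic-kernel
    support vector machine on PC scores, relates PC scores to athlete skill
    level with one-way ANOVAs and a monotone-trend rule, and builds
    multi-component reconstructed "beginner" and "elite" movement avatars with
    derived frontal-area, ski-angle and joint-power metrics. Includes a
    synthetic skier simulator and GNSS track generator so the whole pipeline is
    testable without field recordings, plus 3D track reconstruction from GNSS
    lap data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
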