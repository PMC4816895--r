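Package: teftools
Title: Thermic Effect of Food Estimation from Whole-Room Indirect Calorimetry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the thermic effect of food (TEF) from
    minute-resolution whole-room indirect calorimetry sessions. Implements the
    fed-minus-fasted difference (delta-EE), the activity-regression intercept
    methods with resting or sleeping metabolic rate baselines, and a
    NEAT-removal method that subtracts nonexercise activity thermogenesis
    estimated from lag-optimized integrated accelerometer activity before
    accumulating the postprandial rise. Includes energy expenditure derivation
    from gas exchange and urinary nitrogen (Weir equation), a synthetic chamber
    session simulator with known latent basal/TEF/NEAT components for
    validation, Bland-Altman method agreement analysis, and a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
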