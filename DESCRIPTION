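Package: plasmaflow
Title: Capillary-Driven Cake-Filtration Modelling of Quantitative Plasma Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models passive, capillary-force-driven separation of blood plasma
    through a filtration membrane as constant-pressure cake filtration. Provides
    the closed-form filtration kinetics (volume versus time, relative-rate
    steady-state criterion, steady-state volume versus effective filtration
    area), nonlinear estimation of the two lumped model parameters (filtering
    constant k and equivalent filtrate volume Ve) from time-course or
    area-calibration data, inversion of the fitted model to design the membrane
    area that delivers a target plasma volume, image-based plasma volume
    quantification (segmented area times channel height), red-blood-cell
    residue and capture-efficiency metrics, and synthetic-data generators with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
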