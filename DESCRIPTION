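Package: cardiomech
Title: Reduced-Order Subject-Specific Cardiac Mechanics with Infarct
    Homogenization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and exercises desk-scale beating-heart models:
    orthotropic hyperelastic passive myocardium with continuous
    infarct homogenization, a time-varying elastance active
    contraction law, a thick-walled truncated-ellipsoid reduced-order
    ventricle, a closed-loop lumped-parameter circulation producing
    pressure-volume loops, diffusion-tensor fiber-architecture
    analysis (fractional anisotropy gating, invariant interpolation,
    inclination angles, AHA 17-segment profiling), continuous tissue
    health fields from binary infarct segmentations, multi-stage
    material calibration against six-mode simple-shear data and
    Klotz-type end-diastolic pressure-volume targets, and 16-segment
    endocardial strain extraction with cubic splines. Ships seeded
    synthetic-data generators for every input class so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    pracma,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
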