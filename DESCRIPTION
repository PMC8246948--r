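Package: gesturespeech
Title: Gesture-Speech Physics: Coupled Analysis of Limb Kinematics and Vocal Acoustics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how rhythmic upper-limb movement
    perturbs vocal acoustics. Extracts the smoothed Hilbert amplitude envelope
    and an autocorrelation-based fundamental frequency (F0) track from mono
    audio, detects beat events (maximum extension and the preceding
    deceleration phase) in vertical motion-capture traces, epochs the acoustic
    signals around each beat, constructs a surrogate random-pairing baseline,
    and fits the three statistical analyses of the paradigm: mixed-effects
    condition contrasts on per-trial acoustics, penalized-spline trajectory
    smooths of beat-locked acoustics, and mixed-effects regressions of
    acoustic peaks on maximum deceleration. Includes a synthetic-session
    generator that injects known biomechanical coupling so every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    mgcv,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
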