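Package: burstdrive
Title: Burst-Superimposition Assessment of Plantarflexor Central Drive
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Processing and statistical validation pipeline for burst-superimposition
    (interpolated twitch) assessment of plantarflexor central drive from isometric
    dynamometry torque traces. Provides zero-phase low-pass filtering and extraction
    of voluntary (F_vol) and stimulation-elicited (F_stim) torque, automated trial
    quality control, origin-constrained cubic calibration of device-measured central
    drive against true central drive (with leave-one-out cross-validation and
    Breusch-Pagan heteroscedasticity diagnostics), agreement statistics (ICC(2,1),
    Bland-Altman limits of agreement), cohort group comparisons (one-way ANOVA with
    eta-squared and Sidak-adjusted pairwise tests), six-minute-walk-test outcome
    metrics, and a synthetic torque-trace simulator that supplies ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    optparse,
    withr
Config/testthat/edition: 3
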