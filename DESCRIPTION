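Package: rmmod
Title: Moderation Analysis for Two-Instance Repeated Measures Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests and probes moderation of a within-participant (two-instance)
    effect by one or more between-participant moderators using difference-score
    regression. Supports additive and multiplicative multiple-moderator models,
    pick-a-point (simple slopes) probing with contrast-vector standard errors,
    and the Johnson-Neyman procedure with closed-form boundaries of
    significance. Includes a synthetic-data generator with correlated
    within-person errors for power and type-I error studies, plain-text
    reporting, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
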