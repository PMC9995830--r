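Package: woolsim
Title: Seeded Agent-Based Simulation and Evaluation of a Sheep
    Lameness-Detection Game
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless, seeded agent-based simulator of a virtual sheep
    flock used in a lameness-detection serious game, together with the
    quantitative evaluation pipeline for player scores. Sheep graze, stand
    and walk according to a semi-Markov activity budget; lameness is
    assigned at session start and expressed as gait cues during walking.
    Virtual observers scan the flock, classify walking sheep by a
    signal-detection rule and mark suspects, yielding accuracy (precision)
    and recall scores. The analysis side provides the arcsine square-root
    transform, D'Agostino's skewness test, noncentral-F power analysis
    (Cohen's f-squared), single-predictor linear models with sequential
    Bonferroni correction and a stopping rule, contingency-table tests,
    group summaries with a quartile-versus-confidence-interval quality
    flag, Likert summaries, and a synthetic participant-cohort generator
    with planted or null effects for calibration and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
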