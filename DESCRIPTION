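Package: seevfit
Title: Expectancy-Value Attention Modelling and Situation-Awareness Scoring for Eye-Tracking Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mobile eye-tracking recordings of
    procedural tasks with the SEEV (salience, effort, expectancy, value)
    model of visual attention and its expectancy-value (EV) reduction.
    Computes percentage dwell time on phase-dependent groups of areas of
    interest from fixation records, derives model-predicted dwell-time
    distributions from lowest-ordinal expert parametrizations, scores
    observed-versus-predicted model fit per participant, scores
    freeze-probe situation-awareness questionnaires, and quantifies
    fit-awareness associations. Includes a synthetic cohort generator
    (Dirichlet dwell compositions linked to questionnaire correctness)
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
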