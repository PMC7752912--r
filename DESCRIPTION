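Package: ats5c
Title: Simulation and Analysis of Automated 5-Choice Serial Reaction Time
    Task Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale engine for designing, simulating and analysing
    home-cage automated training of mice on the 5-choice serial reaction
    time task (5CSRTT). Implements the trial-level finite-state engine
    (inter-trial interval, light cue, limited hold, timeout), the 12-stage
    adaptive difficulty ladder with criterion-gated advancement, a
    voluntary-entry gate scheduler with circadian structure and training
    breaks, a parameterised stochastic virtual-mouse agent for generating
    behaviourally plausible trial logs, and the standard 5CSRTT performance
    analytics (accuracy, premature and omission rates, reaction times,
    sliding-window learning curves, circadian activity profiles). All
    results are tibbles; plotting uses ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
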