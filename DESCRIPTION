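Package: saccadepay
Title: Payoff-Time Modelling of Saccade Reaction Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models saccade reaction times (SRT) with a payoff-time
    cost/benefit heuristic: the latency benefit of foveating a target
    (gain in visual resolution over peripheral preview) is traded against
    the movement cost (saccade duration), and the resulting payoff-time
    sets the accumulation rate of a LATER-style rise-to-threshold decision
    unit. Provides eccentricity-dependent visual resolution and
    main-sequence duration functions, one- and two-parameter model
    fitting to median SRT, recinormal (reciprocal-normal) distribution
    machinery with reciprobit diagnostics, a two-accumulator race model
    of free choice between targets (mutual inhibition, directional bias,
    priority index), descriptive power-law and ROC analyses, saccade
    detection from gaze traces, and a seeded synthetic-data generator
    emulating the three experimental designs so the whole pipeline is
    testable end to end.
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
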