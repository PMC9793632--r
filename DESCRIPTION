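Package: nof1engine
Title: Design, Schedule, Simulate and Summarise Personal N-of-1 Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for user-centric N-of-1 trials (single-case
    crossover experiments). Specifies trials as a canonical JSON document with
    four components (goal, interventions, measures, schedule), generates
    balanced phase sequences for withdrawal and alternating-treatment designs,
    expands reminder policies into dated task calendars, validates and records
    typed measurements (numeric keyboard entry, categorical lists, bounded
    scales), and summarises results by day and by phase with an optional Welch
    phase contrast. A simulated-participant module produces observation and
    task logs under a stated outcome and adherence model so the full
    create-run-summarise loop is testable without human participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
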