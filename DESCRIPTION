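Package: migratiming
Title: Growth-Predation Tradeoffs and the Timing of Adfluvial Fish Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the seasonal timing of juvenile trout migration from a
    natal stream to a lake as a size-dependent tradeoff between predation
    pressure and temperature-dependent growth.  Provides the seasonal
    growth and predation submodels, a daily-resolution solver for the day
    on which the lake's predation-to-growth ratio first drops below the
    stream's (the predicted migration date), a Monte-Carlo sweep over
    predator-vulnerability and habitat growth-differential parameters, a
    statistical pipeline for tabular migration records (size-versus-date
    regression with stream and year covariates, percentile-gap and
    seasonal summaries), and a seeded synthetic-record generator that
    emulates the structure of PIT-tag outmigration data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
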