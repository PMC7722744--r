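Package: callrhythm
Title: Persistence Analysis of Circadian Telephone-Call Rhythms from Call Detail Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses whether an individual's circadian rhythm of telephone-call
    activity persists across successive time periods, using call detail records
    (CDRs). Hourly 24-bin daily-rhythm profiles are compared with the square-root
    Jensen-Shannon divergence distance; an individual's intra-individual
    dissimilarity between two periods is ranked against their inter-individual
    dissimilarities within each period, and persistence is tested with an exact
    one-sided binomial sign test of quantiles, with a sequential extension for
    more than two periods. Includes a seeded synthetic CDR generator with known
    ground truth (stable versus drifting hourly profiles) so the full pipeline
    can be exercised and calibrated without access to private CDR data, plus
    tidy result tables, diagnostic plots, and a small command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
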