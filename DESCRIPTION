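Package: swellkin
Title: Hydrogel Swelling Kinetics: Unified Model Fitting and Transport-Mechanism Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits time-resolved hydrogel water-uptake data with the unified
    swelling-kinetics equation S(t) = (1 - exp(-k t)) (a* sqrt(t) + b*) and its
    classical limiting cases (power law, first-order, Peppas-Sahlin two-term,
    short-time Fickian approximation), decomposes uptake into Fickian-diffusion
    and macromolecular-relaxation contributions over time, classifies the
    transport mechanism from the a*/b* ratio or the power-law exponent,
    regresses network density against inverse square-root time, and compares
    fitted parameters across formulations with ANOVA and Tukey HSD compact
    letter displays. Includes a seeded synthetic-data generator reproducing the
    replicate structure of typical swelling studies, so every stage of the
    pipeline is testable without experimental data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
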