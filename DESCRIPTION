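Package: longmed
Title: Summaries, Multiplicity-Adjusted Comparisons and Mixed Models for
    Long-Format Longitudinal Medical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable toolkit for longitudinal clinical studies with many
    outcomes recorded per evaluation occasion (for example repeated symptom
    intensity scores on a 0-10 visual analog scale). Reads and validates
    long-format tables with declared variable roles; produces per-occasion
    descriptive tables with percentile-bootstrap confidence intervals for
    medians and exact binomial intervals for proportions; compares two groups
    of subjects across all outcomes under familywise-error control
    (Holm-Bonferroni and Westfall-Young step-down min-P permutation
    adjustment) and false-discovery-rate control (Benjamini-Hochberg and
    Benjamini-Yekutieli Q values); fits per-outcome linear and logistic
    regression including Firth's penalized likelihood for separated data and
    restricted cubic splines for nonlinear associations; fits random-intercept
    mixed models over all evaluation times; and draws the accompanying plot
    family (boxplots, spaghetti, lasagna, timeline bubbles, correlation heat
    maps, dendrograms, clustered heat maps). A synthetic-data generator
    emulates the structure of a multi-symptom erythema migrans cohort so every
    statistical routine can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
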