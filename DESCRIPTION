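Package: genlex
Title: Lifespan Estimation and Representativeness Diagnostics for
    Crowdsourced Genealogies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating adult male lifespan measures from
    genealogy-style individual microdata and for diagnosing how
    representative such crowdsourced data are of the underlying
    population.  Individual lifelines are cleaned with auditable
    exclusion rules, tabulated to death counts and person-year
    exposures on an age-by-period Lexis grid (optionally with left
    truncation at a delayed entry age), smoothed with two-dimensional
    P-splines under a Poisson count model, and converted to abridged
    period life tables (5-year age groups, open 80+ interval) carrying
    remaining life expectancy at age 30 and the Gini coefficient of
    remaining lifespan.  Confidence intervals come from binomial Monte
    Carlo resampling of death counts.  Representativeness diagnostics
    cover yearly population coverage, elite (scholar) record linkage
    and oversampling factors, and coverage-resemblance correlations.
    A synthetic-data generator with known Gompertz-Makeham ground
    truth emulates the biases of crowdsourced genealogies (partial
    dates, duplicates, transcription errors, time- and
    status-dependent inclusion) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
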