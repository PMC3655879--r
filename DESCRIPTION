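Package: riskbridge
Title: Risk-Equivalence Translation for Recreational Water Quality Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for translating a tolerable swimming-associated illness
    rate defined under one gastrointestinal-illness case definition into the
    equivalent rate under another, and for converting the translated rate
    into an Enterococcus qPCR water-quality criterion. Implements a
    beta-binomial model of beach-level background illness among non-swimmers
    with maximum-likelihood and adaptive Metropolis MCMC inference, the
    relative-risk equivalence translation algorithm, an identity-link
    binomial exposure-response model of illness on log10 Enterococcus qPCR
    cell equivalents with pooling tests and criterion inversion, and
    calibrated synthetic-cohort generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
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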