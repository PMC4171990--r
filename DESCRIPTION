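Package: melent
Title: Information-Theoretic Modeling of Melodic Expectation and Predictive
    Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling predictive uncertainty in melodic
    expectation. Implements a variable-order Markov model of pitch
    expectation with PPM-style smoothing, long- and short-term sub-models
    and entropy-weighted geometric-mean combination over linked melodic
    viewpoints (pitch interval, scale degree, inter-onset-interval
    contour); Shannon information content and entropy of the resulting
    predictive distributions; Krumhansl-Schmuckler key finding; an
    entropy-driven two-stage probe-tone stimulus-selection procedure; a
    rule-based Implication-Realization baseline; mixed-design behavioral
    statistics (Welch and pooled t, chi-square, Cronbach's alpha,
    Williams' t for dependent correlations, mixed and rank-transform
    ANOVA); and generators for synthetic melodic corpora and simulated
    probe-tone listeners so the full analysis pipeline can be exercised
    without external musical corpora.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
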