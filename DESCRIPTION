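Package: multirace
Title: Race-Model Analysis of Bisensory Reaction Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing speeded audiovisual (bisensory) detection
    data: quantile-based empirical CDFs, Raab's independent race model and
    its preceding-modality-conditioned variant, Grice and Miller bounds,
    multisensory benefit and gain statistics, competition (bias) models and
    facilitation-competition mixtures, modality switch effects, LATER
    (reciprocal-normal) channel fits with a correlated-channel (rho, eta)
    race extension, and a nonparametric inference layer (permutation tests
    with max-statistic and FDR correction, BCa bootstrap, Hedge's g, JZS
    Bayes factors, rank-based inverse normal transform, participant
    matching, moving-window comparisons, mixed-effects RT models and
    mediation). Includes a synthetic cohort generator that emulates the
    trial and reaction-time structure of an interleaved audiovisual
    detection task so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
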