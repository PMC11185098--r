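Package: dlcirt
Title: Dependent Latent Class Item Response Models for Disengaged Responding
Version: 0.1.0
Authors@R: person("dlcirt", "maintainers", email = "dlcirt@example.org", role = c("aut", "cre"))
Description: Fits dependent latent class item response (DLC-IRT) models that
    detect disengaged responding in multiple-choice tests. Each item-by-person
    encounter is assigned a latent engagement class; engaged responses follow a
    Rasch model while disengaged responses succeed at the guessing rate implied
    by the number of response options. Class membership is regressed on the log
    item response time, on dichotomous process-data indicators (answer change,
    text reread, item revisit), and optionally on a person-level random
    engagement threshold correlated with ability. Includes marginal maximum
    likelihood estimation via Gauss-Hermite quadrature, likelihood-ratio tests
    and information criteria, posterior classification and entropy, extraction
    of the process-data indicators from raw navigation/selection event logs,
    a generative simulator for parameter-recovery studies, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
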