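Package: mecmr
Title: Multi-Event Capture-Mark-Recapture Models of Age- and Quality-Dependent Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing breeding probability in long-lived iteroparous
    animals from coded annual capture histories. Fits multi-event (hidden
    Markov) capture-mark-recapture models with a two-class latent quality
    mixture, age-dependent survival, recruitment and breeding-state
    transitions, and year-block detection; provides goodness-of-fit tests
    (transience and memory components) with an overdispersion coefficient,
    quasi-likelihood information criteria (QSIC, QAICc), delta-method derived
    demographic quantities (inter-seasonal reproductive period, probability of
    future reproduction), Leslie-matrix life-history traits (growth rate, net
    reproductive rate, generation time, Gini index of iteroparity, pace and
    shape of aging and fecundity, reproductive value), and inter-breeding
    interval models (cluster-robust Cox proportional hazards and
    zero-truncated Poisson regression). A synthetic cohort generator with
    known truth supports end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
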