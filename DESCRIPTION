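Package: mixrank
Title: Prioritization and Hazard Characterization of Sufficiently Similar
    Chemical Mixtures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forms "sufficiently similar" surrogate mixtures from measured
    environmental chemical concentrations and multi-source toxicity metrics,
    and characterizes their hazard. Provides per-metric hazard ranking with
    average-rank aggregation under abundance, toxicity and abundance-weighted
    toxicity prioritization schemes; mixture recipes scaled to the most
    abundant component; a six-model continuous dose-response suite
    (log-logistic and Weibull families) with AIC selection, delta-method EC50
    standard errors and lowest-effect-level estimation via Dunnett many-to-one
    comparisons; binary developmental-endpoint statistics (exact binomial
    significance thresholds, Fisher's exact tests with Bonferroni correction,
    outlier and quality-control screens, quantal EC50/LC50); Pearson
    correlation diagnostics of metric rankings; and seeded synthetic-data
    generators that reproduce the statistical structure of every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    multcomp,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
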