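Package: CoronaCausality
Title: Actual-Causality Analysis of Protein Corona Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies which small-molecule plasma treatments are actual
    causes, in the Halpern-Pearl token-level sense with a probabilistic
    (probability-raising) counterfactual condition, of desired shifts in
    protein corona composition measured as per-protein log2 fold changes.
    Provides an empirical causal-model container, a dual-threshold effect
    predicate conditioned on protein abundance class, contingency-matched
    counterfactual comparison with exact rational probabilities, ranked
    cause reports, a two-dimensional threshold sweep with rank-frequency
    summaries, and a synthetic-data generator with planted causes and a
    confounder scenario so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'rational.R'
    'AllClasses.R'
    'AllGenerics.R'
    'schema.R'
    'causal-model.R'
    'effect.R'
    'cause-search.R'
    'brute-force.R'
    'sweep.R'
    'io.R'
    'simulate.R'
    'pipeline.R'
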