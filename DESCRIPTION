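Package: hierconf
Title: Hierarchical Bayesian Models of Confidence in Sample-Based Inference Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers combine small-sample evidence with
    an inferred context when reporting decision confidence. Implements the
    generative model of a two-level "airplane" task (a binary block tendency
    selecting skewed Beta distributions over hidden proportions, binomial
    samples of varying size), exact ideal-observer inference by Beta-binomial
    message passing, non-probabilistic heuristic observers (ratio, difference,
    averaging, tally), sigmoidal and flexible polynomial response mappings with
    a truncated-Gaussian-plus-lapse response likelihood, cross-validated
    maximum-likelihood model fitting with random-effects Bayesian model
    selection, and the behavioral pattern analyses (sample-size slopes,
    previous-trial weights, evidence-opposing choice rates) used to diagnose
    hierarchical probabilistic inference in confidence reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
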