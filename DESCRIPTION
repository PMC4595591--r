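Package: flexcontrol
Title: Volatility-Driven Flexible Control of Conflict Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of conflict-adaptation
    (Stroop-type) behaviour under changing control demands. Implements a
    discrete-grid hierarchical Bayesian filter in which a volatility-driven
    flexible learning rate governs trial-by-trial prediction of conflict,
    with reaction-speed emissions fitted by expectation-maximization;
    fixed-learning-rate Rescorla-Wagner comparators with exhaustive search;
    BIC-based random-effects group model selection with exceedance
    probabilities; a residualized trial-level behavioural GLM with the
    associated exclusion rules; and a synthetic task/behaviour generator
    reproducing a volatility-manipulated proportion-congruency design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
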