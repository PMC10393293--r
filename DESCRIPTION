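Package: banditnorm
Title: Context-Dependent Outcome Normalization in Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and maximum-likelihood fitting of reinforcement
    learning models with context-dependent outcome normalization on factorial
    multi-armed bandit tasks. Provides the factorial task designs (learning,
    transfer and explicit-rating phases), delta-rule learning agents with
    separate chosen/unchosen learning rates, five outcome-encoding rules
    (unbiased, divisive normalization, range normalization, and nonlinear
    range normalization with one or two weighting exponents), softmax and
    argmax decision rules, out-of-sample log-likelihood model comparison on
    transfer-phase choices, and parameter and model recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, graphics, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
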