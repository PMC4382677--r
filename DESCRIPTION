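Package: catcircuit
Title: Reward-Modulated Category Learning in a Mean-Field Cortical Circuit Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-circuit (sensory, association, decision) mean-field
    cortical network that learns a motion-direction categorization task through
    reward-prediction-error-modulated Hebbian plasticity. Provides the analytical
    theory core (covariance decomposition of the learning rule, a toy-model neuron,
    closed-form choice probability for Gaussian rates), a full neural-data analysis
    toolkit (category-tuning index, choice probability, category sensitivity,
    tuning-curve and ridge-GLM classification, noise correlations, Hartigan dip
    test, classical multidimensional scaling), and a synthetic fixture generator
    with known ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
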