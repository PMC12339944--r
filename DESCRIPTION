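Package: infodyn
Title: Information-Theoretic Measures and Estimators for Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimation of entropies (Shannon, Renyi, Tsallis), joint and
    cross-entropy, mutual information, conditional mutual information,
    transfer entropy, conditional transfer entropy and the
    Kullback-Leibler and Jensen-Shannon divergences from discrete or
    continuous data.  Estimator families include the discrete plug-in and
    bias-corrected (Miller-Madow, Grassberger, Chao-Shen, James-Stein
    shrinkage) estimators, kernel density estimators (box and Gaussian),
    nearest-neighbour metric estimators (Kozachenko-Leonenko and
    Kraskov-Stoegbauer-Grassberger) and ordinal-pattern symbolization.
    All measures support local (pointwise) values; inference is provided
    through permutation surrogates (p-values and t-scores), moving-block
    bootstrap confidence intervals and effective transfer entropy.
    Coupled tent-map and Ulam-map lattice generators reproduce classical
    closed-form validation experiments, and a small command-line
    interface exposes the one-liner API for delimited text input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
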