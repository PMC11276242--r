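Package: espamarkov
Title: Entropic Learning from Noisy Time-Ordered Data with Markov Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Supervised classification of noisy, time-ordered data in the
    small-data regime via entropic learning with a Markov smoothness prior
    (eSPA-Markov). Jointly learns a per-cluster Gaussian discretization of
    feature space, entropy-regularized feature weights, a Bayesian
    cluster-to-label classifier, and fuzzy cluster affiliations that are
    regularized towards the latent path of a Markov process. The affiliation
    step is a convex quadratic program over a product of probability
    simplices, solved with a spectral projected gradient method. Includes a
    direct one-shot learning variant for the case of a bijection between
    clusters and labels, hyperparameter grid search with chronological
    triple splitting, and generators for the variance-switching, rotated
    bivariate, and nanopore-inspired current-trace benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
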