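Package: cfimpute
Title: Collaborative Filtering for Sparse Subjective Rating Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers unobserved subjective ratings (emotions, continuous
    affect time-series, social decisions) from sparse user-by-item data
    using collaborative filtering. Provides a mean baseline, user-based
    k-nearest-neighbors prediction, non-negative matrix factorization with
    user/item biases trained by stochastic gradient descent, a Lee-Seung
    multiplicative-update factorization, and a chained-equations imputation
    comparator, together with a masking cross-validation harness reporting
    normalized per-user error, kernel-based dilation of sparse time-series
    annotations, intersubject-correlation summaries, and seeded synthetic
    generators for three rating-data archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
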