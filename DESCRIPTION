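Package: mncse
Title: Multiscale Symbolic Entropy Analysis of Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scale-based complexity analysis of physiological time series,
    in particular heart-rate variability recorded as interbeat (RR) interval
    series. Implements the multiscale normalized corrected Shannon entropy
    (MNCSE), a symbolic-dynamics complexity measure that stays defined on
    short records, alongside the classical multiscale sample entropy (MSE)
    comparator. Includes generators for the canonical white Gaussian and
    1/f validation noises, nonparametric per-scale group comparison (mean
    ranks, Kruskal-Wallis, Wilcoxon-Mann-Whitney, AUC), and a
    cross-validated classification layer over entropy-derived features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    FNN,
    quadprog,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
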