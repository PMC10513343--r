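Package: genart
Title: Flow-Field Generative Art, Statistical Image Features, and
    Time-Dependent Aesthetics Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates flow-field generative artworks (a Perlin-noise vector
    field steering a particle system onto an additively blended canvas),
    samples them into image sequences, and quantifies each image with a
    battery of 22 statistical image features (luminance statistics, Gabor
    edge-orientation entropy, PHOG anisotropy/complexity/self-similarity,
    oriented-filter symmetry scores, frequency-tuned and graph-based
    manifold-ranking saliency, pictorial balance, and generator color
    statistics). Provides the nonparametric comparison battery
    (Shapiro-Wilk, Kruskal-Wallis, pairwise Wilcoxon with Bonferroni
    correction, Spearman correlations with Fisher-z confidence intervals)
    and balanced-panel regression machinery (standardization, best-subset
    selection, VIF, pooled OLS, within fixed effects, Nerlove random
    effects, Hausman test, principal-component regression, Grubbs residual
    diagnostics) used to model aesthetic ratings of the sequences over
    time, plus a synthetic-ratings generator for end-to-end tests and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
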