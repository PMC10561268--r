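Package: pcnet
Title: Hierarchical Predictive-Coding Networks with Hebbian Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multilayered predictive-coding networks of rate neurons
    in which top-down predictions and bottom-up prediction errors drive both
    inference and purely Hebbian, local learning. Networks trained on
    temporally continuous transformation sequences (translating, rotating or
    scaling shapes) develop high-level representations that are invariant to
    the transformation, a hierarchy of intrinsic activity timescales, and a
    generative top-down pathway able to reconstruct and pattern-complete
    partially occluded inputs. Includes a synthetic stimulus generator,
    continuous and static training paradigms, representational dissimilarity
    and linear-decoding analyses with k-means and slow-feature-analysis
    baselines, autocorrelation timescale estimation with Welch ANOVA and
    Games-Howell statistics, and top-down reconstruction and occlusion
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
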