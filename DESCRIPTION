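Package: eegemotion
Title: EEG Emotion Recognition with Differential-Entropy Grid Features and
    an Efficient Transformer Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes affective state (valence, arousal, dominance) from
    multichannel EEG. One-second signal segments are band-pass filtered into
    the theta, alpha, beta and gamma bands, summarised per channel by
    Gaussian differential entropy, min-max normalised, placed onto a sparse
    9x9 scalp grid following 10-20 electrode geometry, and optionally passed
    through a logarithmic dynamic-range enhancement. The resulting C x 9 x 9
    tensors are classified by a compact network: a two-layer convolutional
    front-end followed by a stack of transformer encoders whose softmax
    attention is replaced by a linear-algebraic attention built from
    norm-scaled key-value Hadamard products and trainable mixing matrices.
    Includes loaders for the DEAP and DREAMER dataset dialects, a synthetic
    band-power EEG generator for download-free testing, label schemes
    (binary, fine-grained 8/5-class, composite VA/VAD), subject-dependent
    k-fold evaluation with macro-averaged metrics, and a parameter/FLOP
    audit comparing the efficient encoder with a standard one.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
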