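Package: msatnet
Title: Multi-Scale Adaptive Transformer Networks for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("MSATNet", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Classification of 2-4 class motor-imagery electroencephalography
    (EEG) trials with a multi-scale temporal-convolution feature extractor, a
    dilated-causal temporal decoder, a multi-head self-attention unit, and a
    residual bottleneck subject adapter for cross-subject transfer. Includes a
    seedable generator of event-related-desynchronization (ERD) structured
    synthetic EEG so that every stage is testable without external recordings,
    a minimal GDF reader for BCI-competition style files, within-subject and
    cross-subject (pretrain / adapter fine-tune) training protocols, and a
    command-line interface. All network layers, backpropagation and the Adam
    optimizer are implemented in R with compiled (Rcpp) convolution and
    normalization kernels; no deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
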