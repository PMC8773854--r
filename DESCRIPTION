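Package: mbeeg
Title: Multibranch Convolutional Networks for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decoding of four-class motor-imagery EEG with compact
    multibranch convolutional networks. Implements multibranch EEGNet-style
    and ShallowConvNet-style architectures in which parallel branches with
    heterogeneous temporal kernel sizes are concatenated before a shared
    softmax layer, together with the surrounding toolchain: an epoched-EEG
    container with an HDF5 archive format, cue-locked epoch extraction and
    per-channel standardization, polyphase resampling and channel selection,
    a BLAS-backed float32 training engine (Adam, best-checkpoint restore),
    a full evaluation suite (confusion matrices, Cohen's kappa, per-class
    precision/recall/F1, per-subject aggregation), a trainable-parameter and
    multiplication-count auditor, and a synthetic motor-imagery EEG
    generator with a band-power reference classifier for end-to-end testing
    without dataset downloads.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
SystemRequirements: HDF5 (libhdf5 C library)
Config/testthat/edition: 3
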