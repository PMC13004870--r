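Package: qtstack
Title: Standardized Quantum-Transistor Blocks for Hybrid Gait Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic implementation of the quantum-transistor (QT) variational
    block: closed-form Bloch-sphere transfer curves with exact parameter-shift
    gradients, a statevector reference oracle, stacked 4-3-2 hybrid networks with
    an index-preserving wiring rule and effective-chain pruning, class-weighted
    logistic training under subject-grouped cross-validation with F1-optimal
    threshold calibration, Pauli-transfer-matrix noise contraction and finite-shot
    estimation, block conformance tests with JSON manifests, and a synthetic
    gait-spectrogram generator emulating multi-channel wearable sensor streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
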