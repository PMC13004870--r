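# qtstack

Analytic tooling for the **quantum transistor (QT)** — a standardized
two-qubit variational block with transistor-like semantics — and for the
stacked hybrid classifier built from it, evaluated end to end on a synthetic
wearable-gait classification task.

## The block

A QT consumes one normalized scalar `s ∈ [−1, 1]` and returns the Pauli-Z
expectation of a *channel* qubit after a fixed gate sequence: input-scaled
rotations `R_y(κ₁s), R_x(κ₂s), R_z(κ₃s)` (plus composite re-uploads
`Rot(κⱼs)` for j ≥ 4, with `κⱼ = π θⱼ`), followed by a bias interaction — a
controlled `R_y(φ)` from a *gate* qubit prepared in `|1⟩`, which in this
instantiation is operationally an unconditional `R_y(φ)` on the channel. On
the Bloch sphere the p = 3 readout is the closed form

    y(s) = cos φ · cos(κ₁s) cos(κ₂s)
         − sin φ · [ sin(κ₁s) cos(κ₃s) + cos(κ₁s) sin(κ₂s) sin(κ₃s) ]

with midpoint `y(0) = cos φ`, transconductance `g_q(0) = −κ₁ sin φ`, and
exact parameter-shift gradients
`∂y/∂θⱼ = πs · ½ [y|₊π/₂ − y|₋π/₂]`. The bias angle `φ` opens or closes the
small-signal gain window exactly like a transistor's operating point.

The hybrid classifier contracts a 40×12 spectrogram window to eight bounded
signals `h = tanh(Wx + b)` and feeds a 4–3–2 stack of QTs with
index-preserving wiring; the logit is the second block of the last layer, so
the gradient-carrying *effective* model is a single 1–1–1 chain
(481 + 3p parameters) inside the executed 4–3–2 template (3848 + 9p
parameters).

## What the package provides

- `qt_forward()`, `qt_statevector()` — closed-form transfer and an
  independent two-qubit statevector oracle (agreement ≤ 1e−10).
- `qt_transconductance()`, `qt_small_signal()`, `qt_slope_bound()`,
  `qt_parameter_shift()` — gain analysis and exact gradients.
- `stack_config()`, `qt_forward_template()`, `qt_forward_effective()`,
  `qt_network_grad()`, `qt_resource_budget()` — the stacked network, its
  effective-chain pruning, and deterministic resource/shot accounting.
- `qt_train()`, `calibrate_threshold()`, `grouped_folds()`,
  `qt_hyper_search()` — class-weighted Adam training under subject-grouped
  cross-validation with validation-calibrated F1 thresholds carried
  unchanged to test.
- `noise_spec()`, `apply_noise()`, `sample_shots()`, `threshold_drift()` —
  Pauli-transfer-matrix noise contraction and finite-shot estimation.
- `qt_manifest()`, `conformance_midpoint()` / `_slope()` / `_contraction()`,
  `conformance_suite()` — the block manifest and conformance tests.
- `simulate_subject()`, `build_gait_dataset()`, `auto_label()` — a synthetic
  gait-spectrogram generator (70 Hz dual-foot sensor streams, PSD
  spectrograms quantized to 0–255, STFT band-energy auto-labeling with a
  five-second sustain rule).

## Worked example

```r
library(qtstack)

qp <- qt_params(theta = c(0.3, 0.2, 0.1), phi = pi / 3)
qt_forward(0, qp)                 # 0.5        (midpoint cos(pi/3))
qt_transconductance(0, qp)        # -0.8162097 (-kappa_1 sin(phi))
qt_statevector(0.37, qp)          # 0.1416002  (oracle agrees with qt_forward)

qt_resource_budget(stack_config(c(4, 3, 2), p = 5))
#   layout p n_blocks max_concurrent_qubits two_qubit_gates_per_forward
#    4-3-2 5        9                     8                          18
#   data_rotations_per_block shifted_circuits_per_step declared_params
#                          9                        90            3893
#   effective_params shots_per_update_factor
#                496                      91

data <- build_gait_dataset(seed = 1)
fit  <- qt_train(data, stack_config(p = 5), train_config(lr = 1e-3, seed = 1))
glance(fit)     # per-fold mean/sd of test accuracy and F1, micro-averages
```

The resource table reproduces the architecture arithmetic of the 4–3–2
template: 18 entangling gates per forward pass under the two-CNOT
controlled-Ry synthesis, at most 8 concurrent qubits, 90 parameter-shift
circuits per optimizer step, and the declared/effective parameter split
3893 / 496 at p = 5.

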