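#' Pauli-transfer-matrix noise specification for the QT readout
#'
#' Single-qubit channel noise acting on the measured channel is summarized by
#' the diagonal PTM contraction factors `(lambda_x, lambda_y, lambda_z)`, a
#' non-unital z-offset `t_z`, a readout bit-flip probability `p_r`, and a
#' two-qubit error contraction `lambda_2q`. The noisy readout is the exact
#' affine composition `(1 - 2 p_r) * lambda_2q * (lambda_z * y + t_z)`.
#'
#' @param lambda_x,lambda_y,lambda_z Diagonal PTM factors in `[-1, 1]`.
#' @param t_z Non-unital offset; physicality requires
#'   `|lambda_z| + |t_z| <= 1`.
#' @param p_r Readout flip probability in `[0, 1/2]`.
#' @param lambda_2q Two-qubit error contraction in `(0, 1]`.
#' @param shots Positive integer shot count `M`, or `"exact"`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(lambda_x = 1, lambda_y = 1, lambda_z = 1, t_z = 0,
                       p_r = 0, lambda_2q = 1, shots = "exact") {
  for (l in c(lambda_x, lambda_y, lambda_z)) {
    if (abs(l) > 1) stop("PTM contraction factors must lie in [-1, 1]",
                         call. = FALSE)
  }
  if (abs(lambda_z) + abs(t_z) > 1 + 1e-12) {
    stop("unphysical spec: |lambda_z| + |t_z| > 1, output could leave [-1, 1]",
         call. = FALSE)
  }
  if (p_r < 0 || p_r > 0.5) stop("p_r must lie in [0, 1/2]", call. = FALSE)
  if (lambda_2q <= 0 || lambda_2q > 1) {
    stop("lambda_2q must lie in (0, 1]", call. = FALSE)
  }
  if (!identical(shots, "exact")) stopifnot(shots >= 1)
  structure(
    list(lambda_x = lambda_x, lambda_y = lambda_y, lambda_z = lambda_z,
         t_z = t_z, p_r = p_r, lambda_2q = lambda_2q, shots = shots),
    class = "noise_spec"
  )
}

#' Depolarizing channel of rate q as a noise spec
#'
#' All three Bloch components contract by `1 - 4 q / 3`.
#' @param q Depolarizing rate in `[0, 3/4]`.
#' @export
depolarizing_spec <- function(q) {
  l <- 1 - 4 * q / 3
  noise_spec(lambda_x = l, lambda_y = l, lambda_z = l)
}

#' Small-rate amplitude damping as a noise spec
#'
#' First-order PTM: `lambda_z = 1 - q`, `t_z = q` (the channel relaxes toward
#' `|0>`), transverse factors `sqrt(1 - q)`.
#' @param q Damping rate in `[0, 1]`.
#' @export
amplitude_damping_spec <- function(q) {
  noise_spec(lambda_x = sqrt(1 - q), lambda_y = sqrt(1 - q),
             lambda_z = 1 - q, t_z = q)
}

#' Pure dephasing about Z as a noise spec
#'
#' Transverse components contract by `c`; `Z` is an eigenoperator so
#' `lambda_z = 1` and the readout is untouched.
#' @param c Transverse contraction in `[0, 1]`.
#' @export
dephasing_spec <- function(c = 0.5) {
  noise_spec(lambda_x = c, lambda_y = c, lambda_z = 1)
}

#' Apply a PTM noise spec to an ideal readout
#'
#' Exact affine composition, in order: channel contraction and offset, then
#' the two-qubit factor, then the readout-flip factor.
#'
#' @param y_ideal Numeric readouts in `[-1, 1]`.
#' @param spec A [noise_spec()].
#' @return Noisy readouts `(1 - 2 p_r) * lambda_2q * (lambda_z * y + t_z)`.
#' @export
apply_noise <- function(y_ideal, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  (1 - 2 * spec$p_r) * spec$lambda_2q * (spec$lambda_z * y_ideal + spec$t_z)
}

#' Check that a spec leaves the readout invariant (pure dephasing)
#'
#' Pure dephasing about Z has `lambda_z = 1` and no offset or readout error,
#' so the readout of any block is exactly unchanged. Returns `TRUE` iff
#' `apply_noise` is the identity on a sampled transfer curve.
#'
#' @param params A [qt_params()] object.
#' @param spec A [noise_spec()].
#' @param s Sample grid (default 101 points over `[-1, 1]`).
#' @export
dephasing_invariance_check <- function(params, spec,
                                       s = seq(-1, 1, length.out = 101)) {
  y <- qt_forward(s, params)
  all(apply_noise(y, spec) == y)
}

#' Finite-shot estimate of a bounded readout
#'
#' Draws `M` outcomes in `{-1, +1}` with `P(+1) = (1 + y) / 2` and returns
#' their mean: an unbiased estimator of `y` with variance `(1 - y^2) / M`.
#'
#' @param y True readout in `[-1, 1]`.
#' @param M Number of shots (`>= 1`).
#' @param seed Optional seed for a reproducible substream.
#' @return The shot-mean estimate.
#' @export
sample_shots <- function(y, M, seed = NULL) {
  stopifnot(M >= 1)
  if (abs(y) > 1) stop("|y| > 1 is not a valid readout", call. = FALSE)
  draw <- function() 2 * stats::rbinom(1, M, (1 + y) / 2) / M - 1
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Threshold drift under monotone noise contraction
#'
#' For each noise spec, transforms the scores by the exact affine noise map,
#' re-runs F1 threshold calibration, and compares: because a strictly
#' positive affine map preserves score ordering, the maximal F1 is exactly
#' invariant and the optimal threshold moves by the same affine map.
#'
#' @param scores Ideal scores in `[-1, 1]`.
#' @param labels 0/1 labels.
#' @param specs A list of [noise_spec()] objects.
#' @return A tibble with one row per spec: the recalibrated `max_f1`, the
#'   reference `max_f1_ideal`, the recalibrated and affine-mapped thresholds,
#'   and the F1 obtained on the noisy scores at the mapped threshold.
#' @export
threshold_drift <- function(scores, labels, specs) {
  cal0 <- calibrate_threshold(scores, labels)
  purrr::imap_dfr(specs, function(sp, i) {
    noisy <- apply_noise(scores, sp)
    cal <- calibrate_threshold(noisy, labels)
    tau_mapped <- apply_noise(cal0$tau_star, sp)
    m <- binary_metrics(as.integer(noisy > tau_mapped), as.integer(labels))
    tibble::tibble(
      spec = as.character(i),
      lambda_z = sp$lambda_z, t_z = sp$t_z, p_r = sp$p_r,
      lambda_2q = sp$lambda_2q,
      max_f1_ideal = cal0$max_f1, max_f1 = cal$max_f1,
      tau_star = cal$tau_star, tau_mapped = tau_mapped,
      f1_at_mapped = m$f1
    )
  })
}
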