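#' Rotate a Bloch vector about a coordinate axis
#'
#' Applies the SO(3) image of the half-angle qubit rotation
#' `R_a(angle) = exp(-i * angle * sigma_a / 2)` to a Bloch vector. The three
#' rotation matrices are the standard right-handed forms: `R_y` maps
#' `(0,0,1)` to `(sin a, 0, cos a)`.
#'
#' @param v Numeric length-3 Bloch vector `(v_x, v_y, v_z)`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle Rotation angle in radians.
#' @return The rotated length-3 Bloch vector; Euclidean norm is preserved.
#' @examples
#' rotate_axis(c(0, 0, 1), "y", pi / 2) # -> (1, 0, 0)
#' @export
rotate_axis <- function(v, axis, angle) {
  stopifnot(is.numeric(v), length(v) == 3, is.finite(angle))
  V <- rotate_axis_cols(matrix(v, nrow = 3), axis, angle)
  as.numeric(V)
}

# Vectorized rotation: V is a 3 x n matrix of Bloch vectors, angle a scalar or
# length-n vector. Returns the rotated 3 x n matrix.
rotate_axis_cols <- function(V, axis, angle) {
  ca <- cos(angle); sa <- sin(angle)
  switch(axis,
    x = rbind(V[1, ],
              ca * V[2, ] - sa * V[3, ],
              sa * V[2, ] + ca * V[3, ]),
    y = rbind( ca * V[1, ] + sa * V[3, ],
              V[2, ],
              -sa * V[1, ] + ca * V[3, ]),
    z = rbind(ca * V[1, ] - sa * V[2, ],
              sa * V[1, ] + ca * V[2, ],
              V[3, ]),
    stop("unknown axis '", axis, "'; must be one of x, y, z", call. = FALSE)
  )
}

# Constituent elementary rotations of a block, in application order.
# Base parameters j = 1..min(p,3) contribute one rotation each (axes y, x, z);
# each re-upload j >= 4 contributes the triple Rx, Ry, Rz sharing kappa_j * s
# (so the operator product Rz Ry Rx acts on the state).
qt_constituents <- function(params) {
  axes <- character(0); js <- integer(0)
  for (j in seq_len(params$p)) {
    if (params$axes[j] == "rot") {
      axes <- c(axes, "x", "y", "z"); js <- c(js, j, j, j)
    } else {
      axes <- c(axes, params$axes[j]); js <- c(js, j)
    }
  }
  list(axis = axes, j = js, n = length(axes))
}

# Core Bloch-sphere evaluation, vectorized over s. `shift` is an optional
# numeric vector of per-constituent angle offsets (parameter-shift probes);
# `phi_shift` offsets the bias angle. Returns the full 3 x n Bloch matrix.
qt_bloch <- function(s, params, shift = NULL, phi_shift = 0) {
  con <- qt_constituents(params)
  if (is.null(shift)) shift <- numeric(con$n)
  n <- length(s)
  V <- rbind(numeric(n), numeric(n), rep(1, n))
  for (k in seq_len(con$n)) {
    V <- rotate_axis_cols(V, con$axis[k], params$kappa[con$j[k]] * s + shift[k])
  }
  rotate_axis_cols(V, "y", params$phi + phi_shift)
}

#' Closed-form QT transfer curve
#'
#' Evaluates the block readout `y(s) = <Z>` on the Bloch sphere: starting from
#' `(0, 0, 1)`, the data rotations are applied in schedule order with angles
#' `kappa_j * s`, then the bias y-rotation by `phi`, and the z-component is
#' returned. For `p = 3` this equals the closed-form expression
#' `cos(phi) cos(a s) cos(b s) - sin(phi) [sin(a s) cos(c s) +
#' cos(a s) sin(b s) sin(c s)]` with `(a, b, c) = kappa[1:3]`.
#'
#' @param s Numeric vector of scalar inputs; the port contract is
#'   `s` in `[-1, 1]` (values outside are processed but flagged with a
#'   warning, since the math is total and silent clipping would corrupt
#'   gradients).
#' @param params A [qt_params()] object.
#' @return Numeric vector of readouts in `[-1, 1]`.
#' @examples
#' qp <- qt_params(c(0.3, 0.2, 0.1), phi = pi / 3)
#' qt_forward(0, qp) # cos(pi/3) = 0.5 independent of theta
#' @export
qt_forward <- function(s, params) {
  stopifnot(inherits(params, "qt_params"))
  if (any(abs(s) > 1)) {
    warning("qt_forward: input outside the declared port range [-1, 1]",
            call. = FALSE)
  }
  qt_bloch(s, params)[3, ]
}

#' Statevector reference oracle for the QT block
#'
#' Independent two-qubit simulation of the block unitary on the ordered basis
#' (gate, channel) with the gate qubit as the most significant factor (so
#' `|10>` means gate = 1, channel = 0). The gate is prepared `|1>` via X, the
#' channel starts in `|0>`; single-qubit rotations use
#' `R_a(t) = exp(-i t sigma_a / 2)`; the controlled-Ry bias (gate as control)
#' is applied last, and `<Z>` on the channel is returned. With
#' `bias = "unconditional"` the controlled rotation is replaced by a plain
#' `Ry(phi)` on the channel, which is operationally identical in this
#' fixed-control instantiation.
#'
#' @inheritParams qt_forward
#' @param bias `"controlled"` (default) or `"unconditional"`.
#' @return Numeric vector of channel `<Z>` values.
#' @export
qt_statevector <- function(s, params, bias = c("controlled", "unconditional")) {
  stopifnot(inherits(params, "qt_params"))
  bias <- match.arg(bias)
  vapply(s, qt_statevector1, numeric(1), params = params, bias = bias)
}

qt_statevector1 <- function(s, params, bias) {
  I2 <- diag(2)
  # |00> then X on the gate (left factor): |10> = basis index 3 (1-based)
  psi <- complex(real = c(0, 0, 1, 0))
  con <- qt_constituents(params)
  for (k in seq_len(con$n)) {
    g <- su2_rotation(con$axis[k], params$kappa[con$j[k]] * s)
    psi <- kronecker(I2, g) %*% psi
  }
  ry <- su2_rotation("y", params$phi)
  U_bias <- if (bias == "controlled") {
    p0 <- matrix(c(1, 0, 0, 0), 2, 2)
    p1 <- matrix(c(0, 0, 0, 1), 2, 2)
    kronecker(p0, I2) + kronecker(p1, ry)
  } else {
    kronecker(I2, ry)
  }
  psi <- U_bias %*% psi
  Zt <- kronecker(I2, diag(c(1, -1)))
  Re(Conj(t(psi)) %*% Zt %*% psi)[1, 1]
}

# SU(2) rotation matrices R_a(t) = exp(-i t sigma_a / 2)
su2_rotation <- function(axis, t) {
  c2 <- cos(t / 2); s2 <- sin(t / 2)
  switch(axis,
    x = matrix(c(c2, -1i * s2, -1i * s2, c2), 2, 2, byrow = TRUE),
    y = matrix(c(c2, -s2, s2, c2), 2, 2, byrow = TRUE) + 0i,
    z = diag(c(exp(-1i * t / 2), exp(1i * t / 2))),
    stop("unknown axis", call. = FALSE)
  )
}

#' Transconductance of the QT transfer
#'
#' The derivative `dy/ds` of the block readout. For `p = 3` the closed form
#' is evaluated literally; for general `p` (or on request) a central finite
#' difference is used.
#'
#' @inheritParams qt_forward
#' @param mode `"closed_form"` (requires `p == 3`), `"finite_difference"`, or
#'   `"auto"` (closed form when available).
#' @param step Central-difference step (default `1e-5`).
#' @return Numeric vector `dy/ds` at each `s`.
#' @examples
#' qp <- qt_params(c(0.3, 0.2, 0.1), phi = pi / 3)
#' qt_transconductance(0, qp) # equals -kappa_1 * sin(phi)
#' @export
qt_transconductance <- function(s, params,
                                mode = c("auto", "closed_form",
                                         "finite_difference"),
                                step = 1e-5) {
  stopifnot(inherits(params, "qt_params"))
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (params$p == 3) "closed_form" else "finite_difference"
  if (mode == "closed_form") {
    if (params$p != 3) {
      stop("closed-form transconductance requires p == 3", call. = FALSE)
    }
    a <- params$kappa[1]; b <- params$kappa[2]; g <- params$kappa[3]
    phi <- params$phi
    # d/ds of the closed-form transfer; the odd (sin phi) bracket contributes
    # five product-rule terms, including g * cos(as) sin(bs) cos(gs) from the
    # re-upload factor sin(gs).
    -cos(phi) * (a * sin(a * s) * cos(b * s) + b * cos(a * s) * sin(b * s)) -
      sin(phi) * (a * cos(a * s) * cos(g * s) - g * sin(a * s) * sin(g * s) -
                  a * sin(a * s) * sin(b * s) * sin(g * s) +
                  b * cos(a * s) * cos(b * s) * sin(g * s) +
                  g * cos(a * s) * sin(b * s) * cos(g * s))
  } else {
    (qt_bloch(s + step, params)[3, ] - qt_bloch(s - step, params)[3, ]) /
      (2 * step)
  }
}

#' Small-signal expansion of a p = 3 block
#'
#' Returns the transconductance at the operating point `s = 0`,
#' `g0 = -kappa_1 sin(phi)`, and the coefficient of `s^2` in the small-`s`
#' expansion, `quad = -(cos(phi) (kappa_1^2 + kappa_2^2) / 2 +
#' kappa_2 kappa_3 sin(phi))`, so that
#' `y(s) = cos(phi) + g0 s + quad s^2 + O(s^3)`.
#'
#' @param params A [qt_params()] object with `p == 3`.
#' @return A tibble with columns `g0` and `quad`.
#' @export
qt_small_signal <- function(params) {
  stopifnot(inherits(params, "qt_params"))
  if (params$p != 3) stop("small-signal expansion requires p == 3", call. = FALSE)
  a <- params$kappa[1]; b <- params$kappa[2]; g <- params$kappa[3]
  tibble::tibble(
    g0 = -a * sin(params$phi),
    quad = -(0.5 * cos(params$phi) * (a^2 + b^2) + b * g * sin(params$phi))
  )
}

#' Exact parameter-shift gradient of the QT readout
#'
#' For half-angle rotation generators the shift rule is exact:
#' `dy/dtheta_j = pi * s * (y(angle_j + pi/2) - y(angle_j - pi/2)) / 2` per
#' constituent angle (composite re-upload parameters sum the three shifted
#' differences of their constituent axis rotations), and
#' `dy/dphi = (y(phi + pi/2) - y(phi - pi/2)) / 2`.
#'
#' @inheritParams qt_forward
#' @param which Integer parameter index `j` in `1..p`, or `"phi"`.
#' @return Numeric vector of derivatives at each `s`.
#' @export
qt_parameter_shift <- function(s, params, which) {
  stopifnot(inherits(params, "qt_params"))
  if (identical(which, "phi")) {
    return((qt_bloch(s, params, phi_shift = pi / 2)[3, ] -
            qt_bloch(s, params, phi_shift = -pi / 2)[3, ]) / 2)
  }
  j <- which
  if (!is.numeric(j) || length(j) != 1 || j < 1 || j > params$p ||
      j != round(j)) {
    stop("`which` must be a parameter index in 1..p or \"phi\"", call. = FALSE)
  }
  con <- qt_constituents(params)
  idx <- which(con$j == j)
  out <- numeric(length(s))
  for (k in idx) {
    sh <- numeric(con$n)
    sh[k] <- pi / 2
    yp <- qt_bloch(s, params, shift = sh)[3, ]
    sh[k] <- -pi / 2
    ym <- qt_bloch(s, params, shift = sh)[3, ]
    out <- out + pi * s * (yp - ym) / 2
  }
  out
}

# Exact input derivative dy/ds via the chain rule over constituent angles:
# every pre-bias angle is kappa_j * s, so dy/ds = sum_k kappa_{j(k)} dy/dangle_k
# with each dy/dangle_k given by the parameter-shift rule. Vectorized over s.
qt_input_grad <- function(s, params) {
  con <- qt_constituents(params)
  out <- numeric(length(s))
  for (k in seq_len(con$n)) {
    sh <- numeric(con$n)
    sh[k] <- pi / 2
    yp <- qt_bloch(s, params, shift = sh)[3, ]
    sh[k] <- -pi / 2
    ym <- qt_bloch(s, params, shift = sh)[3, ]
    out <- out + params$kappa[con$j[k]] * (yp - ym) / 2
  }
  out
}

#' Analytic bound on the transfer slope of a p = 3 block
#'
#' Returns `|cos(phi)| (|k1| + |k2|) + |sin(phi)| (2 |k1| + |k2| + |k3|)`,
#' which dominates `|dy/ds|` for every `s` and supports layer-wise gain
#' budgeting when blocks are cascaded.
#'
#' @param params A [qt_params()] object with `p == 3`.
#' @return A single non-negative number.
#' @export
qt_slope_bound <- function(params) {
  stopifnot(inherits(params, "qt_params"))
  if (params$p != 3) stop("slope bound requires p == 3", call. = FALSE)
  k <- abs(params$kappa)
  abs(cos(params$phi)) * (k[1] + k[2]) +
    abs(sin(params$phi)) * (2 * k[1] + k[2] + k[3])
}

#' Transfer-curve data for plotting
#'
#' @inheritParams qt_forward
#' @param n Number of grid points over `[-1, 1]`.
#' @return A tibble with columns `s`, `y`, and `slope`.
#' @export
qt_transfer_curve <- function(params, n = 201) {
  s <- seq(-1, 1, length.out = n)
  tibble::tibble(
    s = s,
    y = qt_forward(s, params),
    slope = qt_transconductance(s, params)
  )
}

#' Plot a QT transfer curve with its operating point
#'
#' @param object A [qt_params()] object.
#' @param ... Unused.
#' @return A ggplot object showing `y(s)` and the midpoint `y(0) = cos(phi)`.
#' @export
autoplot.qt_params <- function(object, ...) {
  df <- qt_transfer_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$y)) +
    ggplot2::geom_hline(yintercept = cos(object$phi), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::annotate("point", x = 0, y = cos(object$phi), colour = "#b2182b") +
    ggplot2::labs(
      x = "input s", y = expression(y(s) == group("<", Z, ">")),
      title = sprintf("QT transfer (p = %d, phi = %.3f)", object$p, object$phi),
      subtitle = sprintf("midpoint y(0) = cos(phi) = %.3f; g_q(0) = %.3f",
                         cos(object$phi), -object$kappa[1] * sin(object$phi))
    ) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::theme_minimal()
}
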