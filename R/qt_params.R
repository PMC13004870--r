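#' Construct the parameter set of one quantum-transistor block
#'
#' A QT block is parameterized by `p >= 2` dimensionless rotation scalings
#' `theta` (the data-dependent rotation angles are `kappa_j * s` with
#' `kappa_j = pi * theta_j`) and a bias angle `phi` in radians, applied last
#' as a (controlled) y-rotation. The axis schedule is fixed by the block
#' standard: parameter 1 rotates about y, parameter 2 about x, parameter 3
#' about z, and every parameter `j >= 4` is a data re-upload applying the
#' composite rotation `Rot(a) = Rz(a) Ry(a) Rx(a)` with the shared angle
#' `kappa_j * s`.
#'
#' @param theta Numeric vector of length `p >= 2`, rotation scalings.
#' @param phi Bias angle in radians, in `[-pi, pi]`.
#' @return An object of class `qt_params` with fields `theta`, `kappa`
#'   (`= pi * theta`), `phi`, `p`, and the per-parameter axis schedule.
#' @examples
#' qp <- qt_params(theta = c(0.3, 0.2, 0.1), phi = pi / 3)
#' qt_forward(0.4, qp)
#' @export
qt_params <- function(theta, phi = pi / 3) {
  theta <- as.numeric(theta)
  if (length(theta) < 2) {
    stop("a QT block requires p >= 2 rotation scalings", call. = FALSE)
  }
  if (!all(is.finite(theta))) stop("theta must be finite", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1 || !is.finite(phi)) {
    stop("phi must be a single finite number", call. = FALSE)
  }
  if (abs(phi) > pi + 1e-12) {
    stop("phi must lie in [-pi, pi]", call. = FALSE)
  }
  p <- length(theta)
  structure(
    list(
      theta = theta,
      kappa = pi * theta,
      phi = phi,
      p = p,
      axes = qt_axis_schedule(p)
    ),
    class = "qt_params"
  )
}

# Fixed axis schedule: y, x, z for the base triplet; "rot" (Rz Ry Rx with a
# shared angle) for every re-upload j >= 4.
qt_axis_schedule <- function(p) {
  base <- c("y", "x", "z")
  if (p <= 3) base[seq_len(p)] else c(base, rep("rot", p - 3))
}

#' @export
print.qt_params <- function(x, ...) {
  cat("<qt_params> p =", x$p, "\n")
  cat("  theta:", format(x$theta, digits = 4), "\n")
  cat("  kappa:", format(x$kappa, digits = 4), "(pi * theta)\n")
  cat("  phi  :", format(x$phi, digits = 4), "rad; axes:",
      paste(x$axes, collapse = " "), "\n")
  invisible(x)
}

#' Draw random QT block parameters
#'
#' Samples `theta_j ~ Uniform(0.1, 0.5)` i.i.d., the initialization range used
#' throughout: it keeps `|kappa_j s| < pi/2` for `|s| <= 1`, so blocks start
#' off-saturation with a usable small-signal slope.
#'
#' @param p Number of rotation scalings.
#' @param phi Bias angle (default `pi/3`).
#' @param min,max Uniform range for `theta`.
#' @return A `qt_params` object.
#' @export
random_qt_params <- function(p = 3, phi = pi / 3, min = 0.1, max = 0.5) {
  qt_params(stats::runif(p, min, max), phi = phi)
}
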