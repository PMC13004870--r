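#' Standardized QT block manifest
#'
#' The manifest declares everything an implementation needs to reproduce a
#' block: the port contract, the fixed axis schedule for the base triplet,
#' the number of data re-uploads `p - 3`, the bias angle, the measurement,
#' the gate ordering, the gateset, and the initialization. Serialization is
#' strict: unknown fields are rejected and round-trips are bit-exact.
#'
#' @param params A [qt_params()] object (or `p`/`phi` supplied directly).
#' @param p,phi Used when `params` is missing.
#' @return An object of class `qt_manifest`.
#' @export
qt_manifest <- function(params = NULL, p = NULL, phi = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "qt_params"))
    p <- params$p
    phi <- params$phi
  }
  structure(
    list(
      schema_version = "qtstack/manifest/v1",
      ports = list(input = "real in [-1,1]",
                   output = "Z-expectation in [-1,1]"),
      axes = c("y", "x", "z"),
      reuploads = max(0L, as.integer(p) - 3L),
      phi = phi,
      meas = "Z on channel",
      s_order = "all data rotations first, bias last",
      gateset = c("X", "Rx", "Ry", "Rz", "CRY"),
      init = "gate |1> via X, channel |0>"
    ),
    class = "qt_manifest"
  )
}

manifest_fields <- c("schema_version", "ports", "axes", "reuploads", "phi",
                     "meas", "s_order", "gateset", "init")

#' Write a manifest to JSON
#' @param manifest A [qt_manifest()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "qt_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read and validate a manifest from JSON
#'
#' Strict schema: the version string, field set, and the fixed literals
#' (axes, gate order, measurement, gateset, init) are all checked; unknown
#' fields raise an error.
#'
#' @param path File path.
#' @return A `qt_manifest` object.
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(doc), manifest_fields)
  if (length(extra) > 0) {
    stop("unknown manifest fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(manifest_fields, names(doc))
  if (length(missing) > 0) {
    stop("missing manifest fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(doc$schema_version, "qtstack/manifest/v1")) {
    stop("unsupported manifest schema: ", doc$schema_version, call. = FALSE)
  }
  ref <- qt_manifest(p = doc$reuploads + 3L, phi = as.numeric(doc$phi))
  fixed <- c("axes", "meas", "s_order", "gateset", "init", "ports")
  for (f in fixed) {
    got <- doc[[f]]
    want <- ref[[f]]
    if (is.list(want)) {
      got <- lapply(got, as.character)
      want <- lapply(want, as.character)
    }
    if (!identical(unname(unlist(got)), unname(unlist(want)))) {
      stop("manifest field '", f, "' deviates from the block standard",
           call. = FALSE)
    }
  }
  out <- ref
  out$phi <- as.numeric(doc$phi)
  out$reuploads <- as.integer(doc$reuploads)
  out
}

conf_result <- function(check, measured, expected, tol) {
  tibble::tibble(check = check, measured = measured, expected = expected,
                 tol = tol, pass = abs(measured - expected) <= tol)
}

# z-quantile for the two-sided binomial CI used in shot mode
shot_z <- function(alpha = 1e-3) stats::qnorm(1 - alpha / 2)

#' Conformance check: midpoint
#'
#' Certifies that a block evaluator reproduces the midpoint
#' `y(0) = cos(phi)`. In exact mode the tolerance is `1e-10`; in shot mode a
#' two-sided binomial confidence bound at significance `1e-3` on the shot
#' mean of `M` outcomes is used.
#'
#' @param block_eval Function `s -> y` (may be noisy or shot-sampled).
#' @param phi Declared bias angle.
#' @param mode `"exact"` or `"shots"`.
#' @param M Shot count (required in shot mode).
#' @return A one-row tibble: `check`, `measured`, `expected`, `tol`, `pass`.
#' @export
conformance_midpoint <- function(block_eval, phi, mode = c("exact", "shots"),
                                 M = NULL) {
  mode <- match.arg(mode)
  y0 <- block_eval(0)
  tol <- if (mode == "exact") 1e-10 else {
    stopifnot(!is.null(M))
    shot_z() * sqrt(max(1e-12, 1 - cos(phi)^2) / M + 1 / M)
  }
  conf_result("midpoint", y0, cos(phi), tol)
}

#' Conformance check: small-signal slope
#'
#' Symmetric two-point probe around `s = 0`:
#' `(y(+eps) - y(-eps)) / (2 eps)` compared with the declared slope
#' `-kappa_1 sin(phi)` (exact for the base-triplet block). The exact-mode
#' tolerance accounts for the `O(eps^2)` probe bias; shot mode adds the
#' binomial CI of the two shot means divided by `2 eps`.
#'
#' @inheritParams conformance_midpoint
#' @param kappa1 Declared y-axis scaling (radians per unit input).
#' @param probe_eps Probe half-width in `(0, 0.05]` (default `1e-3`).
#' @export
conformance_slope <- function(block_eval, kappa1, phi, probe_eps = 1e-3,
                              mode = c("exact", "shots"), M = NULL) {
  mode <- match.arg(mode)
  stopifnot(probe_eps > 0, probe_eps <= 0.05)
  est <- (block_eval(probe_eps) - block_eval(-probe_eps)) / (2 * probe_eps)
  bias_tol <- 10 * probe_eps^2 + 1e-10
  tol <- if (mode == "exact") bias_tol else {
    stopifnot(!is.null(M))
    bias_tol + shot_z() * sqrt(2 / M) / (2 * probe_eps)
  }
  conf_result("slope", est, -kappa1 * sin(phi), tol)
}

#' Conformance check: monotone noise contraction
#'
#' Repeated executions of a conforming block over a common `s` grid must
#' agree up to a scalar contraction `lambda_Z` in `(0, 1]`: the second run is
#' regressed through the origin on the first and the residual RMS must stay
#' below `tol`.
#'
#' @param runs A list of (at least two) numeric vectors: repeated
#'   evaluations of the transfer over the same `s` grid.
#' @param tol Residual RMS tolerance (default `1e-8` for exact evaluations).
#' @return A one-row tibble with fitted `lambda`, `residual_rms`, and `pass`.
#' @export
conformance_contraction <- function(runs, tol = 1e-8) {
  stopifnot(is.list(runs), length(runs) >= 2)
  r1 <- runs[[1]]
  r2 <- runs[[2]]
  stopifnot(length(r1) == length(r2))
  lambda <- sum(r1 * r2) / sum(r1^2)
  rms <- sqrt(mean((r2 - lambda * r1)^2))
  tibble::tibble(check = "contraction", lambda = lambda, residual_rms = rms,
                 tol = tol,
                 pass = rms <= tol && lambda > 0 && lambda <= 1 + 1e-9)
}

#' Run the block-level unit-test suite on one parameter set
#'
#' Aggregates the three verification pathways of the block standard:
#' (i) the closed-form transfer against the independent statevector oracle,
#' (ii) the small-`s` slope against a central finite difference, and
#' (iii) every parameter-shift gradient against finite differences.
#'
#' @param params A [qt_params()] object.
#' @param forward_fn Transfer implementation under test (default
#'   [qt_forward()]; tests can inject a corrupted implementation).
#' @param n_s Number of random `s` draws for check (i).
#' @param seed Seed for the draws.
#' @return A tibble with one row per check: `check`, `max_error`, `tol`,
#'   `pass`.
#' @export
conformance_suite <- function(params, forward_fn = qt_forward, n_s = 50,
                              seed = 1) {
  s <- with_local_seed(derive_seed(seed, "suite"), stats::runif(n_s, -1, 1))
  err_sv <- max(abs(forward_fn(s, params) - qt_statevector(s, params)))
  eps <- 1e-4
  slope_fd <- (forward_fn(eps, params) - forward_fn(-eps, params)) / (2 * eps)
  slope_ref <- qt_input_grad(0, params)
  err_slope <- abs(slope_fd - slope_ref)
  h <- 1e-5
  err_ps <- 0
  s_g <- s[seq_len(min(5, n_s))]
  for (j in seq_len(params$p)) {
    fd <- (forward_fn(s_g, qt_params(params$theta + h * (seq_len(params$p) == j),
                                     phi = params$phi)) -
           forward_fn(s_g, qt_params(params$theta - h * (seq_len(params$p) == j),
                                     phi = params$phi))) / (2 * h)
    err_ps <- max(err_ps, max(abs(qt_parameter_shift(s_g, params, j) - fd)))
  }
  dplyr::bind_rows(
    tibble::tibble(check = "statevector", max_error = err_sv, tol = 1e-10),
    tibble::tibble(check = "slope", max_error = err_slope, tol = 1e-6),
    tibble::tibble(check = "parameter_shift", max_error = err_ps, tol = 1e-6)
  ) |>
    dplyr::mutate(pass = .data$max_error <= .data$tol)
}
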