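#' Classical contraction front-end parameters
#'
#' The only classical trainable stage before the QT stack: a single affine map
#' `W x + b` (`W` is `8 x D`, `b` length 8) followed by a pointwise `tanh`,
#' producing eight bounded signals in `(-1, 1)`. For the 40x12 spectrogram
#' windows used throughout, `D = 480` and the contraction carries
#' `8 D + 8 = 3848` parameters.
#'
#' @param W Numeric `8 x D` matrix.
#' @param b Numeric length-8 vector (default zeros).
#' @return An object of class `contraction_params`.
#' @export
contraction_params <- function(W, b = numeric(8)) {
  W <- as.matrix(W)
  if (nrow(W) != 8) stop("W must have 8 rows", call. = FALSE)
  b <- as.numeric(b)
  if (length(b) != 8) stop("b must have length 8", call. = FALSE)
  structure(list(W = W, b = b, D = ncol(W)), class = "contraction_params")
}

#' Random contraction initialization
#'
#' `W` entries `~ Uniform(-0.05, 0.05)`, `b = 0`: a small init that keeps
#' `W x` well-conditioned for inputs scaled to `[0, 1]`.
#'
#' @param D Flattened input length (480 for 40x12 windows).
#' @return A [contraction_params()] object.
#' @export
random_contraction <- function(D = 480) {
  contraction_params(matrix(stats::runif(8 * D, -0.05, 0.05), nrow = 8))
}

#' Apply the contraction front-end
#'
#' @param x Numeric vector of length `D`, or a `D x n` matrix of columns.
#' @param contraction A [contraction_params()] object.
#' @return `tanh(W x + b)`: an 8-vector, or `8 x n` matrix for matrix input.
#' @export
qt_contract <- function(x, contraction) {
  stopifnot(inherits(contraction, "contraction_params"))
  if (is.matrix(x)) {
    if (nrow(x) != contraction$D) {
      stop("x must have D = ", contraction$D, " rows", call. = FALSE)
    }
    tanh(contraction$W %*% x + contraction$b)
  } else {
    if (length(x) != contraction$D) {
      stop("x must have length D = ", contraction$D, call. = FALSE)
    }
    as.numeric(tanh(contraction$W %*% x + contraction$b))
  }
}

#' Configuration of a stacked QT network
#'
#' Declares the executed template: layer widths (default `c(4, 3, 2)`), the
#' per-block parameter count `p`, the shared bias angle `phi`, per-layer
#' block parameters, and the logit address (default: block 2 of the last
#' layer, as in the 4-3-2 standard). Wiring is the fixed index-preserving
#' rule `s^(l+1)_i = z^(l)_i`.
#'
#' @param widths Integer vector of layer sizes; layer 1 width must not
#'   exceed the 8 contraction outputs.
#' @param p Rotation scalings per block (`>= 2`).
#' @param phi Shared bias angle (default `pi/3`).
#' @param blocks Optional list (one element per layer) of lists of
#'   [qt_params()]; drawn via [random_qt_params()] when omitted.
#' @param logit_layer Index of the layer holding the logit block (default:
#'   last layer).
#' @param logit_block Block index within that layer (default 2, or the last
#'   block if the layer is narrower).
#' @return An object of class `stack_config`.
#' @export
stack_config <- function(widths = c(4, 3, 2), p = 5, phi = pi / 3,
                         blocks = NULL,
                         logit_layer = length(widths),
                         logit_block = min(2, widths[length(widths)])) {
  widths <- as.integer(widths)
  if (length(widths) < 1 || any(widths < 1)) {
    stop("widths must be positive integers", call. = FALSE)
  }
  if (widths[1] > 8) {
    stop("layer 1 width exceeds the 8 contraction outputs", call. = FALSE)
  }
  if (is.null(blocks)) {
    blocks <- lapply(widths, function(w) {
      lapply(seq_len(w), function(i) random_qt_params(p, phi = phi))
    })
  }
  stopifnot(length(blocks) == length(widths))
  for (l in seq_along(widths)) {
    stopifnot(length(blocks[[l]]) == widths[l])
    for (blk in blocks[[l]]) {
      if (blk$p != p) stop("all blocks must share the configured p", call. = FALSE)
    }
  }
  if (logit_layer < 1 || logit_layer > length(widths) ||
      logit_block < 1 || logit_block > widths[logit_layer]) {
    stop("logit indices do not address an existing block", call. = FALSE)
  }
  structure(
    list(widths = widths, p = p, phi = phi, blocks = blocks,
         logit_layer = logit_layer, logit_block = logit_block),
    class = "stack_config"
  )
}

#' @export
print.stack_config <- function(x, ...) {
  cat("<stack_config>", paste(x$widths, collapse = "-"),
      "template, p =", x$p, ", phi =", format(x$phi, digits = 4), "\n")
  cat("  logit: layer", x$logit_layer, "block", x$logit_block, "\n")
  invisible(x)
}

# Chain of (layer, block) indices carrying gradient to the logit under the
# index-preserving wiring: the logit block index, at every layer up to the
# logit layer.
effective_chain <- function(stack) {
  i <- stack$logit_block
  layers <- seq_len(stack$logit_layer)
  if (any(stack$widths[layers] < i)) {
    stop("logit block index ", i, " is not wired through every layer",
         call. = FALSE)
  }
  lapply(layers, function(l) list(layer = l, block = i))
}

#' Evaluate the full executed template
#'
#' Runs the contraction and every declared block: layer 1 consumes the first
#' `n_1` contracted signals, and layer `l + 1` block `i` consumes layer-`l`
#' block-`i` output (index-preserving wiring). Off-path blocks are evaluated
#' and logged but do not influence the logit.
#'
#' @param x Flattened input vector of length `D` (values scaled to `[0, 1]`).
#' @param contraction A [contraction_params()] object.
#' @param stack A [stack_config()] object.
#' @return A list of class `qt_activations` with fields `h` (8-vector),
#'   `z` (per-layer output vectors in `[-1, 1]`), `logit`, and
#'   `prob = sigmoid(logit)`.
#' @export
qt_forward_template <- function(x, contraction, stack) {
  h <- qt_contract(x, contraction)
  s_in <- h[seq_len(stack$widths[1])]
  z <- vector("list", length(stack$widths))
  for (l in seq_along(stack$widths)) {
    if (l > 1) s_in <- z[[l - 1]][seq_len(stack$widths[l])]
    z[[l]] <- vapply(seq_len(stack$widths[l]), function(i) {
      qt_forward(s_in[i], stack$blocks[[l]][[i]])
    }, numeric(1))
  }
  logit <- z[[stack$logit_layer]][stack$logit_block]
  structure(list(h = h, z = z, logit = logit, prob = sigmoid(logit)),
            class = "qt_activations")
}

#' Evaluate only the effective gradient-carrying chain
#'
#' Computes the logit through the single index-preserving chain ending at the
#' logit block (`h_i -> z^(1)_i -> ... -> logit`), skipping every off-path
#' block. Bit-identical to [qt_forward_template()]'s logit because each block
#' consumes one scalar and blocks are independent.
#'
#' @inheritParams qt_forward_template
#' @param x Flattened input vector of length `D`, or a `D x n` matrix to
#'   evaluate a batch.
#' @return Numeric logit(s) in `[-1, 1]`.
#' @export
qt_forward_effective <- function(x, contraction, stack) {
  i <- stack$logit_block
  chain <- effective_chain(stack)
  # row-extracted matrix product keeps the summation order (hence the float
  # result) bit-identical to the full-template contraction
  xm <- if (is.matrix(x)) x else matrix(x)
  s <- tanh(as.numeric(contraction$W[i, , drop = FALSE] %*% xm) +
              contraction$b[i])
  for (st in chain) s <- qt_forward(s, stack$blocks[[st$layer]][[st$block]])
  s
}

#' Gradient of the class-weighted loss through the network
#'
#' Chain-rule product along the effective chain: the loss derivative at the
#' logit, the exact parameter-shift input-derivatives of each on-path block,
#' and the tanh contraction Jacobian. Per-theta derivatives use the
#' parameter-shift rule; every off-path parameter receives exactly zero.
#'
#' @inheritParams qt_forward_template
#' @param y_label 0/1 class label.
#' @param lambda Positive-class weight in the loss (default 1).
#' @return A list with `loss`, `logit`, `grad_W` (8 x D, only the on-path row
#'   nonzero), `grad_b` (length 8), and `grad_theta` (list over layers of
#'   `p x width` matrices, only the on-path column nonzero).
#' @export
qt_network_grad <- function(x, y_label, contraction, stack, lambda = 1) {
  i <- stack$logit_block
  chain <- effective_chain(stack)
  nlayer <- length(chain)
  # forward along the chain, keeping stage inputs
  a <- as.numeric(contraction$W[i, , drop = FALSE] %*% matrix(x)) +
    contraction$b[i]
  s_stage <- numeric(nlayer)  # input to each on-path block
  s_cur <- tanh(a)
  for (k in seq_len(nlayer)) {
    s_stage[k] <- s_cur
    s_cur <- qt_forward(s_cur, stack$blocks[[k]][[i]])
  }
  logit <- s_cur
  dL_dlogit <- weighted_bce_grad(logit, y_label, lambda)

  # backward: upstream[k] = dL / d z^(k); block input-derivatives via the
  # chain rule over shifted constituent angles
  gin <- vapply(seq_len(nlayer), function(k) {
    qt_input_grad(s_stage[k], stack$blocks[[k]][[i]])
  }, numeric(1))
  upstream <- numeric(nlayer)
  acc <- dL_dlogit
  for (k in rev(seq_len(nlayer))) {
    upstream[k] <- acc            # dL / d z^(k) for the on-path block
    acc <- acc * gin[k]           # dL / d s^(k) = dL / d z^(k-1)
  }
  dL_ds1 <- acc                   # dL / d h_i

  grad_theta <- lapply(seq_along(stack$widths), function(l) {
    matrix(0, nrow = stack$p, ncol = stack$widths[l])
  })
  for (k in seq_len(nlayer)) {
    blk <- stack$blocks[[k]][[i]]
    for (j in seq_len(stack$p)) {
      grad_theta[[k]][j, i] <- upstream[k] *
        qt_parameter_shift(s_stage[k], blk, j)
    }
  }

  grad_W <- matrix(0, nrow = 8, ncol = contraction$D)
  grad_b <- numeric(8)
  dtanh <- 1 - tanh(a)^2
  grad_W[i, ] <- dL_ds1 * dtanh * x
  grad_b[i] <- dL_ds1 * dtanh
  list(
    loss = weighted_bce(logit, y_label, lambda),
    logit = logit,
    grad_W = grad_W,
    grad_b = grad_b,
    grad_theta = grad_theta
  )
}

#' Resource accounting for a stacked QT network
#'
#' Deterministic counts for scheduling and budgeting: concurrent qubits,
#' entangling gates under the two-CNOT controlled-Ry synthesis (sequential
#' layers), data-dependent rotations per block, shifted circuits per
#' optimizer step, declared (executed-template) and effective
#' (gradient-carrying) parameter totals, and the per-update shot budget.
#'
#' @param stack A [stack_config()] object (or `widths`/`p` via arguments).
#' @param D Flattened input length (default 480).
#' @param mode `"explicit_cry"` counts two CNOTs per block;
#'   `"compiled_away"` counts zero (fixed-control bias collapsed by the
#'   compiler).
#' @return A one-row tibble with the counts and a `shot_budget` function-free
#'   column `shots_per_update_factor` (multiply by M shots).
#' @examples
#' qt_resource_budget(stack_config(c(4, 3, 2), p = 5))
#' @export
qt_resource_budget <- function(stack, D = 480,
                               mode = c("explicit_cry", "compiled_away")) {
  mode <- match.arg(mode)
  widths <- stack$widths
  p <- stack$p
  n_blocks <- sum(widths)
  shifted <- 2L * p * n_blocks
  tibble::tibble(
    layout = paste(widths, collapse = "-"),
    p = p,
    n_blocks = n_blocks,
    max_concurrent_qubits = 2L * max(widths),
    two_qubit_gates_per_forward =
      if (mode == "explicit_cry") 2L * n_blocks else 0L,
    data_rotations_per_block = if (p >= 3) 3L + 3L * (p - 3L) else p,
    shifted_circuits_per_step = shifted,
    declared_params = 8L * D + 8L + p * n_blocks,
    effective_params = (D + 1L) + length(widths) * p,
    shots_per_update_factor = shifted + 1L
  )
}

#' Parameter counts of the classical reference models
#'
#' @param D Flattened input length.
#' @param hidden Hidden width of the tiny MLP (default 8).
#' @return A one-row tibble: `logistic = D + 1` and
#'   `mlp = D * hidden + hidden + hidden + 1` (one hidden layer with biases).
#' @examples
#' baseline_param_counts(480) # logistic 481, mlp 3857
#' @export
baseline_param_counts <- function(D, hidden = 8) {
  stopifnot(D >= 1)
  tibble::tibble(
    D = D, hidden = hidden,
    logistic = D + 1L,
    mlp = D * hidden + hidden + hidden + 1L
  )
}

#' Serialize a stack and contraction to a versioned JSON document
#'
#' Embeds the per-block manifests (see [qt_manifest()]) plus the flattened
#' numeric arrays. The schema string is mandatory and checked on read.
#'
#' @param contraction A [contraction_params()] object.
#' @param stack A [stack_config()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_stack_json <- function(contraction, stack, path) {
  doc <- list(
    schema = "qtstack/stack/v1",
    widths = stack$widths,
    p = stack$p,
    phi = stack$phi,
    logit_layer = stack$logit_layer,
    logit_block = stack$logit_block,
    theta = lapply(stack$blocks, function(layer) {
      lapply(layer, function(blk) blk$theta)
    }),
    manifests = lapply(stack$blocks, function(layer) {
      lapply(layer, function(blk) unclass(qt_manifest(blk)))
    }),
    W = as.numeric(t(contraction$W)),  # row-major
    b = contraction$b,
    D = contraction$D
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a stack serialized by [write_stack_json()]
#'
#' @param path File path.
#' @return A list with elements `contraction` and `stack`.
#' @export
read_stack_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "qtstack/stack/v1")) {
    stop("unrecognized stack schema: ", doc$schema, call. = FALSE)
  }
  phi <- as.numeric(doc$phi)
  blocks <- lapply(doc$theta, function(layer) {
    lapply(layer, function(th) qt_params(unlist(th), phi = phi))
  })
  stack <- stack_config(unlist(doc$widths), p = as.integer(doc$p), phi = phi,
                        blocks = blocks,
                        logit_layer = as.integer(doc$logit_layer),
                        logit_block = as.integer(doc$logit_block))
  W <- matrix(unlist(doc$W), nrow = 8, byrow = TRUE)
  list(contraction = contraction_params(W, unlist(doc$b)), stack = stack)
}
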