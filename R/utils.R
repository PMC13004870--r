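#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(t))
softplus <- function(t) log1p(exp(-abs(t))) + pmax(t, 0)

# Deterministic substream seeds: one root seed fans out to named streams
# (data, init, shuffle, shots, ...) so every randomness source is
# reproducible and independent. Kept below 2^31.
derive_seed <- function(root, stream) {
  # polynomial rolling hash over the stream name, seeded by the root;
  # all intermediates stay below 2^53 so the arithmetic is exact
  h <- (as.numeric(root) * 48271) %% 2147483647
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Run code under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Flatten labeled windows into a model input matrix
#'
#' Row-major flattening of each 40x12 grid, scaled from 0-255 to `[0, 1]`.
#'
#' @param grids A list of integer matrices (rows = frequency rows,
#'   columns = time frames).
#' @return An `n x D` numeric matrix (one row per window).
#' @export
flatten_windows <- function(grids) {
  t(vapply(grids, function(g) as.numeric(t(g)) / 255,
           numeric(nrow(grids[[1]]) * ncol(grids[[1]]))))
}

binary_metrics <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / length(labels),
                 precision = prec, recall = rec, f1 = f1)
}
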