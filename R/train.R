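#' Training configuration
#'
#' Defaults follow the selected operating configuration of the hybrid stack:
#' learning rate `4.318e-4`, positive-class weight resolved per training fold
#' (`"auto"` sets `lambda = N_neg / N_pos`), Adam moments `(0.9, 0.999)`,
#' 30 epochs of batch size 32, and 3 subject-grouped folds.
#'
#' @param lr Positive learning rate.
#' @param pos_weight Positive real or `"auto"`.
#' @param epochs,batch_size Integers.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed Root seed; every randomness source derives a named substream
#'   from it.
#' @param folds Number of grouped cross-validation folds (`>= 2`).
#' @param theta_range Gain-budget projection range for the rotation
#'   scalings: after every optimizer step `theta` is clamped into this
#'   interval, keeping `|kappa_j s| <= pi/2` at the default upper bound so
#'   blocks cannot lock onto zero-slope transfer plateaus.
#' @param select_best_epoch Epoch-level early stopping: report the
#'   parameters of the epoch with the best validation max-F1 (default
#'   `TRUE`), mirroring the early-stoppage used throughout the protocol.
#' @param max_restarts Maximum number of deterministic re-initializations
#'   when a run's training F1 never beats the trivial one-class baseline
#'   (a pinched-off chain with a dead discrimination gradient).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 4.318e-4, pos_weight = "auto", epochs = 30,
                         batch_size = 32, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1, folds = 3,
                         theta_range = c(0.02, 0.5),
                         select_best_epoch = TRUE, max_restarts = 3) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, folds >= 2)
  stopifnot(length(theta_range) == 2, theta_range[1] < theta_range[2])
  if (!identical(pos_weight, "auto")) stopifnot(pos_weight > 0)
  structure(
    list(lr = lr, pos_weight = pos_weight, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), beta1 = beta1, beta2 = beta2,
         eps = eps, seed = as.integer(seed), folds = as.integer(folds),
         theta_range = theta_range,
         select_best_epoch = isTRUE(select_best_epoch),
         max_restarts = as.integer(max_restarts)),
    class = "train_config"
  )
}

#' Class-weighted logistic loss
#'
#' `lambda * y * log(1 + exp(-l)) + (1 - y) * log(1 + exp(l))`, computed with
#' the numerically stable softplus form. With `lambda = 1` this is the
#' standard binary cross-entropy on a logit.
#'
#' @param logit Numeric vector of logits.
#' @param y 0/1 labels.
#' @param lambda Positive weight applied to the positive class.
#' @return Numeric vector of per-example losses.
#' @export
weighted_bce <- function(logit, y, lambda = 1) {
  lambda * y * softplus(-logit) + (1 - y) * softplus(logit)
}

#' Gradient of the class-weighted logistic loss w.r.t. the logit
#'
#' `sigma(l) * (1 + (lambda - 1) y) - lambda * y`, identically equal to
#' `(sigma(l) - y) - (lambda - 1) y (1 - sigma(l))`.
#'
#' @inheritParams weighted_bce
#' @return Numeric vector of derivatives.
#' @export
weighted_bce_grad <- function(logit, y, lambda = 1) {
  sigmoid(logit) * (1 + (lambda - 1) * y) - lambda * y
}

#' Subject-grouped fold assignment
#'
#' Greedy largest-subject-first assignment: subjects (whole, never split) are
#' ordered by window count and each is placed into the currently smallest
#' fold, so folds are approximately balanced by window count and no subject
#' ever appears in two folds. Ties in subject size are broken by a seeded
#' shuffle.
#'
#' @param subject_ids Vector of per-window subject identifiers.
#' @param k Number of folds.
#' @param seed Seed for tie-breaking.
#' @return Integer vector of fold labels (1..k) aligned with `subject_ids`.
#' @export
grouped_folds <- function(subject_ids, k, seed = 1) {
  subjects <- unique(subject_ids)
  if (length(subjects) < k) {
    stop("need at least k = ", k, " distinct subjects", call. = FALSE)
  }
  counts <- table(subject_ids)[as.character(subjects)]
  ord <- with_local_seed(derive_seed(seed, "folds"), {
    subjects[order(-as.numeric(counts), stats::runif(length(subjects)))]
  })
  fold_of <- stats::setNames(integer(length(subjects)), ord)
  load <- numeric(k)
  for (s in ord) {
    f <- which.min(load)
    fold_of[s] <- f
    load[f] <- load[f] + sum(subject_ids == s)
  }
  unname(fold_of[as.character(subject_ids)])
}

#' F1-optimal decision-threshold calibration
#'
#' Scans candidate thresholds (midpoints of consecutive sorted unique scores
#' plus the endpoints 0 and 1 for probability scores, or range-spanning
#' endpoints otherwise), computes the exact confusion counts per threshold
#' under the strict decision rule `predict positive iff score > tau`, and
#' selects the smallest threshold attaining the maximum F1.
#'
#' @param scores Numeric scores (probabilities or any monotone score).
#' @param labels 0/1 labels; both classes must be present.
#' @return An object of class `qt_calibration`: a list with the threshold
#'   `curve` tibble (`tau, tp, fp, fn, tn, f1`), `tau_star`, `max_f1`, and
#'   class priors `pi0`, `pi1`.
#' @examples
#' cal <- calibrate_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' cal$max_f1 # 0.8
#' @export
calibrate_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to calibrate F1", call. = FALSE)
  }
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  ends <- if (all(scores >= 0 & scores <= 1)) {
    c(0, 1)
  } else {
    c(min(scores) - 1, max(scores) + 1)
  }
  # a score exactly at the low endpoint would make the all-positive rule
  # unreachable; complete the candidate set below the smallest score
  if (min(scores) <= ends[1]) ends <- c(min(scores) - 1, ends)
  taus <- sort(unique(c(ends, mids)))
  curve <- purrr::map_dfr(taus, function(tau) {
    dplyr::bind_cols(tibble::tibble(tau = tau),
                     binary_metrics(as.integer(scores > tau), labels))
  })
  max_f1 <- max(curve$f1)
  tau_star <- min(curve$tau[curve$f1 >= max_f1 - 1e-15])
  structure(
    list(curve = curve[, c("tau", "tp", "fp", "fn", "tn", "f1")],
         tau_star = tau_star, max_f1 = max_f1,
         pi1 = mean(labels), pi0 = 1 - mean(labels)),
    class = "qt_calibration"
  )
}

#' @export
print.qt_calibration <- function(x, ...) {
  cat("<qt_calibration>", nrow(x$curve), "candidate thresholds\n")
  cat("  tau* =", format(x$tau_star, digits = 6),
      " max F1 =", format(x$max_f1, digits = 6),
      " priors (pi0, pi1) = (", format(x$pi0, digits = 3), ",",
      format(x$pi1, digits = 3), ")\n")
  invisible(x)
}

#' @export
tidy.qt_calibration <- function(x, ...) x$curve

#' @export
autoplot.qt_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$tau, y = .data$f1)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$tau_star, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::labs(x = expression(tau), y = "F1",
                  title = "Validation F1 threshold calibration",
                  subtitle = sprintf("tau* = %.4f, max F1 = %.4f",
                                     object$tau_star, object$max_f1)) +
    ggplot2::theme_minimal()
}

# ---- effective-chain optimizer -------------------------------------------

# Batched forward over the effective chain. X: n x D matrix (rows = windows).
# Returns list(logit, s_stage [n x nlayer], a) where a is the pre-tanh affine.
chain_forward <- function(X, w, b0, blocks) {
  a <- as.numeric(X %*% w) + b0
  s <- tanh(a)
  s_stage <- matrix(0, nrow = length(s), ncol = length(blocks))
  for (k in seq_along(blocks)) {
    s_stage[, k] <- s
    s <- qt_forward(s, blocks[[k]])
  }
  list(logit = s, s_stage = s_stage, a = a)
}

# Batched gradient of the mean weighted loss over the effective chain.
chain_grad <- function(X, y, w, b0, blocks, lambda) {
  fw <- chain_forward(X, w, b0, blocks)
  n <- nrow(X)
  dL <- weighted_bce_grad(fw$logit, y, lambda)
  nlayer <- length(blocks)
  gin <- vapply(seq_len(nlayer), function(k) {
    qt_input_grad(fw$s_stage[, k], blocks[[k]])
  }, numeric(n))
  gin <- matrix(gin, nrow = n)
  upstream <- matrix(0, nrow = n, ncol = nlayer)
  acc <- dL
  for (k in rev(seq_len(nlayer))) {
    upstream[, k] <- acc
    acc <- acc * gin[, k]
  }
  grad_theta <- lapply(seq_len(nlayer), function(k) {
    blk <- blocks[[k]]
    vapply(seq_len(blk$p), function(j) {
      mean(upstream[, k] * qt_parameter_shift(fw$s_stage[, k], blk, j))
    }, numeric(1))
  })
  coef <- acc * (1 - tanh(fw$a)^2)
  list(
    loss = mean(weighted_bce(fw$logit, y, lambda)),
    grad_w = as.numeric(crossprod(X, coef)) / n,
    grad_b0 = mean(coef),
    grad_theta = grad_theta,
    logit = fw$logit,
    mean_abs_z = mean(abs(fw$logit))
  )
}

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0)

adam_step <- function(state, grad, cfg) {
  state$t <- state$t + 1
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mhat <- state$m / (1 - cfg$beta1^state$t)
  vhat <- state$v / (1 - cfg$beta2^state$t)
  state$delta <- cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
  state
}

# Fit the effective chain, re-initializing (deterministically) when an
# unlucky draw leaves the chain pinched off: a run whose training F1 never
# beats the trivial one-class baseline has a dead discrimination gradient
# and is restarted from the next derived seed. Uses training data only.
fit_chain <- function(X, y, stack, cfg, init_seed, shuffle_seed,
                      lambda, X_val = NULL, y_val = NULL) {
  baseline_f1 <- 2 * mean(y) / (1 + mean(y))  # predict-all-positive
  fit <- NULL
  for (attempt in seq_len(cfg$max_restarts + 1)) {
    fit <- fit_chain_once(X, y, stack, cfg, init_seed, shuffle_seed, lambda,
                          X_val, y_val)
    fit$attempt <- attempt
    if (max(fit$epochs$train_f1) > baseline_f1 + 0.02) break
    init_seed <- derive_seed(init_seed, paste0("restart", attempt))
    shuffle_seed <- derive_seed(shuffle_seed, paste0("restart", attempt))
  }
  fit
}

# One optimization run; deterministic given seeds. When a validation split
# is supplied and cfg$select_best_epoch is TRUE, the parameters of the epoch
# with the highest validation max-F1 are returned (epoch-level early
# stopping, ties to the earlier epoch).
fit_chain_once <- function(X, y, stack, cfg, init_seed, shuffle_seed,
                           lambda, X_val = NULL, y_val = NULL) {
  D <- ncol(X)
  with_local_seed(init_seed, {
    w <- stats::runif(D, -0.05, 0.05)
    b0 <- 0
    blocks <- lapply(seq_along(stack$widths), function(l) {
      random_qt_params(stack$p, phi = stack$phi)
    })
  })
  chain_len <- length(effective_chain(stack))
  blocks <- blocks[seq_len(chain_len)]
  np <- D + 1 + chain_len * stack$p
  st <- adam_new(np)
  logs <- vector("list", cfg$epochs)
  best <- NULL
  n <- nrow(X)
  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- with_local_seed(derive_seed(shuffle_seed, epoch), sample.int(n))
    losses <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      g <- chain_grad(X[idx, , drop = FALSE], y[idx], w, b0, blocks, lambda)
      gvec <- c(g$grad_w, g$grad_b0, unlist(g$grad_theta))
      st <- adam_step(st, gvec, cfg)
      w <- w - st$delta[seq_len(D)]
      b0 <- b0 - st$delta[D + 1]
      off <- D + 1
      for (k in seq_len(chain_len)) {
        th <- blocks[[k]]$theta - st$delta[off + seq_len(stack$p)]
        # gain budget: rotation scalings are projected back into the
        # off-saturation range so |kappa_j s| stays below ~pi/2 and the
        # transfer never locks onto a zero-slope plateau
        th <- pmin(pmax(th, cfg$theta_range[1]), cfg$theta_range[2])
        blocks[[k]] <- qt_params(th, phi = stack$phi)
        off <- off + stack$p
      }
      losses <- c(losses, g$loss)
    }
    fw <- chain_forward(X, w, b0, blocks)
    prob <- sigmoid(fw$logit)
    m <- binary_metrics(as.integer(prob > 0.5), y)
    val_f1 <- NA_real_
    if (!is.null(X_val) && length(unique(y_val)) > 1) {
      vp <- sigmoid(chain_forward(X_val, w, b0, blocks)$logit)
      val_f1 <- calibrate_threshold(vp, y_val)$max_f1
      if (is.null(best) || val_f1 > best$val_f1 + 1e-12) {
        best <- list(w = w, b0 = b0, blocks = blocks, val_f1 = val_f1,
                     epoch = epoch)
      }
    }
    logs[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = mean(losses),
      train_accuracy = m$accuracy, train_f1 = m$f1, val_f1 = val_f1,
      mean_abs_z = mean(abs(cbind(fw$s_stage[, -1, drop = FALSE], fw$logit))),
      wall_time = proc.time()[["elapsed"]] - t0
    )
    if (!is.finite(mean(losses))) {
      stop("training diverged: non-finite loss at epoch ", epoch,
           call. = FALSE)
    }
  }
  out <- list(w = w, b0 = b0, blocks = blocks, best_epoch = cfg$epochs,
              epochs = dplyr::bind_rows(logs))
  if (isTRUE(cfg$select_best_epoch) && !is.null(best)) {
    out$w <- best$w
    out$b0 <- best$b0
    out$blocks <- best$blocks
    out$best_epoch <- best$epoch
  }
  out
}

chain_prob <- function(X, fit) {
  sigmoid(chain_forward(X, fit$w, fit$b0, fit$blocks)$logit)
}

#' Train the hybrid stack under subject-grouped cross-validation
#'
#' For each of `cfg$folds` grouped folds: one held-out subject group inside
#' the training portion serves as the validation split; the effective chain
#' (on-path contraction row plus one block per layer — the only parameters
#' that carry gradient under the index-preserving single-head wiring) is fit
#' with Adam on the remaining training subjects; the decision threshold is
#' calibrated on the validation probabilities to maximize F1 and carried
#' unchanged to the test fold. Fully deterministic given `cfg$seed`.
#'
#' @param data A tibble with columns `grid` (list of 40x12 integer
#'   matrices), `label` (0/1) and `subject_id` — e.g. from
#'   [build_gait_dataset()].
#' @param stack A [stack_config()]; its blocks are re-initialized per fold
#'   from the seeded substream.
#' @param cfg A [train_config()].
#' @return An object of class `qt_eval`: per-fold metrics (`folds`),
#'   per-epoch logs (`epochs`), the resolved configuration, and fitted
#'   per-fold parameters.
#' @export
qt_train <- function(data, stack = stack_config(), cfg = train_config()) {
  stopifnot(all(c("grid", "label", "subject_id") %in% names(data)))
  X <- flatten_windows(data$grid)
  y <- as.integer(data$label)
  fold <- grouped_folds(data$subject_id, cfg$folds, seed = cfg$seed)
  fold_rows <- vector("list", cfg$folds)
  epoch_rows <- vector("list", cfg$folds)
  fits <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    test_idx <- which(fold == f)
    trainval_idx <- which(fold != f)
    subj <- unique(data$subject_id[trainval_idx])
    val_subj <- with_local_seed(derive_seed(cfg$seed, paste0("val", f)),
                                sample(subj, 1))
    val_idx <- trainval_idx[data$subject_id[trainval_idx] == val_subj]
    tr_idx <- setdiff(trainval_idx, val_idx)
    lambda <- if (identical(cfg$pos_weight, "auto")) {
      sum(y[tr_idx] == 0) / max(1, sum(y[tr_idx] == 1))
    } else {
      cfg$pos_weight
    }
    fit <- fit_chain(X[tr_idx, , drop = FALSE], y[tr_idx], stack, cfg,
                     init_seed = derive_seed(cfg$seed, paste0("init", f)),
                     shuffle_seed = derive_seed(cfg$seed, paste0("shuf", f)),
                     lambda = lambda,
                     X_val = X[val_idx, , drop = FALSE], y_val = y[val_idx])
    cal <- calibrate_threshold(chain_prob(X[val_idx, , drop = FALSE], fit),
                               y[val_idx])
    test_prob <- chain_prob(X[test_idx, , drop = FALSE], fit)
    m <- binary_metrics(as.integer(test_prob > cal$tau_star), y[test_idx])
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, lambda = lambda, tau = cal$tau_star,
                     val_f1 = cal$max_f1, n_test = length(test_idx)), m)
    epoch_rows[[f]] <- dplyr::mutate(fit$epochs, fold = f, .before = 1)
    fits[[f]] <- fit
  }
  structure(
    list(folds = dplyr::bind_rows(fold_rows),
         epochs = dplyr::bind_rows(epoch_rows),
         config = cfg, stack = stack, fits = fits),
    class = "qt_eval"
  )
}

#' @export
print.qt_eval <- function(x, ...) {
  cat("<qt_eval>", nrow(x$folds), "grouped folds\n")
  cat(sprintf("  mean test accuracy %.4f, mean test F1 %.4f\n",
              mean(x$folds$accuracy), mean(x$folds$f1)))
  invisible(x)
}

#' @export
tidy.qt_eval <- function(x, ...) x$folds

#' @export
glance.qt_eval <- function(x, ...) {
  agg <- binary_metrics(
    rep(c(1, 0, 0, 1), c(sum(x$folds$tp), sum(x$folds$fp), sum(x$folds$tn),
                         sum(x$folds$fn))),
    rep(c(1, 0, 0, 0), c(sum(x$folds$tp), sum(x$folds$fp), sum(x$folds$tn),
                         sum(x$folds$fn))))
  tibble::tibble(
    folds = nrow(x$folds),
    mean_accuracy = mean(x$folds$accuracy),
    sd_accuracy = stats::sd(x$folds$accuracy),
    mean_f1 = mean(x$folds$f1),
    sd_f1 = stats::sd(x$folds$f1),
    micro_precision = agg$precision,
    micro_recall = agg$recall,
    micro_f1 = agg$f1
  )
}

#' @export
autoplot.qt_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$epochs,
    c("loss", "train_accuracy", "train_f1", "mean_abs_z"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(colour = "fold", title = "Training dynamics per fold") +
    ggplot2::theme_minimal()
}

#' Seeded grid search over learning rate and re-upload count
#'
#' A deterministic stand-in for bandit-style hyperparameter search: every
#' `(lr, p)` candidate is trained on the first grouped fold and scored by its
#' best validation F1 across epochs; ties prefer smaller `p`, then smaller
#' `lr`.
#'
#' @param data Dataset tibble as in [qt_train()].
#' @param grid A tibble with columns `lr` and `p`.
#' @param cfg Base [train_config()]; `lr` is overridden per trial.
#' @param widths Stack layout for the trials.
#' @return A list with `best` (one-row tibble) and `trials` (the full search
#'   log, mirroring per-trial best validation F1).
#' @export
qt_hyper_search <- function(data, grid, cfg = train_config(), widths = c(4, 3, 2)) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  stopifnot(all(c("lr", "p") %in% names(grid)))
  X <- flatten_windows(data$grid)
  y <- as.integer(data$label)
  fold <- grouped_folds(data$subject_id, cfg$folds, seed = cfg$seed)
  trainval_idx <- which(fold != 1)
  subj <- unique(data$subject_id[trainval_idx])
  val_subj <- with_local_seed(derive_seed(cfg$seed, "val1"), sample(subj, 1))
  val_idx <- trainval_idx[data$subject_id[trainval_idx] == val_subj]
  tr_idx <- setdiff(trainval_idx, val_idx)
  lambda <- sum(y[tr_idx] == 0) / max(1, sum(y[tr_idx] == 1))
  trials <- purrr::pmap_dfr(grid, function(lr, p, ...) {
    cfg_t <- cfg
    cfg_t$lr <- lr
    stack <- with_local_seed(derive_seed(cfg$seed, paste0("hs", lr, p)),
                             stack_config(widths, p = p))
    fit <- fit_chain(X[tr_idx, , drop = FALSE], y[tr_idx], stack, cfg_t,
                     init_seed = derive_seed(cfg$seed, paste0("hsi", lr, p)),
                     shuffle_seed = derive_seed(cfg$seed, paste0("hss", lr, p)),
                     lambda = lambda,
                     X_val = X[val_idx, , drop = FALSE], y_val = y[val_idx])
    val_prob <- chain_prob(X[val_idx, , drop = FALSE], fit)
    best_val_f1 <- if (length(unique(y[val_idx])) > 1) {
      calibrate_threshold(val_prob, y[val_idx])$max_f1
    } else {
      NA_real_
    }
    tibble::tibble(lr = lr, p = p, best_val_f1 = best_val_f1,
                   best_epoch = fit$best_epoch)
  })
  ranked <- dplyr::arrange(trials, dplyr::desc(.data$best_val_f1), .data$p,
                           .data$lr)
  list(best = ranked[1, ], trials = trials)
}
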