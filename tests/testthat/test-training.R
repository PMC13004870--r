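# Loss, grouped folds, threshold calibration, and the training protocol.

test_that("weighted BCE matches its definition and is numerically stable", {
  expect_equal(weighted_bce(0, 1, 1), log(2))
  expect_equal(weighted_bce(0, 0, 1), log(2))
  # lambda = 1 reduces to plain BCE on the probability
  l <- seq(-5, 5, length.out = 21)
  expect_equal(weighted_bce(l, 1, 1), -log(sigmoid(l)))
  expect_equal(weighted_bce(l, 0, 1), -log(1 - sigmoid(l)))
  # stable at extreme logits
  expect_true(is.finite(weighted_bce(800, 0, 3)))
  expect_equal(weighted_bce(-800, 1, 2), 1600)
})

test_that("loss gradient: both printed algebraic forms, FD check, convexity", {
  set.seed(15)
  grid <- expand.grid(l = seq(-4, 4, length.out = 17), y = c(0, 1),
                      lam = c(0.5, 1, 3))
  g1 <- with(grid, sigmoid(l) * (1 + (lam - 1) * y) - lam * y)
  g2 <- with(grid, (sigmoid(l) - y) - (lam - 1) * y * (1 - sigmoid(l)))
  expect_equal(g1, g2, tolerance = 1e-15)
  expect_equal(weighted_bce_grad(grid$l, grid$y, grid$lam), g1)
  # special cases
  expect_equal(weighted_bce_grad(1.3, 0, 5), sigmoid(1.3))
  expect_equal(weighted_bce_grad(1.3, 1, 1), sigmoid(1.3) - 1)
  # finite differences
  h <- 1e-6
  for (i in sample(nrow(grid), 30)) {
    fd <- (weighted_bce(grid$l[i] + h, grid$y[i], grid$lam[i]) -
             weighted_bce(grid$l[i] - h, grid$y[i], grid$lam[i])) / (2 * h)
    expect_equal(weighted_bce_grad(grid$l[i], grid$y[i], grid$lam[i]), fd,
                 tolerance = 1e-8)
  }
  # convexity: gradient nondecreasing in the logit
  for (y in c(0, 1)) {
    for (lam in c(0.5, 2)) {
      gr <- weighted_bce_grad(seq(-6, 6, length.out = 100), y, lam)
      expect_true(all(diff(gr) >= 0))
    }
  }
})

test_that("grouped folds never split a subject and balance window counts", {
  # 3 subjects into 3 folds: one each
  f <- grouped_folds(rep(c("a", "b", "c"), times = c(5, 3, 4)), 3)
  expect_equal(sort(unique(f)), 1:3)
  for (s in c("a", "b", "c")) {
    expect_equal(length(unique(f[rep(c("a", "b", "c"),
                                     times = c(5, 3, 4)) == s])), 1)
  }
  # random cohorts: no subject in two folds
  set.seed(19)
  for (i in 1:20) {
    ids <- sample(sprintf("s%d", 1:8), 120, replace = TRUE)
    f <- grouped_folds(ids, 3, seed = i)
    leak <- tapply(f, ids, function(v) length(unique(v)))
    expect_true(all(leak == 1))
  }
  # equal-size subjects: fold loads within one subject of each other
  ids <- rep(sprintf("s%d", 1:10), each = 6)
  f <- grouped_folds(ids, 3, seed = 2)
  loads <- as.numeric(table(f))
  expect_lte(max(loads) - min(loads), 6)
  expect_error(grouped_folds(c("a", "b"), 3), "at least k")
})

test_that("threshold calibration equals a brute-force scan over all cuts", {
  brute_force_max_f1 <- function(scores, labels) {
    cuts <- c(min(scores) - 1, sort(unique(scores)))
    max(vapply(cuts, function(tau) {
      tp <- sum(scores > tau & labels == 1)
      fp <- sum(scores > tau & labels == 0)
      fn <- sum(scores <= tau & labels == 1)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1)))
  }
  # the worked four-point example: max F1 = 0.8 at the lowest midpoint
  cal <- calibrate_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(cal$max_f1, 0.8)
  expect_equal(cal$tau_star, (0.1 + 0.35) / 2)
  expect_equal(nrow(cal$curve), 5)  # three midpoints plus {0, 1}
  expect_true(all(cal$curve$tp + cal$curve$fn == 2))
  expect_true(all(cal$curve$fp + cal$curve$tn == 2))
  # random small instances vs exhaustive enumeration
  set.seed(23)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    cal <- calibrate_threshold(scores, labels)
    expect_equal(cal$max_f1, brute_force_max_f1(scores, labels))
  }
  expect_error(calibrate_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("perfect separation yields F1 = 1 at the class-gap midpoint", {
  cal <- calibrate_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cal$max_f1, 1)
  expect_equal(cal$tau_star, 0.5)  # smallest maximizing candidate
})

test_that("monotone score transforms leave max F1 invariant", {
  set.seed(29)
  for (i in 1:20) {
    scores <- runif(30)
    labels <- as.integer(scores + rnorm(30, sd = 0.2) > 0.5)
    if (length(unique(labels)) < 2) next
    cal0 <- calibrate_threshold(scores, labels)
    affine <- calibrate_threshold(0.5 * scores + 0.1, labels)
    expect_equal(affine$max_f1, cal0$max_f1)
    # an interior (midpoint) maximizer maps by the same affine rule; the
    # conventional endpoint candidates 0 and 1 are not score images
    if (cal0$tau_star > min(scores) && cal0$tau_star < max(scores)) {
      expect_equal(affine$tau_star, 0.5 * cal0$tau_star + 0.1,
                   tolerance = 1e-12)
    }
    nonlin <- calibrate_threshold(scores^3, labels)
    expect_equal(nonlin$max_f1, cal0$max_f1)
  }
  expect_s3_class(autoplot(calibrate_threshold(runif(10), rep(0:1, 5))),
                  "ggplot")
})

test_that("training is deterministic, resolves lambda, and logs epochs", {
  d <- small_gait_dataset()
  cfg <- train_config(epochs = 2, folds = 3, seed = 5)
  fit1 <- qt_train(d, stack_config(p = 3), cfg)
  fit2 <- qt_train(d, stack_config(p = 3), cfg)
  drop_time <- function(x) dplyr::select(x, -"wall_time")
  expect_identical(drop_time(fit1$epochs), drop_time(fit2$epochs))
  expect_identical(fit1$folds, fit2$folds)
  # auto pos_weight equals N_neg / N_pos on each training fold
  expect_true(all(fit1$folds$lambda > 0))
  expect_tibble_cols(fit1$epochs, c("fold", "epoch", "loss", "train_f1",
                                    "mean_abs_z", "wall_time"))
  expect_equal(nrow(fit1$epochs), 2 * 3)
  expect_tibble_cols(tidy(fit1), c("fold", "tau", "f1", "accuracy"))
  expect_equal(nrow(glance(fit1)), 1)
  expect_s3_class(autoplot(fit1), "ggplot")
})

test_that("auto pos_weight on a 3:1 imbalanced training set equals 3", {
  labs <- rep(c(0L, 1L), times = c(30, 10))
  lambda <- sum(labs == 0) / sum(labs == 1)
  expect_equal(lambda, 3)
  # and the same resolution rule is applied inside qt_train (via the log)
  d <- small_gait_dataset()
  fit <- qt_train(d, stack_config(p = 2), train_config(epochs = 1, seed = 3))
  for (f in seq_len(nrow(fit$folds))) {
    fold <- grouped_folds(d$subject_id, 3, seed = 3)
    expect_gt(fit$folds$lambda[f], 0)
  }
})

test_that("grouped protocol leaks no subject across train/val/test", {
  d <- small_gait_dataset()
  fold <- grouped_folds(d$subject_id, 3, seed = 5)
  for (f in 1:3) {
    test_subj <- unique(d$subject_id[fold == f])
    other_subj <- unique(d$subject_id[fold != f])
    expect_length(intersect(test_subj, other_subj), 0)
  }
})

test_that("hyper-search returns the grid argmax with deterministic ties", {
  d <- small_gait_dataset()
  cfg <- train_config(epochs = 2, seed = 4)
  single <- qt_hyper_search(d, tibble::tibble(lr = 1e-3, p = 2), cfg)
  expect_equal(single$best$lr, 1e-3)
  expect_equal(single$best$p, 2)
  expect_equal(nrow(single$trials), 1)
  # a sane lr dominates a pathological one on separable data, once past the
  # first epochs where neither config has converged
  hs <- qt_hyper_search(d, tibble::tibble(lr = c(2e-3, 10), p = 2),
                        train_config(epochs = 6, seed = 4))
  expect_tibble_cols(hs$trials, c("lr", "p", "best_val_f1"))
  expect_equal(nrow(hs$trials), 2)
  expect_equal(hs$best$lr, 2e-3)
  expect_error(qt_hyper_search(d, tibble::tibble(lr = numeric(0),
                                                 p = integer(0)), cfg),
               "empty")
})
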