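# Contraction front-end, template/effective equivalence, network gradients,
# and resource accounting.

test_that("contraction is tanh(Wx + b), bounded, and shape-checked", {
  ct <- contraction_params(matrix(0, 8, 10))
  expect_equal(qt_contract(runif(10), ct), rep(0, 8))
  set.seed(2)
  W <- matrix(rnorm(8 * 10), 8)
  b <- rnorm(8)
  x <- rnorm(10)
  h <- qt_contract(x, contraction_params(W, b))
  expect_equal(h, as.numeric(tanh(W %*% x + b)))
  expect_true(all(abs(h) < 1))
  # saturation under row scaling
  expect_equal(abs(qt_contract(x, contraction_params(W * 1e6, b))),
               rep(1, 8), tolerance = 1e-12)
  expect_error(qt_contract(rnorm(9), contraction_params(W, b)), "length D")
  # batch form agrees with per-column evaluation
  X <- matrix(rnorm(30), nrow = 10)
  H <- qt_contract(X, contraction_params(W, b))
  expect_equal(H[, 2], qt_contract(X[, 2], contraction_params(W, b)))
})

test_that("template logit equals the effective chain bitwise", {
  set.seed(3)
  for (i in 1:25) {
    D <- 24
    ct <- contraction_params(matrix(runif(8 * D, -0.5, 0.5), 8), rnorm(8, sd = 0.1))
    st <- stack_config(c(4, 3, 2), p = sample(2:5, 1))
    x <- runif(D)
    act <- qt_forward_template(x, ct, st)
    expect_identical(act$logit, qt_forward_effective(x, ct, st))
    expect_identical(act$prob, sigmoid(act$logit))
    expect_true(all(abs(unlist(act$z)) <= 1))
  }
})

test_that("theta = 0 blocks propagate the midpoint cos(phi)", {
  blocks <- lapply(c(4, 3, 2), function(w) {
    lapply(seq_len(w), function(i) qt_params(rep(1e-30, 5), pi / 3))
  })
  st <- stack_config(c(4, 3, 2), p = 5, blocks = blocks)
  ct <- contraction_params(matrix(0.01, 8, 12))
  act <- qt_forward_template(runif(12), ct, st)
  expect_equal(unlist(act$z), rep(0.5, 9), tolerance = 1e-12)
  expect_equal(act$logit, 0.5, tolerance = 1e-12)
})

test_that("perturbing any off-path block leaves the logit bitwise unchanged", {
  set.seed(8)
  D <- 24
  ct <- contraction_params(matrix(runif(8 * D, -0.3, 0.3), 8))
  st <- stack_config(c(4, 3, 2), p = 3)
  x <- runif(D)
  base <- qt_forward_template(x, ct, st)$logit
  off_path <- list(c(1, 1), c(1, 3), c(1, 4), c(2, 1), c(2, 3), c(3, 1))
  for (bi in off_path) {
    st2 <- st
    st2$blocks[[bi[1]]][[bi[2]]] <- random_qt_params(3)
    expect_identical(qt_forward_template(x, ct, st2)$logit, base)
  }
})

test_that("network gradient matches finite differences; off-path exactly zero", {
  set.seed(12)
  D <- 24
  ct <- contraction_params(matrix(runif(8 * D, -0.3, 0.3), 8), rnorm(8, sd = 0.05))
  st <- stack_config(c(4, 3, 2), p = 4)
  x <- runif(D)
  g <- qt_network_grad(x, 1, ct, st, lambda = 2.5)
  loss_of <- function(ct2, st2) {
    weighted_bce(qt_forward_effective(x, ct2, st2), 1, 2.5)
  }
  expect_equal(g$loss, loss_of(ct, st))
  # off-path gradients are identically zero
  expect_true(all(g$grad_W[-2, ] == 0))
  expect_true(all(g$grad_b[-2] == 0))
  for (l in 1:3) expect_true(all(g$grad_theta[[l]][, -2] == 0))
  # the third derivative through the composed trig chain is large, so the
  # central-difference oracle uses a small step
  h <- 1e-6
  for (col in c(1, 7, 20)) {
    Wp <- ct$W; Wp[2, col] <- Wp[2, col] + h
    Wm <- ct$W; Wm[2, col] <- Wm[2, col] - h
    fd <- (loss_of(contraction_params(Wp, ct$b), st) -
             loss_of(contraction_params(Wm, ct$b), st)) / (2 * h)
    expect_equal(g$grad_W[2, col], fd, tolerance = 1e-6)
  }
  perturb <- function(l, j, d) {
    st2 <- st
    th <- st2$blocks[[l]][[2]]$theta
    th[j] <- th[j] + d
    st2$blocks[[l]][[2]] <- qt_params(th, st$phi)
    st2
  }
  for (l in 1:3) {
    for (j in c(1, 4)) {
      fd <- (loss_of(ct, perturb(l, j, h)) - loss_of(ct, perturb(l, j, -h))) /
        (2 * h)
      expect_equal(g$grad_theta[[l]][j, 2], fd, tolerance = 1e-6)
    }
  }
})

test_that("theta gradients vanish when a stage input is zero", {
  # zero contraction row => s^(1) = 0 => layer-1 shift prefactor pi * s = 0
  D <- 12
  ct <- contraction_params(matrix(0, 8, D))
  st <- stack_config(c(4, 3, 2), p = 3)
  g <- qt_network_grad(runif(D), 0, ct, st)
  expect_true(all(g$grad_theta[[1]] == 0))
})

test_that("chain Jacobian product respects the gain-budget bound", {
  set.seed(14)
  for (i in 1:20) {
    st <- stack_config(c(4, 3, 2), p = 3)
    chain_blocks <- lapply(1:3, function(l) st$blocks[[l]][[2]])
    s1 <- runif(1, -1, 1)
    # d logit / d s^(1) along the chain
    s <- s1
    dchain <- 1
    for (blk in chain_blocks) {
      dchain <- dchain * qt_transconductance(s, blk)
      s <- qt_forward(s, blk)
    }
    bound <- prod(vapply(chain_blocks, qt_slope_bound, numeric(1)))
    expect_lte(abs(dchain), bound)
  }
})

test_that("resource accounting reproduces the printed layout counts", {
  b432 <- qt_resource_budget(stack_config(c(4, 3, 2), p = 5))
  expect_equal(b432$two_qubit_gates_per_forward, 18L)
  expect_equal(b432$max_concurrent_qubits, 8L)
  expect_equal(b432$shifted_circuits_per_step, 90L)
  expect_equal(b432$data_rotations_per_block, 9L)
  expect_equal(b432$declared_params, 3893L)
  expect_equal(b432$effective_params, 496L)
  expect_equal(b432$shots_per_update_factor, 91L)

  b8421 <- qt_resource_budget(stack_config(c(8, 4, 2, 1), p = 5))
  expect_equal(b8421$two_qubit_gates_per_forward, 30L)
  expect_equal(b8421$max_concurrent_qubits, 16L)

  b21 <- qt_resource_budget(stack_config(c(2, 1), p = 5))
  expect_equal(b21$two_qubit_gates_per_forward, 6L)
  expect_equal(b21$max_concurrent_qubits, 4L)
  expect_equal(b21$n_blocks, 3L)

  # compiled-away bias needs no two-qubit gates; p = 2 rotation count is p
  expect_equal(qt_resource_budget(stack_config(c(4, 3, 2), p = 5),
                                  mode = "compiled_away")$two_qubit_gates_per_forward,
               0L)
  expect_equal(qt_resource_budget(stack_config(c(4, 3, 2), p = 2))$data_rotations_per_block,
               2L)
})

test_that("baseline parameter counts match the reference models", {
  counts <- baseline_param_counts(480)
  expect_equal(counts$logistic, 481L)
  expect_equal(counts$mlp, 3857L)
  tiny <- baseline_param_counts(1, hidden = 1)
  expect_equal(tiny$logistic, 2L)
  expect_equal(tiny$mlp, 4L)
})

test_that("stack JSON serialization round-trips and validates its schema", {
  set.seed(6)
  ct <- random_contraction(12)
  st <- stack_config(c(4, 3, 2), p = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_stack_json(ct, st, path)
  back <- read_stack_json(path)
  x <- runif(12)
  expect_identical(qt_forward_effective(x, back$contraction, back$stack),
                   qt_forward_effective(x, ct, st))
  expect_equal(back$stack$widths, st$widths)
  # corrupted schema string is rejected
  doc <- jsonlite::read_json(path)
  doc$schema <- "qtstack/stack/v999"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_stack_json(path), "schema")
})
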