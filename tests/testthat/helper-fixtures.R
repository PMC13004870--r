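# Shared fixtures: all randomness is seeded so every run is reproducible.

random_block_cases <- function(n, p_range = 2:7, phi_range = c(-pi, pi),
                               seed = 1) {
  withr_seed <- function(code) qtstack:::with_local_seed(seed, code)
  withr_seed(lapply(seq_len(n), function(i) {
    p <- sample(p_range, 1)
    list(
      params = qt_params(runif(p, 0.05, 1), phi = runif(1, phi_range[1],
                                                        phi_range[2])),
      s = runif(1, -1, 1)
    )
  }))
}

# small deterministic dataset reused by training tests (built once per run)
small_gait_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_gait_dataset(n_subjects = 4, windows_per_subject = 16,
                                   seed = 11)
    }
    cache
  }
})

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
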