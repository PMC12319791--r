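test_that("run splits enumerate every train/test partition exactly once", {
  s53 <- enumerate_run_splits(5, 3)
  expect_length(s53, 10L)          # the study's 10 combinations
  expect_length(enumerate_run_splits(3, 2), 3L)
  # brute-force subset oracle: all 3-subsets of 1..5, no duplicates
  keys <- vapply(s53, function(sp) paste(sp$train, collapse = ","), "")
  oracle <- apply(combn(5, 3), 2, paste, collapse = ",")
  expect_identical(keys, oracle)
  for (sp in s53) {
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), 1:5)
  }
  expect_error(enumerate_run_splits(5, 5), "n_train")
})

test_that("fit_linear_map matches the normal-equations oracle and recovers exact maps", {
  set.seed(21)
  # exact identifiability with orthonormal demeaned predictors
  n <- 60L
  X <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  X <- sweep(X, 2, colMeans(X))
  B <- matrix(rnorm(8), 4, 2)
  Y <- X %*% B
  expect_equal(unname(fit_linear_map(X, Y)), B, tolerance = 1e-10,
               ignore_attr = TRUE)

  # random instances against (X'X)^-1 X'Y, p,q <= 10, time <= 200
  for (rep in 1:20) {
    p <- sample(2:10, 1); q <- sample(1:10, 1); n <- sample((p + 5):200, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    expect_equal(unname(fit_linear_map(X, Y)), unname(ne_solve(X, Y)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # betas shrink toward zero for pure-noise targets
  n <- 4000L
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(rnorm(n), n, 1)
  se_bound <- 3 / sqrt(n)
  expect_lt(max(abs(fit_linear_map(X, Y))), 3 * se_bound * 3)
  expect_error(fit_linear_map(matrix(1, 2, 5), matrix(1, 2, 1)), "timepoints")
})

test_that("noiseless encoding achieves perfect test correlations and decode/encode agree", {
  spec <- small_spec(snr = Inf, participant_gain_sd = 0,
                     participant_beta_sd = 0, drift_amplitude = 0,
                     motion_weight = 0, baseline = 0)
  sim <- quick_study(spec)
  enc <- between_run_cv(sim$dataset, sim$designs$perceived, "encode",
                        n_train = 2)
  nz <- rowSums(sim$truth$beta != 0) > 0      # ROIs carrying signal
  expect_true(all(abs(enc$fit[, nz] - 1) < 1e-6))
  dec <- between_run_cv(sim$dataset, sim$designs$perceived, "decode",
                        n_train = 2)
  # identifiable emotions (non-degenerate regressors) decode perfectly
  act <- vapply(sim$designs$perceived, function(d) apply(d$matrix, 2, sd),
                numeric(length(dec$fit)))
  identifiable <- rowSums(act == 0) == 0
  expect_true(all(abs(dec$fit[identifiable] - 1) < 1e-6))
})

test_that("group statistics are invariant to participant order", {
  spec <- small_spec(snr = 3)
  sim <- quick_study(spec)
  ds <- sim$dataset
  perm <- c(3, 1, 5, 2, 4)
  ds2 <- ds
  ds2$signals <- ds$signals[perm]
  ds2$confounds <- ds$confounds[perm]
  ds2$participants <- ds$participants[perm]
  enc1 <- between_run_cv(ds, sim$designs$felt, "encode", n_train = 2)
  enc2 <- between_run_cv(ds2, sim$designs$felt, "encode", n_train = 2)
  expect_equal(unname(enc1$beta), unname(enc2$beta), tolerance = 1e-12)
  expect_equal(unname(enc1$fit[perm, ]), unname(enc2$fit), tolerance = 1e-12)
})

test_that("three training runs beat one on noisy data, on average", {
  fits <- vapply(1:3, function(seed) {
    spec <- small_spec(n_runs = 4L, snr = 0.5, rng_seed = seed + 100L)
    sim <- quick_study(spec)
    c(mean(between_run_cv(sim$dataset, sim$designs$perceived, "encode",
                          n_train = 1)$fit),
      mean(between_run_cv(sim$dataset, sim$designs$perceived, "encode",
                          n_train = 3)$fit))
  }, numeric(2))
  expect_gte(mean(fits[2, ]), mean(fits[1, ]))
})

test_that("within-run CV partitions participants and is exact in the noiseless limit", {
  spec <- small_spec(n_participants = 6L, snr = Inf,
                     participant_gain_sd = 0, participant_beta_sd = 0,
                     drift_amplitude = 0, motion_weight = 0, baseline = 0)
  sim <- quick_study(spec)
  res <- within_run_cv(sim$dataset, sim$designs$perceived, n_folds = 3,
                       n_train = 2, seed = 5)
  expect_length(res$folds, 6L)
  expect_true(all(table(res$folds) == 2L))   # every participant held out once
  nz <- rowSums(sim$truth$beta != 0) > 0
  expect_true(all(abs(res$fit[, nz] - 1) < 1e-6))
  # 50 participants in 10 folds -> training sets of 45
  fold_of <- rep(seq_len(10L), length.out = 50L)
  expect_true(all(50L - table(fold_of) == 45L))
  expect_error(within_run_cv(sim$dataset, sim$designs$perceived,
                             n_folds = 10), "folds")
})

test_that("felt-vs-perceived contrast is null on identical inputs and detects planted effects", {
  set.seed(33)
  fits <- matrix(rnorm(8 * 12, mean = 0.4, sd = 0.1), 8, 12)
  res0 <- contrast_tasks(fits, fits, n_perm = 100, seed = 2)
  expect_true(all(res0$t == 0))
  expect_true(all(res0$mask == 0))

  # felt advantage planted in ROIs 1-5 of a larger map
  hits <- 0L
  for (seed in 1:5) {
    set.seed(seed * 7)
    n_p <- 16L; n_roi <- 20L
    base <- matrix(rnorm(n_p * n_roi, 0.3, 0.05), n_p, n_roi)
    felt <- base
    felt[, 1:5] <- felt[, 1:5] + 0.25
    res <- contrast_tasks(felt, base, n_perm = 300, seed = seed)
    if (all(res$mask[1:5] == 1)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
  expect_error(contrast_tasks(fits[1, , drop = FALSE],
                              fits[1, , drop = FALSE]), "two participants")
})

test_that("encoding weights are recovered from synthetic data across the SNR ladder", {
  # prediction accuracy decreases monotonically with noise (averaged seeds)
  mean_fit <- function(snr) {
    mean(vapply(1:5, function(seed) {
      spec <- small_spec(snr = snr, rng_seed = seed + 50L)
      sim <- quick_study(spec)
      ds <- condition_dataset(sim$dataset, psc = TRUE, bandpass = FALSE)
      mean(between_run_cv(ds, sim$designs$perceived, "encode",
                          n_train = 2)$fit)
    }, 0))
  }
  fits <- vapply(c(Inf, 5, 1, 0.2), mean_fit, 0)
  expect_true(all(diff(fits) <= 0.01))  # non-increasing up to seed noise
})
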