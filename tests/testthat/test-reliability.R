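test_that("coverage fractions match brute-force scans on randomized panels", {
  set.seed(11)
  nt <- 40L; n_raters <- 10L
  for (rep in 1:5) {
    m <- matrix(pmax(0, rnorm(nt * n_raters)), nt, n_raters)
    m[, sample(n_raters, 3)] <- 0                    # some silent raters
    arr <- make_series_array(list(m))
    g <- grid_from_series(list(perceived = arr))
    # brute-force per-rater / per-timepoint scans
    rc_oracle <- sum(vapply(seq_len(n_raters),
                            function(r) any(m[, r] > 0), TRUE)) / n_raters
    tc_oracle <- sum(vapply(seq_len(nt),
                            function(t) any(m[t, ] > 0), TRUE)) / nt
    expect_equal(rater_coverage(g)["e1", "perceived"], rc_oracle)
    expect_equal(timepoint_coverage(g)["e1", "perceived"], tc_oracle)
  }
  # direct fraction example: 2 of 4 raters non-zero
  m <- cbind(c(1, 0, 2), 0, c(0, 1, 0), 0)
  g <- grid_from_series(list(felt = make_series_array(list(m))))
  expect_equal(rater_coverage(g)["e1", "felt"], 0.5)
  g0 <- grid_from_series(list(felt = make_series_array(list(m * 0))))
  expect_equal(rater_coverage(g0)["e1", "felt"], 0)
  expect_equal(timepoint_coverage(g0)["e1", "felt"], 0)
})

test_that("pairwise ISC equals the mean of all pairwise correlations", {
  set.seed(12)
  nt <- 30L
  m <- matrix(rnorm(nt * 5), nt, 5)
  g <- grid_from_series(list(perceived = make_series_array(list(m))))
  pairs <- combn(5, 2)
  oracle <- mean(apply(pairs, 2, function(p) cor(m[, p[1]], m[, p[2]])))
  expect_equal(pairwise_isc(g)["e1", "perceived"], oracle, tolerance = 1e-12)

  # identical non-constant series -> 1; sign-flipped -> -1
  two <- cbind(m[, 1], m[, 1])
  g2 <- grid_from_series(list(perceived = make_series_array(list(two))))
  expect_equal(pairwise_isc(g2)["e1", "perceived"], 1)
  anti <- cbind(m[, 1], -m[, 1] + 2 * mean(m[, 1]))
  g3 <- grid_from_series(list(perceived = make_series_array(list(anti))))
  expect_equal(pairwise_isc(g3)["e1", "perceived"], -1)

  # constant raters drop out of the pair mean
  mc <- cbind(m[, 1], m[, 2], 0)
  g4 <- grid_from_series(list(perceived = make_series_array(list(mc))))
  expect_equal(pairwise_isc(g4)["e1", "perceived"], cor(m[, 1], m[, 2]))
})

test_that("combined reliability is the geometric mean with non-positive clamping", {
  expect_equal(combined_reliability(1, 1, 1), 1)
  expect_equal(combined_reliability(0.5, 0.2, 0.1), (0.01)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(combined_reliability(0.5, 0.2, -0.1), 0)
  expect_equal(combined_reliability(0.5, 0, 0.9), 0)
  # bounds and scale equivariance on positive components
  set.seed(3)
  a <- runif(20); b <- runif(20); c <- runif(20)
  g <- combined_reliability(a, b, c)
  expect_true(all(g <= pmax(a, b, c) + 1e-12))
  expect_true(all(g >= pmin(a, b, c) - 1e-12))
  expect_equal(combined_reliability(2 * a, 2 * b, 2 * c), 2 * g,
               tolerance = 1e-12)
})

test_that("permutation threshold matches exhaustive enumeration on a 3-emotion toy", {
  # single-run toy with three emotions and hand-set component values
  set.seed(4)
  nt <- 20L
  mats <- lapply(c(1, 0.6, 0.1), function(amp) {
    base <- pmax(0, sin(seq(0, 3 * pi, length.out = nt))) * amp
    cbind(base, base * 0.8 + 0.1 * amp * runif(nt), 0)
  })
  arr <- make_series_array(mats, emotions = c("e1", "e2", "e3"))
  g <- grid_from_series(list(perceived = arr))
  tab <- reliability_table(list(g))
  res <- reliability_threshold(tab, method = "exhaustive")

  # independent oracle: enumerate all 6^3 permutation triples directly
  a <- tab$pct_raters; b <- tab$pct_timepoints; c <- tab$mean_isc
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  pool <- c()
  for (pa in perms) for (pb in perms) for (pc in perms)
    pool <- c(pool, combined_reliability(a[pa], b[pb], c[pc]))
  expect_equal(attr(res, "threshold"),
               unname(quantile(pool, 0.95, type = 7)), tolerance = 1e-12)
  expect_equal(sort(attr(res, "null")), sort(pool), tolerance = 1e-12)
})

test_that("threshold is permutation-invariant when components are identical, and seed-stable", {
  nt <- 20L
  base <- pmax(0, sin(seq(0, 2 * pi, length.out = nt)))
  mats <- replicate(3, cbind(base, base), simplify = FALSE)
  arr <- make_series_array(mats, emotions = c("e1", "e2", "e3"))
  g <- grid_from_series(list(felt = arr))
  tab <- reliability_table(list(g))
  res <- suppressWarnings(reliability_threshold(tab, n_perm = 25, seed = 1))
  # identical components across emotions: every null value equals the common
  # combined value, so the threshold equals it too
  expect_equal(unique(round(attr(res, "null"), 12)),
               round(tab$combined[1], 12))
  expect_equal(attr(res, "threshold"), tab$combined[1], tolerance = 1e-12)

  t1 <- reliability_threshold(tab, n_perm = 50, seed = 9)
  t2 <- reliability_threshold(tab, n_perm = 50, seed = 9)
  expect_identical(attr(t1, "threshold"), attr(t2, "threshold"))
})

test_that("reliable emotions are recovered from synthetic panels", {
  # generator + screening as a whole: sensitivity and false-positive rate
  # at the generator's default study layout, averaged over 5 seeds
  sens <- c(); fpr <- c()
  for (seed in 1:5) {
    spec <- simulation_spec(rng_seed = seed)
    manifests <- generate_run_manifests(spec)
    panel <- generate_rating_panel(spec, manifests)
    grids <- lapply(manifests, function(m) interpolate_to_grid(panel, m))
    tab <- reliability_threshold(reliability_table(grids),
                                 n_perm = 100, seed = seed)
    per_em <- tab[tab$task == "perceived", ]
    truly <- per_em$emotion %in% sprintf("emotion%02d",
                                         seq_len(spec$n_reliable))
    sens <- c(sens, mean(per_em$reliable[truly]))
    fpr <- c(fpr, mean(per_em$reliable[!truly]))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.1)
})

test_that("felt-perceived similarity reports r and shared variance", {
  nt <- 60L
  set.seed(5)
  x <- pmax(0, rnorm(nt))
  mk <- function(perc, felt) {
    arr_p <- make_series_array(list(cbind(perc, perc)))
    arr_f <- make_series_array(list(cbind(felt, felt)))
    grid_from_series(list(perceived = arr_p, felt = arr_f))
  }
  # identical series -> r = 1, 100% shared variance
  r1 <- felt_perceived_similarity(list(mk(x, x)))
  expect_equal(r1$r, 1)
  expect_equal(r1$shared_variance, 1)
  # constructed r = 0.6 -> 36% shared variance
  set.seed(6)
  z <- rnorm(nt)
  y <- 0.6 * scale(x)[, 1] + sqrt(1 - 0.36) * scale(resid(lm(z ~ x)))[, 1]
  r2 <- felt_perceived_similarity(list(mk(x, y)))
  expect_equal(r2$r, 0.6, tolerance = 1e-10)
  expect_equal(r2$shared_variance, 0.36, tolerance = 1e-9)
  # orthogonalized pair -> 0 within 1e-12
  o <- resid(lm(z ~ x))
  r3 <- felt_perceived_similarity(list(mk(x, o)))
  expect_equal(r3$r, 0, tolerance = 1e-12)
  # constant series flagged undefined
  r4 <- felt_perceived_similarity(list(mk(x, rep(0, nt))))
  expect_false(r4$defined)
  expect_true(is.na(r4$r))
})
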