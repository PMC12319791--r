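test_that("emotion-ROI correlations match the covariance formula", {
  spec <- small_spec(n_participants = 3L, snr = 2)
  sim <- quick_study(spec)
  r <- emotion_roi_correlation(sim$dataset, sim$designs$perceived)
  expect_equal(dim(r), c(3L, 10L, 6L, 3L))
  expect_true(all(abs(r) <= 1, na.rm = TRUE))
  # direct formula oracle on a handful of random cells
  set.seed(9)
  for (i in 1:10) {
    p <- sample(3, 1); roi <- sample(10, 1); e <- sample(6, 1)
    run <- sample(3, 1)
    y <- sim$dataset$signals[[p]][[run]][, roi]
    x <- sim$designs$perceived[[run]]$matrix[, e]
    oracle <- if (sd(y) == 0 || sd(x) == 0) NA_real_ else
      sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(r[p, roi, e, run]), oracle, tolerance = 1e-12)
  }
  # a ROI that equals a regressor correlates at exactly 1
  ds <- sim$dataset
  ds$signals[[1]][[1]][, 1] <- sim$designs$perceived[[1]]$matrix[, 2]
  r2 <- emotion_roi_correlation(ds, sim$designs$perceived)
  expect_equal(unname(r2[1, 1, 2, 1]), 1, tolerance = 1e-12)
})

test_that("circular shifts preserve the value multiset and circular autocorrelation", {
  set.seed(10)
  x <- rnorm(120)
  circ_acf1 <- function(v) cor(v, v[c(2:length(v), 1)])
  for (i in 1:10) {
    y <- circular_shift(x, min_shift = 20)
    k <- attr(y, "shift")
    expect_true(k >= 20 && k <= 100)
    expect_identical(sort(y), sort(x))
    expect_equal(circ_acf1(y), circ_acf1(x), tolerance = 1e-12)
  }
  # a full-cycle shift is the identity
  expect_equal(as.vector(circular_shift(x, k = length(x))), x)
  expect_error(circular_shift(rnorm(30), min_shift = 20), "length")
})

test_that("observed thresholds equal an independently sorted percentile of the maxima", {
  spec <- small_spec(n_participants = 6L, n_rois = 6L, n_emotions = 4L,
                     n_reliable = 3L, snr = 2)
  sim <- quick_study(spec)
  res <- shiftnull_fwer_test(sim$dataset, sim$designs$perceived,
                             n_shift = 15, n_perm = 80, seed = 3)
  nm <- sort(res$null_max)
  # type-7 percentile by hand
  h <- (length(nm) - 1) * 0.975 + 1
  oracle <- nm[floor(h)] + (h - floor(h)) * (nm[ceiling(h)] - nm[floor(h)])
  expect_equal(res$threshold, oracle, tolerance = 1e-12)
  expect_true(all((res$mask_run != 0) == (abs(res$t_run) > res$threshold)))
})

test_that("negating all ROI series flips t-map signs but not the threshold", {
  spec <- small_spec(n_participants = 6L, n_rois = 5L, n_emotions = 4L,
                     n_reliable = 3L, snr = 2)
  sim <- quick_study(spec)
  ds_neg <- sim$dataset
  for (p in seq_along(ds_neg$signals))
    ds_neg$signals[[p]] <- lapply(ds_neg$signals[[p]], function(m) -m)
  a <- shiftnull_fwer_test(sim$dataset, sim$designs$perceived,
                           n_shift = 10, n_perm = 60, seed = 4)
  b <- shiftnull_fwer_test(ds_neg, sim$designs$perceived,
                           n_shift = 10, n_perm = 60, seed = 4)
  expect_equal(b$t_run, -a$t_run, tolerance = 1e-10)
  expect_equal(b$threshold, a$threshold, tolerance = 1e-10)
  expect_equal(b$mask_avg, -a$mask_avg)
})

test_that("planted single-emotion effects dominate the map without false positives", {
  # A max-statistic circular-shift null is conservative by construction:
  # when a cell's across-participant variance is dominated by amplitude
  # variation of the stimulus-locked component, shifting scales the null
  # mean and sd by the same factor, so the strongest cell's null t tracks
  # its observed t and the family threshold tracks the maximum observed
  # statistic. The attainable guarantees are specificity and ranking.
  filt <- design_bandpass()
  total_detected <- 0L; false_pos <- 0L; top_planted <- 0L
  for (seed in 11:15) {
    spec <- simulation_spec(
      n_raters = 5L, n_emotions = 20L, n_reliable = 20L, n_runs = 3L,
      n_timepoints_per_run = 575L, n_participants = 24L, n_rois = 12L,
      snr = 5, rng_seed = seed, baseline = 0)
    manifests <- generate_run_manifests(spec)
    panel <- generate_rating_panel(spec, manifests)
    built <- build_all_designs(panel, manifests,
                               hrf_kernel(tr = spec$tr_seconds))
    truth <- generate_ground_truth(spec)
    truth$beta[] <- 0
    truth$beta[1:10, 2] <- 1.5       # emotion 2 drives ROIs 1-10, positively
    sim_ds <- generate_bold_dataset(spec, built$designs$perceived, truth)
    sim_ds <- condition_dataset(sim_ds, filt, psc = FALSE)
    res <- shiftnull_fwer_test(sim_ds, built$designs$perceived,
                               n_shift = 30, n_perm = 200, seed = seed)
    total_detected <- total_detected + sum(res$mask_avg[1:10, 2] == 1)
    false_pos <- false_pos +
      sum(res$mask_avg != 0) - sum(res$mask_avg[1:10, 2] != 0)
    top <- which(abs(res$t_avg) == max(abs(res$t_avg)), arr.ind = TRUE)[1, ]
    if (top[1] <= 10 && top[2] == 2 && res$t_avg[top[1], top[2]] > 0)
      top_planted <- top_planted + 1L
  }
  expect_equal(false_pos, 0L)
  expect_equal(top_planted, 5L)
  expect_gte(total_detected, 1L)
})

test_that("activation extent counts match a hand enumeration", {
  mask <- matrix(0, 6, 3, dimnames = list(paste0("roi", 1:6),
                                          c("joy", "fear", "calm")))
  mask[1:2, 1] <- 1; mask[3, 1] <- -1
  mask[4:6, 2] <- 1
  groups <- setNames(c("A", "A", "B", "B", "C", "C"), paste0("roi", 1:6))
  ext <- activation_extent(mask, groups)
  expect_equal(ext$by_emotion$n_positive, c(2, 3, 0))
  expect_equal(ext$by_emotion$n_negative, c(1, 0, 0))
  byA <- ext$by_region[ext$by_region$region == "A", ]
  expect_equal(byA$frac_positive, c(1, 0, 0))
  byB <- ext$by_region[ext$by_region$region == "B", ]
  expect_equal(byB$frac_positive, c(0, 0.5, 0))
  expect_equal(byB$frac_negative, c(0.5, 0, 0))
  # empty and full masks
  ext0 <- activation_extent(mask * 0, groups)
  expect_true(all(ext0$by_emotion$n_total == 0))
  ext1 <- activation_extent((mask * 0) + 1, groups)
  expect_true(all(ext1$by_region$frac_positive == 1))
  expect_error(activation_extent(mask, groups[1:5]), "without")
  expect_error(activation_extent(mask * 2, groups), "ternary")
})
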