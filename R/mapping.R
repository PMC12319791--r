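#' Per-emotion, per-ROI correlation tensor
#'
#' Pearson correlation between each single emotion regressor and each ROI
#' series, separately for every participant and run. Cells with a constant
#' series are undefined (`NA`).
#'
#' @param dataset A conditioned `roi_dataset`.
#' @param designs List of `emotion_design`s, one per run (single task).
#' @return Array participant x ROI x emotion x run of correlations.
#' @export
emotion_roi_correlation <- function(dataset, designs) {
  stopifnot(inherits(dataset, "roi_dataset"),
            length(designs) == length(dataset$runs))
  n_part <- length(dataset$participants)
  nroi <- length(dataset$roi_labels)
  emotions <- designs[[1]]$emotions
  r <- array(NA_real_, dim = c(n_part, nroi, length(emotions),
                               length(dataset$runs)),
             dimnames = list(dataset$participants, dataset$roi_labels,
                             emotions, dataset$runs))
  for (run in seq_along(dataset$runs)) {
    X <- designs[[run]]$matrix
    for (p in seq_len(n_part)) {
      cc <- suppressWarnings(stats::cor(dataset$signals[[p]][[run]], X))
      cc[!is.finite(cc)] <- NA_real_
      r[p, , , run] <- cc
    }
  }
  r
}

#' Circularly shift a time series
#'
#' Rotates the series by `k` samples (positive = forward), preserving the
#' multiset of values and the circular autocorrelation exactly while
#' destroying temporal alignment. When `k` is not given it is drawn
#' uniformly from `[min_shift, n - min_shift]`, i.e. at least `min_shift`
#' samples away from zero lag in both directions.
#'
#' @param series Numeric vector or time-by-k matrix (columns shifted
#'   together).
#' @param min_shift Minimum shift in samples.
#' @param k Optional explicit shift; `k = n` is the identity.
#' @param rng Optional RNG stream from `local_rng()`.
#' @return The rotated series, with attribute `shift`.
#' @export
circular_shift <- function(series, min_shift = 20L, k = NULL, rng = NULL) {
  m <- as.matrix(series)
  n <- nrow(m)
  if (is.null(k)) {
    if (n <= 2L * min_shift)
      stop(sprintf("series length (%d) must exceed twice min_shift (%d)",
                   n, min_shift), call. = FALSE)
    lo <- as.integer(min_shift); hi <- as.integer(n - min_shift)
    k <- if (is.null(rng)) sample(lo:hi, 1L) else lo + rng$sample(hi - lo + 1L, 1L) - 1L
  }
  idx <- ((seq_len(n) - 1L - k) %% n) + 1L
  out <- m[idx, , drop = FALSE]
  if (is.null(dim(series))) out <- drop(out)
  attr(out, "shift") <- as.integer(k)
  out
}

# one-sample t over the first dimension of an array; zero-variance cells -> 0
tstat_over_first <- function(arr) {
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1])
  n <- d[1]
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  t <- mu / sqrt(v / n)
  t[v == 0] <- 0
  array(t, dim = d[-1], dimnames = dimnames(arr)[-1])
}

fisher_z <- function(r, clamp = 1 - 1e-12) atanh(pmin(pmax(r, -clamp), clamp))

#' Single-emotion mapping with circular-shift nulls and FWER control
#'
#' Tests, for every ROI, emotion and run (and the run average), whether the
#' correlation between the emotion regressor and the ROI series is
#' consistently non-zero across participants (one-sample t-test on
#' Fisher-z-transformed correlations). The null distribution respects the
#' autocorrelation of the regressors: each emotion gets `n_shift` surrogate
#' regressors made by circularly shifting its time series by at least
#' `min_shift` samples; each permutation iteration pairs randomly permuted
#' emotion labels with a random surrogate, recomputes all t-statistics and
#' records the maximum absolute value over the whole map (ROIs, runs and
#' the run average, with emotion labels permuted within the iteration).
#' The two-tailed FWER threshold is the `1 - alpha/2` percentile of these
#' per-iteration maxima.
#'
#' @param dataset A conditioned `roi_dataset`.
#' @param designs List of `emotion_design`s, one per run.
#' @param n_shift Number of circularly shifted surrogates per emotion.
#' @param n_perm Number of label-permutation iterations.
#' @param min_shift Minimum shift in samples.
#' @param seed Integer seed.
#' @param alpha Two-tailed family-wise error level.
#' @param use_fisher_z Run the t-tests on Fisher-z-transformed correlations
#'   (default) or on raw correlations.
#' @return An object of class `emotion_roi_map`: the correlation tensor
#'   `r`, t-maps `t_run` (ROI x emotion x run) and `t_avg` (ROI x emotion),
#'   `threshold`, signed masks `mask_run`/`mask_avg`, and the permutation
#'   maxima `null_max`.
#' @export
shiftnull_fwer_test <- function(dataset, designs, n_shift = 100L,
                                n_perm = 1000L, min_shift = 20L, seed = 1L,
                                alpha = 0.05, use_fisher_z = TRUE) {
  if (n_perm < 40L)
    warning("fewer than 40 permutations: tail percentile is unstable")
  r <- emotion_roi_correlation(dataset, designs)
  zt <- if (use_fisher_z) fisher_z(r) else r
  zt[is.na(zt)] <- 0
  t_run <- tstat_over_first(zt)                       # ROI x emotion x run
  n_runs <- dim(zt)[4]
  z_avg <- array(rowMeans(matrix(zt, ncol = n_runs), na.rm = TRUE),
                 dim = dim(zt)[1:3], dimnames = dimnames(zt)[1:3])
  t_avg <- tstat_over_first(z_avg)                    # ROI x emotion

  n_part <- dim(r)[1]; nroi <- dim(r)[2]; nE <- dim(r)[3]
  rng <- local_rng(seed)
  # null correlation tensor: participant x ROI x emotion x shift x run
  z_null <- array(NA_real_, dim = c(n_part, nroi, nE, n_shift, n_runs))
  for (run in seq_len(n_runs)) {
    X <- designs[[run]]$matrix
    shifted <- matrix(0, nrow(X), nE * n_shift)
    for (e in seq_len(nE)) for (s in seq_len(n_shift))
      shifted[, (e - 1L) * n_shift + s] <-
        circular_shift(X[, e], min_shift, rng = rng)
    for (p in seq_len(n_part)) {
      cc <- suppressWarnings(stats::cor(dataset$signals[[p]][[run]], shifted))
      cc[!is.finite(cc)] <- 0
      z_null[p, , , , run] <- if (use_fisher_z) fisher_z(cc) else cc
    }
  }
  null_max <- vapply(seq_len(n_perm), function(it) {
    perm <- rng$sample(nE)
    s_e <- rng$sample(n_shift, nE, replace = TRUE)
    z_it <- array(0, dim = c(n_part, nroi, nE, n_runs))
    for (e in seq_len(nE))
      z_it[, , e, ] <- z_null[, , perm[e], s_e[e], ]
    t_it <- tstat_over_first(z_it)                 # ROI x emotion x run
    za <- array(rowMeans(matrix(z_it, ncol = n_runs)), dim = dim(z_it)[1:3])
    t_av <- tstat_over_first(za)                   # ROI x emotion
    # one maximum per iteration over the full map (ROIs, runs and the
    # run average; emotion labels are permuted within the iteration)
    max(abs(t_it), abs(t_av))
  }, numeric(1))
  threshold <- percentile(null_max, 1 - alpha / 2)
  structure(list(
    r = r, t_run = t_run, t_avg = t_avg, threshold = threshold,
    mask_run = sign(t_run) * (abs(t_run) > threshold),
    mask_avg = sign(t_avg) * (abs(t_avg) > threshold),
    null_max = null_max, use_fisher_z = use_fisher_z,
    n_shift = n_shift, n_perm = n_perm, min_shift = min_shift,
    seed = seed, alpha = alpha),
    class = "emotion_roi_map")
}

#' @export
print.emotion_roi_map <- function(x, ...) {
  cat(sprintf(paste0(
    "Emotion-ROI map: %d ROIs x %d emotions x %d runs\n",
    "  two-tailed FWER threshold |t| > %.3f (%d shifts x %d permutations)\n",
    "  significant cells (run-average): %d positive, %d negative\n"),
    dim(x$t_run)[1], dim(x$t_run)[2], dim(x$t_run)[3], x$threshold,
    x$n_shift, x$n_perm, sum(x$mask_avg > 0), sum(x$mask_avg < 0)))
  invisible(x)
}

#' Activation extent per emotion and macroanatomical region
#'
#' Summarizes a signed significance mask: the number of significantly
#' activated/deactivated ROIs per emotion, and the fraction of member ROIs
#' significant per macroanatomical group.
#'
#' @param mask ROI-by-emotion signed mask with values in `{-1, 0, 1}`.
#' @param roi_groups Named character vector mapping each ROI (rownames of
#'   `mask`) to its macroanatomical group.
#' @return List of data frames `by_emotion` (counts) and `by_region`
#'   (signed fractions per group and emotion).
#' @export
activation_extent <- function(mask, roi_groups) {
  if (!all(mask %in% c(-1, 0, 1)))
    stop("mask must be ternary (-1/0/1)", call. = FALSE)
  rois <- rownames(mask) %||% as.character(seq_len(nrow(mask)))
  ungrouped <- setdiff(rois, names(roi_groups))
  if (length(ungrouped))
    stop("ROI(s) without macroanatomical group: ",
         paste(utils::head(ungrouped, 5), collapse = ", "), call. = FALSE)
  emotions <- colnames(mask) %||% as.character(seq_len(ncol(mask)))
  by_emotion <- data.frame(
    emotion = emotions,
    n_positive = colSums(mask > 0),
    n_negative = colSums(mask < 0),
    n_total = colSums(mask != 0),
    row.names = NULL)
  groups <- roi_groups[rois]
  by_region <- do.call(rbind, lapply(unique(groups), function(g) {
    sub <- mask[groups == g, , drop = FALSE]
    data.frame(region = g, emotion = emotions,
               frac_positive = colMeans(sub > 0),
               frac_negative = colMeans(sub < 0),
               n_rois = nrow(sub), row.names = NULL)
  }))
  list(by_emotion = by_emotion, by_region = by_region)
}
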