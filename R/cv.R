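#' Enumerate between-run train/test splits
#'
#' All `choose(n_runs, n_train)` partitions of the runs into a training and
#' a test set, in deterministic lexicographic order. With the study layout
#' of 5 runs and 3 training runs this yields the 10 combinations over which
#' every between-run statistic is averaged.
#'
#' @param n_runs Total number of runs.
#' @param n_train Number of training runs per split.
#' @return List of splits, each a list with integer vectors `train`, `test`.
#' @export
enumerate_run_splits <- function(n_runs, n_train) {
  if (n_train <= 0 || n_train >= n_runs)
    stop("need 0 < n_train < n_runs", call. = FALSE)
  combos <- utils::combn(n_runs, n_train)
  lapply(seq_len(ncol(combos)), function(i) {
    tr <- combos[, i]
    list(train = tr, test = setdiff(seq_len(n_runs), tr))
  })
}

#' Ordinary least-squares fit of a linear map
#'
#' Column-demeans both predictors and targets, then solves the least-squares
#' problem without an intercept. Rank deficiency is resolved by the
#' minimum-norm solution (pseudoinverse) and flagged in the
#' `rank_deficient` attribute.
#'
#' @param X Time-by-p predictor matrix.
#' @param Y Time-by-q target matrix (or vector).
#' @return p-by-q coefficient matrix.
#' @export
fit_linear_map <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows", call. = FALSE)
  if (nrow(X) < ncol(X))
    stop(sprintf("need at least as many timepoints (%d) as predictors (%d)",
                 nrow(X), ncol(X)), call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], Yc)) / sv$d[keep])
  dimnames(beta) <- list(colnames(X), colnames(Y))
  attr(beta, "rank_deficient") <- sum(keep) < ncol(Xc)
  beta
}

# z-score columns over time; constant columns map to zero
zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd == 0] <- Inf
  sweep(sweep(m, 2, mu), 2, sd, "/")
}

demean_cols <- function(m) sweep(m, 2, colMeans(m))

# columnwise Pearson correlation of two equal-shape matrices; constant
# columns give NA
cor_cols <- function(a, b) {
  a <- demean_cols(a); b <- demean_cols(b)
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# standardize one participant: demean within run, scale by one pooled
# per-ROI sd computed over scale_runs only. A per-run sd would make the
# training runs' targets mutually inconsistent; a sd pooled over all runs
# would leak test-run amplitudes into the training fit.
standardize_participant <- function(runs_list, scale_runs = NULL) {
  if (is.null(scale_runs)) scale_runs <- seq_along(runs_list)
  centered <- lapply(runs_list, demean_cols)
  base <- centered[scale_runs]
  pooled_sd <- sqrt(Reduce(`+`, lapply(base, function(m)
    colSums(m^2))) / (sum(vapply(base, nrow, 0L)) - length(base)))
  pooled_sd[pooled_sd == 0] <- Inf
  lapply(centered, function(m) sweep(m, 2, pooled_sd, "/"))
}

# mean over participants of the standardized series, one matrix per run
mean_standardized_activity <- function(dataset, participants = NULL,
                                       scale_runs = NULL) {
  if (is.null(participants)) participants <- seq_along(dataset$participants)
  acc <- NULL
  for (p in participants) {
    z <- standardize_participant(dataset$signals[[p]], scale_runs)
    acc <- if (is.null(acc)) z else Map(`+`, acc, z)
  }
  lapply(acc, `/`, length(participants))
}

# stack per-run matrices for the given runs with per-run demeaning, so
# inter-run offsets cannot masquerade as signal
stack_runs <- function(mats, runs) {
  do.call(rbind, lapply(runs, function(r) demean_cols(mats[[r]])))
}

design_matrices <- function(designs) lapply(designs, function(d) d$matrix)

#' Between-run cross-validated encoding/decoding
#'
#' For every train/test partition of the runs, fits a linear model on the
#' concatenated training runs and scores it on the held-out runs; scores
#' are averaged over all partitions.
#'
#' Encoding fits the full emotion design to the across-participant mean of
#' the standardized ROI series and scores the predicted test-run series
#' against each individual participant's series (one Pearson correlation per
#' participant and ROI). Decoding fits the mean ROI activity to each emotion
#' regressor and scores predicted against actual ratings per emotion; its
#' null distribution records, per iteration, the maximum score over emotions
#' after shuffling the training emotion labels within each split.
#'
#' @param dataset A conditioned `roi_dataset`.
#' @param designs List of `emotion_design`s, one per run (single task).
#' @param direction `"encode"` or `"decode"`.
#' @param n_train Number of training runs.
#' @param n_perm Label-shuffle iterations for the decoding null (0 = none).
#' @param seed Seed for the decoding null.
#' @param alpha Significance level for the decoding threshold.
#' @return A `fit_result`. For encoding, `fit` is participant-by-ROI; for
#'   decoding, `fit` is a named per-emotion vector with `null_max`,
#'   `threshold` and `significant` attached.
#' @export
between_run_cv <- function(dataset, designs, direction = c("encode", "decode"),
                           n_train = 3L, n_perm = 0L, seed = 1L,
                           alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(inherits(dataset, "roi_dataset"),
            length(designs) == length(dataset$runs))
  splits <- enumerate_run_splits(length(dataset$runs), n_train)
  X_run <- design_matrices(designs)
  n_part <- length(dataset$participants)
  nroi <- length(dataset$roi_labels)
  emotions <- designs[[1]]$emotions

  if (direction == "encode") {
    betas <- vector("list", length(splits))
    fit_split <- vector("list", length(splits))
    for (s in seq_along(splits)) {
      sp <- splits[[s]]
      Ybar <- mean_standardized_activity(dataset, scale_runs = sp$train)
      beta <- fit_linear_map(stack_runs(X_run, sp$train),
                             stack_runs(Ybar, sp$train))
      betas[[s]] <- beta
      acc <- matrix(0, n_part, nroi)
      cnt <- matrix(0, n_part, nroi)
      for (rt in sp$test) {
        pred <- demean_cols(X_run[[rt]]) %*% beta
        for (p in seq_len(n_part)) {
          r <- cor_cols(pred, dataset$signals[[p]][[rt]])
          ok <- !is.na(r)
          acc[p, ok] <- acc[p, ok] + r[ok]
          cnt[p, ok] <- cnt[p, ok] + 1
        }
      }
      fit_split[[s]] <- acc / pmax(cnt, 1)
    }
    fit <- Reduce(`+`, fit_split) / length(fit_split)
    dimnames(fit) <- list(dataset$participants, dataset$roi_labels)
    beta_mean <- Reduce(`+`, betas) / length(betas)
    res <- list(direction = "encode", scheme = "between-runs",
                splits = splits, beta = beta_mean, beta_by_split = betas,
                fit = fit, fit_by_split = fit_split)
  } else {
    score_split <- matrix(NA_real_, length(splits), length(emotions),
                          dimnames = list(NULL, emotions))
    cross <- vector("list", length(splits))  # pred-emotion x actual-emotion
    for (s in seq_along(splits)) {
      sp <- splits[[s]]
      Ybar <- mean_standardized_activity(dataset, scale_runs = sp$train)
      beta <- fit_linear_map(stack_runs(Ybar, sp$train),
                             stack_runs(X_run, sp$train))
      C <- 0
      for (rt in sp$test) {
        pred <- demean_cols(Ybar[[rt]]) %*% beta
        actual <- X_run[[rt]]
        Cm <- suppressWarnings(stats::cor(pred, actual))
        Cm[!is.finite(Cm)] <- 0
        C <- C + Cm
      }
      C <- C / length(sp$test)
      cross[[s]] <- C
      score_split[s, ] <- diag(C)
    }
    fit <- colMeans(score_split)
    res <- list(direction = "decode", scheme = "between-runs",
                splits = splits, fit = fit, fit_by_split = score_split,
                cross_correlation = cross)
    if (n_perm > 0L) {
      rng <- local_rng(seed)
      nE <- length(emotions)
      null_max <- vapply(seq_len(n_perm), function(it) {
        null_scores <- rowMeans(vapply(cross, function(C) {
          perm <- rng$sample(nE)
          C[cbind(perm, seq_len(nE))]
        }, numeric(nE)))
        max(null_scores)
      }, numeric(1))
      res$null_max <- null_max
      res$threshold <- percentile(null_max, 1 - alpha)
      res$significant <- fit > res$threshold
    }
  }
  class(res) <- "fit_result"
  res
}

#' Ground-truth recovery of encoding weights
#'
#' Compares the weights estimated by [between_run_cv()] with the
#' generator's true weights. Because the encoding model fits standardized
#' activity, the estimates carry a known per-ROI scale (the mean reciprocal
#' pooled sd across participants); that scale is inverted before the
#' comparison.
#'
#' @param fit A `fit_result` from an encoding fit.
#' @param dataset The (conditioned) `roi_dataset` that was fitted; must
#'   carry `truth`.
#' @return List with `r` (Pearson correlation over all ROI-by-condition
#'   entries), `beta_hat` (ROI x condition, de-standardized) and
#'   `beta_true`.
#' @export
beta_recovery <- function(fit, dataset) {
  if (is.null(dataset$truth))
    stop("dataset carries no ground truth", call. = FALSE)
  inv_sd <- 0
  for (p in seq_along(dataset$signals)) {
    centered <- lapply(dataset$signals[[p]], demean_cols)
    pooled <- sqrt(Reduce(`+`, lapply(centered, function(m) colSums(m^2))) /
                     (sum(vapply(centered, nrow, 0L)) - length(centered)))
    pooled[pooled == 0] <- Inf
    inv_sd <- inv_sd + 1 / pooled
  }
  inv_sd <- inv_sd / length(dataset$signals)
  beta_hat <- t(fit$beta) / inv_sd   # ROI x condition
  bt <- dataset$truth$beta
  list(r = stats::cor(as.vector(beta_hat), as.vector(bt)),
       beta_hat = beta_hat, beta_true = bt)
}

#' Within-run (across-participant) cross-validated encoding
#'
#' K-fold cross-validation across participants: the model is fitted to the
#' mean standardized activity of the held-in participants on the training
#' runs, and the predicted test-run series are scored against each held-out
#' participant individually. With 50 participants and 10 folds each model is
#' trained on 45 participants. Repeated over every fold and every run split.
#'
#' @param dataset A conditioned `roi_dataset`.
#' @param designs List of `emotion_design`s, one per run.
#' @param n_folds Number of participant folds.
#' @param n_train Number of training runs per split.
#' @param seed Seed for the fold assignment shuffle.
#' @return A `fit_result` with participant-by-ROI `fit` (each participant
#'   scored in the fold that held it out).
#' @export
within_run_cv <- function(dataset, designs, n_folds = 10L, n_train = 3L,
                          seed = 1L) {
  stopifnot(inherits(dataset, "roi_dataset"))
  n_part <- length(dataset$participants)
  if (n_folds > n_part)
    stop("more folds than participants", call. = FALSE)
  rng <- local_rng(seed)
  fold_of <- rep(seq_len(n_folds), length.out = n_part)[rng$sample(n_part)]
  splits <- enumerate_run_splits(length(dataset$runs), n_train)
  X_run <- design_matrices(designs)
  nroi <- length(dataset$roi_labels)
  acc <- matrix(0, n_part, nroi)
  cnt <- matrix(0, n_part, nroi)
  for (k in seq_len(n_folds)) {
    held_out <- which(fold_of == k)
    held_in <- setdiff(seq_len(n_part), held_out)
    for (sp in splits) {
      Ybar <- mean_standardized_activity(dataset, held_in,
                                         scale_runs = sp$train)
      beta <- fit_linear_map(stack_runs(X_run, sp$train),
                             stack_runs(Ybar, sp$train))
      for (rt in sp$test) {
        pred <- demean_cols(X_run[[rt]]) %*% beta
        for (p in held_out) {
          r <- cor_cols(pred, dataset$signals[[p]][[rt]])
          ok <- !is.na(r)
          acc[p, ok] <- acc[p, ok] + r[ok]
          cnt[p, ok] <- cnt[p, ok] + 1
        }
      }
    }
  }
  fit <- acc / pmax(cnt, 1)
  dimnames(fit) <- list(dataset$participants, dataset$roi_labels)
  structure(list(direction = "encode", scheme = "within-run",
                 splits = splits, folds = fold_of, fit = fit),
            class = "fit_result")
}

#' Felt-versus-perceived contrast with max-statistic FWER control
#'
#' Paired t-test per ROI across participants on the difference between the
#' felt and perceived model fits. The null distribution randomizes the
#' felt/perceived order independently for every participant (equivalently,
#' sign-flips each participant's difference with probability one half),
#' recomputes the t-map and records its maximum absolute value over ROIs;
#' the threshold is the 95th percentile of these maxima.
#'
#' @param fit_felt,fit_perceived Participant-by-ROI fit matrices (e.g.
#'   `$fit` of two encoding `fit_result`s) with matching rows and columns.
#' @param n_perm Number of sign-flip iterations.
#' @param seed Integer seed.
#' @param alpha Family-wise error level.
#' @return List with `t` (per ROI), `threshold`, signed `mask`
#'   (-1/0/+1), and the permutation maxima `null_max`.
#' @export
contrast_tasks <- function(fit_felt, fit_perceived, n_perm = 1000L,
                           seed = 1L, alpha = 0.05) {
  stopifnot(all(dim(fit_felt) == dim(fit_perceived)))
  n <- nrow(fit_felt)
  if (n < 2L) stop("paired t-test needs at least two participants",
                   call. = FALSE)
  d <- fit_felt - fit_perceived
  tvec <- function(dm) {
    mu <- colMeans(dm)
    se <- apply(dm, 2, stats::sd) / sqrt(nrow(dm))
    out <- mu / se
    out[se == 0] <- 0
    out
  }
  t_obs <- tvec(d)
  rng <- local_rng(seed)
  null_max <- vapply(seq_len(n_perm), function(it) {
    flips <- rng$rbinom(n, 1L, 0.5) * 2L - 1L
    max(abs(tvec(d * flips)))
  }, numeric(1))
  threshold <- percentile(null_max, 1 - alpha)
  mask <- sign(t_obs) * (abs(t_obs) > threshold)
  list(t = t_obs, threshold = threshold, mask = mask, null_max = null_max,
       n_perm = n_perm, seed = seed)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Cross-validated %s fit (%s): %d splits\n",
              x$direction, x$scheme, length(x$splits)))
  if (is.matrix(x$fit))
    cat(sprintf("  mean test correlation %.3f over %d participants x %d ROIs\n",
                mean(x$fit), nrow(x$fit), ncol(x$fit)))
  else
    cat(sprintf("  mean test correlation %.3f over %d emotions\n",
                mean(x$fit), length(x$fit)))
  invisible(x)
}
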