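#' Simulation specification
#'
#' Parameters of the synthetic study. Dimensions default to the study
#' layout: 16 raters scoring 63 emotions for two tasks over 5 runs, and 50
#' participants scanned over 273 ROIs at 575 TRs per run. Parameters the
#' study does not fix (rater agreement, occurrence rate, SNR, sparsity) get
#' conservative defaults documented in the methods vignette.
#'
#' @param n_raters Number of raters.
#' @param n_emotions Number of emotion categories.
#' @param n_reliable Number of emotions generated with a shared (reliable)
#'   rating signal; the remainder are rater-idiosyncratic.
#' @param n_runs Number of runs.
#' @param n_timepoints_per_run TRs per run.
#' @param n_participants Number of fMRI participants.
#' @param n_rois Number of ROIs.
#' @param rater_agreement Mixing weight in `[0, 1]` of the shared versus
#'   idiosyncratic rating signal for reliable emotions (1 = identical
#'   raters).
#' @param occurrence_rate Probability in `(0, 1]` that a reliable emotion
#'   occurs in a given clip.
#' @param snr Signal-to-noise ratio: sd of the emotion-driven signal over sd
#'   of the AR(1) noise, per ROI. `Inf` = noiseless.
#' @param ar_coefficient Lag-1 autoregressive coefficient of the noise.
#' @param beta_sparsity Fraction of ROI-by-emotion weights set to zero.
#' @param participant_gain_sd Standard deviation of the multiplicative
#'   per-participant gain on the true weights.
#' @param participant_beta_sd Standard deviation of additive per-participant
#'   deviations from the group weights, relative to the root-mean-square of
#'   the non-zero group weights. This is what keeps across-participant
#'   consistency below 1 even without measurement noise; it scales with the
#'   group weights, so null (all-zero beta) datasets remain pure noise.
#' @param task_coupling Correlation-inducing weight between the felt and
#'   perceived latent profiles of the same emotion.
#' @param baseline Additive raw-signal baseline (set 0 for zero-mean series).
#' @param drift_amplitude Linear drift amplitude relative to the noise sd.
#' @param motion_weight Weight of the synthetic motion confound leakage into
#'   the signal, relative to the noise sd.
#' @param tr_seconds Sampling interval.
#' @param n_clips_per_run Movie clips per run.
#' @param rng_seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_raters = 16L, n_emotions = 63L,
                            n_reliable = 46L, n_runs = 5L,
                            n_timepoints_per_run = 575L,
                            n_participants = 50L, n_rois = 273L,
                            rater_agreement = 0.7, occurrence_rate = 0.3,
                            snr = 1, ar_coefficient = 0.4,
                            beta_sparsity = 0.5,
                            participant_gain_sd = 0.2,
                            participant_beta_sd = 0.5,
                            task_coupling = 0.8,
                            baseline = 100, drift_amplitude = 0.3,
                            motion_weight = 0.2,
                            tr_seconds = 2.4, n_clips_per_run = 8L,
                            rng_seed = 1L) {
  spec <- list(n_raters = as.integer(n_raters),
               n_emotions = as.integer(n_emotions),
               n_reliable = as.integer(n_reliable),
               n_runs = as.integer(n_runs),
               n_timepoints_per_run = as.integer(n_timepoints_per_run),
               n_participants = as.integer(n_participants),
               n_rois = as.integer(n_rois),
               rater_agreement = rater_agreement,
               occurrence_rate = occurrence_rate,
               snr = snr, ar_coefficient = ar_coefficient,
               beta_sparsity = beta_sparsity,
               participant_gain_sd = participant_gain_sd,
               participant_beta_sd = participant_beta_sd,
               task_coupling = task_coupling,
               baseline = baseline, drift_amplitude = drift_amplitude,
               motion_weight = motion_weight,
               tr_seconds = tr_seconds,
               n_clips_per_run = as.integer(n_clips_per_run),
               rng_seed = as.integer(rng_seed))
  if (spec$n_reliable > spec$n_emotions)
    stop("n_reliable cannot exceed n_emotions", call. = FALSE)
  for (nm in c("rater_agreement", "beta_sparsity"))
    if (spec[[nm]] < 0 || spec[[nm]] > 1)
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  if (spec$occurrence_rate <= 0 || spec$occurrence_rate > 1)
    stop("occurrence_rate must lie in (0, 1]", call. = FALSE)
  if (abs(spec$ar_coefficient) >= 1)
    stop("ar_coefficient must lie in (-1, 1)", call. = FALSE)
  if (spec$snr < 0) stop("snr must be non-negative", call. = FALSE)
  class(spec) <- "simulation_spec"
  spec
}

emotion_names <- function(spec)
  sprintf("emotion%02d", seq_len(spec$n_emotions))

#' Generate run manifests for a synthetic study
#'
#' Runs begin and end with 4 TRs of fixation; the clips in between are
#' played back to back with randomized lengths.
#'
#' @param spec A `simulation_spec`.
#' @return List of `run_manifest`s.
#' @export
generate_run_manifests <- function(spec) {
  rng <- local_rng(spec$rng_seed + 101L)
  fix_s <- 4 * spec$tr_seconds
  lapply(seq_len(spec$n_runs), function(run) {
    total <- spec$n_timepoints_per_run * spec$tr_seconds - 2 * fix_s
    w <- rng$runif(spec$n_clips_per_run, 0.5, 1.5)
    lens <- total * w / sum(w)
    offs <- fix_s + cumsum(c(0, lens))
    run_manifest(run_id = run,
                 clips = data.frame(
                   clip = sprintf("r%d_c%02d", run,
                                  seq_len(spec$n_clips_per_run)),
                   onset_s = offs[-length(offs)],
                   offset_s = offs[-1]),
                 n_timepoints = spec$n_timepoints_per_run,
                 tr_seconds = spec$tr_seconds)
  })
}

# clipped random walk over segment end-points, the latent intensity profile
walk_profile <- function(n, rng, scale_max = 4) {
  v <- numeric(n)
  v[1] <- rng$runif(1, 0.5, scale_max)
  if (n > 1)
    for (j in 2:n) v[j] <- min(max(v[j - 1] + rng$rnorm(1, 0, 1), 0), scale_max)
  v
}

#' Generate a synthetic dynamic rating panel
#'
#' Emulates sparse piecewise ratings with a continuum of reliability: the
#' first `n_reliable` emotions carry a shared latent piecewise-linear
#' intensity profile, present in `occurrence_rate` of the clips and mixed
#' per rater with idiosyncratic noise at weight `rater_agreement`; the felt
#' and perceived profiles of the same emotion are coupled by
#' `task_coupling`. The remaining emotions are rated sparsely and
#' idiosyncratically by individual raters. Segment lengths are drawn from
#' 3-10 s, matching the rating granularity; intensities are clipped to the
#' 0-4 scale. Ratings are emitted at segment resolution and travel through
#' the same interpolation path as real data.
#'
#' @param spec A `simulation_spec`.
#' @param manifests Run manifests (defaults to
#'   [generate_run_manifests()]).
#' @return A `rating_panel`.
#' @export
generate_rating_panel <- function(spec, manifests = generate_run_manifests(spec)) {
  rng <- local_rng(spec$rng_seed + 202L)
  emotions <- emotion_names(spec)
  raters <- sprintf("rater%02d", seq_len(spec$n_raters))
  reliable <- seq_len(spec$n_reliable)
  rows <- vector("list", 10000L); nr <- 0L
  push <- function(rater, run, clip, task, emotion, onset_s, offset_s,
                   intensity) {
    nr <<- nr + 1L
    rows[[nr]] <<- list(rater, run, clip, task, emotion, onset_s, offset_s,
                        intensity)
  }

  w <- spec$rater_agreement
  for (run_i in seq_along(manifests)) {
    mf <- manifests[[run_i]]
    for (e in seq_along(emotions)) {
      if (e %in% reliable) {
        for (ci in seq_len(nrow(mf$clips))) {
          c_on <- mf$clips$onset_s[ci]; c_off <- mf$clips$offset_s[ci]
          shared_win <- if (rng$runif(1) <= spec$occurrence_rate)
            episode_profile(c_on, c_off, rng) else NULL
          shared <- list(perceived = shared_win, felt = NULL)
          if (!is.null(shared_win)) {
            # felt profile shares the episode timing, coupled in intensity
            own <- walk_profile(length(shared_win$vals) - 2L, rng)
            felt_vals <- shared_win$vals
            inner <- seq_along(own) + 1L
            felt_vals[inner] <- spec$task_coupling * shared_win$vals[inner] +
              (1 - spec$task_coupling) * own
            shared$felt <- list(ends = shared_win$ends, vals = felt_vals)
          }
          for (task in c("perceived", "felt")) {
            for (r in seq_len(spec$n_raters)) {
              # the idiosyncratic component has its own occurrence draw and
              # its own episode timing, so at rater_agreement 0 the raters
              # are fully independent
              idio <- if (rng$runif(1) <= spec$occurrence_rate)
                episode_profile(c_on, c_off, rng) else NULL
              prof <- mix_profiles(shared[[task]], idio, w, c_on)
              if (is.null(prof)) next
              push(raters[r], mf$run_id, mf$clips$clip[ci], task,
                   emotions[e], c(c_on, utils::head(prof$ends, -1)),
                   prof$ends, prof$vals)
            }
          }
        }
      } else {
        # unreliable emotions: rated sparsely by a small random subset of
        # raters, with fully idiosyncratic profiles
        for (task in c("perceived", "felt")) {
          active <- rng$sample(spec$n_raters,
                               min(spec$n_raters, 1L + rng$sample(3L, 1L)))
          for (r in active) {
            for (ci in seq_len(nrow(mf$clips))) {
              if (rng$runif(1) > spec$occurrence_rate * 0.5) next
              c_on <- mf$clips$onset_s[ci]; c_off <- mf$clips$offset_s[ci]
              prof <- episode_profile(c_on, c_off, rng)
              push(raters[r], mf$run_id, mf$clips$clip[ci], task,
                   emotions[e], c(c_on, utils::head(prof$ends, -1)),
                   prof$ends, prof$vals)
            }
          }
        }
      }
    }
  }
  rows <- rows[seq_len(nr)]
  lens <- vapply(rows, function(x) length(x[[8]]), 0L)
  col <- function(i, expand) {
    v <- lapply(rows, `[[`, i)
    if (expand) rep(unlist(lapply(v, `[`, 1)), lens) else unlist(v)
  }
  segments <- data.frame(rater = col(1, TRUE), run = col(2, TRUE),
                         clip = col(3, TRUE), task = col(4, TRUE),
                         emotion = col(5, TRUE), onset_s = col(6, FALSE),
                         offset_s = col(7, FALSE), intensity = col(8, FALSE))
  rating_panel(segments, scale_max = 4, raters = raters, emotions = emotions)
}

# segment end-points at 3-10 s spacing within a clip
segment_ends <- function(onset, offset, rng) {
  ends <- numeric(0)
  t <- onset
  repeat {
    t <- t + rng$runif(1, 3, 10)
    if (t >= offset) break
    ends <- c(ends, t)
  }
  ends
}

# an emotion episode of 20-100 s within a clip: zero outside the episode,
# a piecewise-linear walk inside. Whole-clip occupancy would leave the
# regressor autocorrelated far beyond realistic event lengths.
episode_profile <- function(c_on, c_off, rng) {
  len <- rng$runif(1, 20, 100)
  start <- c_on + rng$runif(1) * max(c_off - c_on - len, 0)
  stop_ <- min(start + len, c_off)
  inner <- segment_ends(start, stop_, rng)
  if (length(inner) == 0L) inner <- (start + stop_) / 2
  # zero anchor at episode start, walk inside, return to zero at the end
  list(ends = c(start, inner, stop_),
       vals = c(0, walk_profile(length(inner), rng), 0))
}

# mixture of two piecewise-linear episode profiles at weight w on the union
# of their breakpoints; both components live in [0, 4] so the mixture does
mix_profiles <- function(a, b, w, c_on) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (w >= 1) b <- NULL
  if (w <= 0) a <- NULL
  if (is.null(a) && is.null(b)) return(NULL)
  grid <- sort(unique(c(a$ends, b$ends)))
  eval_prof <- function(p, t) {
    if (is.null(p)) return(numeric(length(t)))
    xs <- c(c_on, p$ends); ys <- c(0, p$vals)
    keep <- !duplicated(xs, fromLast = TRUE)   # episode may start at c_on
    stats::approx(xs[keep], ys[keep], xout = t, rule = 2)$y
  }
  vals <- w * eval_prof(a, grid) + (1 - w) * eval_prof(b, grid)
  list(ends = grid, vals = vals)
}

#' Generate ground-truth linear weights
#'
#' @param spec A `simulation_spec`.
#' @param conditions Character vector of condition (regressor) labels.
#' @return List with `beta` (ROI x condition, standard normal entries with
#'   `beta_sparsity` of them zeroed) and `reliable_mask` (emotion x task
#'   logical with exactly `n_reliable` reliable emotions per task).
#' @export
generate_ground_truth <- function(spec, conditions = emotion_names(spec)) {
  rng <- local_rng(spec$rng_seed + 303L)
  beta <- matrix(rng$rnorm(spec$n_rois * length(conditions)),
                 spec$n_rois, length(conditions),
                 dimnames = list(sprintf("roi%03d", seq_len(spec$n_rois)),
                                 conditions))
  n_zero <- round(spec$beta_sparsity * length(beta))
  if (n_zero > 0)
    beta[rng$sample(length(beta), n_zero)] <- 0
  mask <- matrix(FALSE, spec$n_emotions, 2,
                 dimnames = list(emotion_names(spec),
                                 c("perceived", "felt")))
  mask[seq_len(spec$n_reliable), ] <- TRUE
  list(beta = beta, reliable_mask = mask,
       noise = list(snr = spec$snr, ar = spec$ar_coefficient))
}

# stationary AR(1) series with unit marginal sd
ar1_series <- function(n, ar, rng) {
  w <- rng$rnorm(n)
  if (ar == 0) return(w)
  as.numeric(stats::filter(w * sqrt(1 - ar^2), ar, method = "recursive",
                           init = rng$rnorm(1)))
}

#' Generate a synthetic BOLD ROI dataset from a design and ground truth
#'
#' Forward model per participant `p` and ROI `r`:
#' `y = baseline + X beta_p_r + AR(1) noise + linear drift + scaled motion
#' confounds`, where the participant's weights
#' `beta_p = beta (1 + gain_p) + tau G_p` combine the group weights with a
#' multiplicative gain and additive individual deviations (`G_p` standard
#' normal, `tau = participant_beta_sd * sd` of the non-zero group weights).
#' The noise sd is set per ROI so that `sd(group signal) / sd(noise) = snr`.
#' Confound channels (white matter, CSF, six motion series) are returned
#' alongside the signals.
#'
#' @param spec A `simulation_spec`.
#' @param designs List per run of `emotion_design`s (or plain time-by-
#'   condition matrices) on the spec's TR grid.
#' @param truth Ground truth from [generate_ground_truth()]; its `beta`
#'   columns must match the design conditions.
#' @return A `roi_dataset` with `truth` attached.
#' @export
generate_bold_dataset <- function(spec, designs,
                                  truth = generate_ground_truth(
                                    spec, design_conditions(designs))) {
  X_run <- lapply(designs, function(d)
    if (inherits(d, "emotion_design")) d$matrix else as.matrix(d))
  if (ncol(truth$beta) != ncol(X_run[[1]]))
    stop("ground-truth beta has ", ncol(truth$beta),
         " conditions but the design has ", ncol(X_run[[1]]), call. = FALSE)
  if (spec$snr == 0 && any(truth$beta != 0))
    stop("snr = 0 with non-zero beta leaves the noise scale undefined",
         call. = FALSE)
  rng <- local_rng(spec$rng_seed + 404L)
  S_run <- lapply(X_run, function(X) X %*% t(truth$beta))  # time x roi
  sd_sig <- apply(do.call(rbind, S_run), 2, stats::sd)
  sd_noise <- if (is.infinite(spec$snr)) rep(0, spec$n_rois) else {
    s <- sd_sig / spec$snr
    s[sd_sig == 0] <- 1
    s
  }
  gains <- if (spec$participant_gain_sd > 0)
    rng$rnorm(spec$n_participants, 0, spec$participant_gain_sd)
  else rep(0, spec$n_participants)
  nonzero <- truth$beta[truth$beta != 0]
  tau <- if (length(nonzero) > 0L && spec$participant_beta_sd > 0)
    spec$participant_beta_sd * sqrt(mean(nonzero^2)) else 0
  nT <- spec$n_timepoints_per_run
  participants <- sprintf("sub%02d", seq_len(spec$n_participants))
  signals <- vector("list", spec$n_participants)
  confounds <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    sig_p <- vector("list", spec$n_runs)
    conf_p <- vector("list", spec$n_runs)
    beta_p <- truth$beta * (1 + gains[p])
    if (tau > 0)
      beta_p <- beta_p + tau * matrix(rng$rnorm(length(beta_p)),
                                      nrow(beta_p), ncol(beta_p))
    Sp_run <- if (tau > 0 || gains[p] != 0)
      lapply(X_run, function(X) X %*% t(beta_p)) else S_run
    for (run in seq_len(spec$n_runs)) {
      # stationary autocorrelated drift plus scan-to-scan jitter; a
      # random-walk model would dominate the nuisance projection at all
      # low frequencies
      motion <- vapply(1:6, function(i)
        0.2 * ar1_series(nT, 0.6, rng) + 0.05 * rng$rnorm(nT), numeric(nT))
      wm <- ar1_series(nT, spec$ar_coefficient, rng)
      csf <- ar1_series(nT, spec$ar_coefficient, rng)
      conf <- cbind(wm = wm, csf = csf, motion)
      colnames(conf) <- c("wm", "csf", paste0("motion", 1:6))
      y <- Sp_run[[run]]
      if (any(sd_noise > 0)) {
        noise <- vapply(seq_len(spec$n_rois), function(rr)
          ar1_series(nT, spec$ar_coefficient, rng) * sd_noise[rr],
          numeric(nT))
        y <- y + noise
      }
      if (spec$drift_amplitude > 0) {
        slopes <- rng$rnorm(spec$n_rois, 0, spec$drift_amplitude) * sd_noise
        y <- y + outer(seq(-0.5, 0.5, length.out = nT), slopes)
      }
      if (spec$motion_weight > 0) {
        W <- matrix(rng$rnorm(6 * spec$n_rois, 0, spec$motion_weight),
                    6, spec$n_rois) * rep(sd_noise, each = 6)
        y <- y + scale(motion, scale = FALSE) %*% W
      }
      y <- y + spec$baseline
      colnames(y) <- rownames(truth$beta)
      sig_p[[run]] <- y
      conf_p[[run]] <- conf
    }
    signals[[p]] <- sig_p
    confounds[[p]] <- conf_p
  }
  truth$participant_gain <- gains
  roi_dataset(signals, confounds, rownames(truth$beta), participants,
              seq_len(spec$n_runs), truth = truth)
}

design_conditions <- function(designs) {
  d <- designs[[1]]
  if (inherits(d, "emotion_design")) d$emotions else
    colnames(d) %||% sprintf("cond%02d", seq_len(ncol(as.matrix(d))))
}

#' Generate a pure-noise (null) dataset
#'
#' A dataset with all ground-truth weights at zero: AR(1) noise, drift and
#' confounds only. Used to measure the false-positive rate of every
#' inference stage.
#'
#' @param spec A `simulation_spec`.
#' @param designs Optional designs defining the condition labels of the
#'   (all-zero) ground-truth beta.
#' @return A `roi_dataset` whose `truth$beta` is identically zero.
#' @export
generate_null_dataset <- function(spec, designs = NULL) {
  conds <- if (is.null(designs)) emotion_names(spec) else
    design_conditions(designs)
  truth <- generate_ground_truth(spec, conds)
  truth$beta[] <- 0
  if (is.null(designs)) {
    nT <- spec$n_timepoints_per_run
    designs <- replicate(spec$n_runs,
                         matrix(0, nT, length(conds),
                                dimnames = list(NULL, conds)),
                         simplify = FALSE)
  }
  generate_bold_dataset(spec, designs, truth)
}

#' Simulate a full synthetic study
#'
#' Chains the generators end to end: run manifests, rating panel, TR grids
#' and HRF-convolved designs for both tasks, ground-truth weights for the
#' driving task, and the BOLD dataset.
#'
#' @param spec A `simulation_spec`.
#' @param kernel HRF kernel (defaults to the package default at the spec's
#'   TR).
#' @param driving_task Task whose design drives the synthetic BOLD signal.
#' @return List with `spec`, `manifests`, `panel`, `grids`, `designs`
#'   (per task), `truth` and `dataset`.
#' @export
simulate_study <- function(spec = simulation_spec(),
                           kernel = hrf_kernel(tr = spec$tr_seconds),
                           driving_task = "perceived") {
  manifests <- generate_run_manifests(spec)
  panel <- generate_rating_panel(spec, manifests)
  built <- build_all_designs(panel, manifests, kernel)
  truth <- generate_ground_truth(spec)
  dataset <- generate_bold_dataset(spec, built$designs[[driving_task]], truth)
  list(spec = spec, manifests = manifests, panel = panel,
       grids = built$grids, designs = built$designs, truth = truth,
       dataset = dataset, driving_task = driving_task)
}
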