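# Small synthetic fixtures shared across test files. Everything is built in
# code; sizes are kept small so the whole suite stays fast.

toy_panel <- function() {
  rating_panel(data.frame(
    rater = c("r1", "r1", "r1"),
    run = 1L, clip = "c1", task = "perceived",
    emotion = "joy",
    onset_s = c(0, 4, 8), offset_s = c(4, 8, 12),
    intensity = c(1, 3, 2)))
}

toy_manifest <- function(n_timepoints = 10L, tr = 2.4,
                         clips = data.frame(clip = "c1", onset_s = 0,
                                            offset_s = 12)) {
  run_manifest(1L, clips, n_timepoints = n_timepoints, tr_seconds = tr)
}

# a grid built directly from per-rater series matrices (one task)
grid_from_series <- function(series_by_task, tr = 1) {
  emotions <- dimnames(series_by_task[[1]])[[2]]
  raters <- dimnames(series_by_task[[1]])[[3]]
  structure(list(run_id = 1L, tr = tr,
                 times = (seq_len(dim(series_by_task[[1]])[1]) - 1) * tr,
                 emotions = emotions, raters = raters,
                 series = series_by_task),
            class = "rating_grid")
}

make_series_array <- function(mat_list, emotions = "e1") {
  # mat_list: list of time x rater matrices, one per emotion
  nt <- nrow(mat_list[[1]]); nr <- ncol(mat_list[[1]])
  arr <- array(0, c(nt, length(mat_list), nr),
               dimnames = list(NULL, emotions,
                               sprintf("r%d", seq_len(nr))))
  for (e in seq_along(mat_list)) arr[, e, ] <- mat_list[[e]]
  arr
}

small_spec <- function(...) {
  args <- list(n_raters = 5L, n_emotions = 6L, n_reliable = 4L, n_runs = 3L,
               n_timepoints_per_run = 150L, n_participants = 5L,
               n_rois = 10L, snr = 5, rng_seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(simulation_spec, args)
}

# dataset with known beta on a simple random design, no confound leakage
quick_study <- function(spec = small_spec(), ...) {
  simulate_study(spec, ...)
}

# direct normal-equations solve used as the least-squares oracle
ne_solve <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(as.matrix(Y), 2,
                                              colMeans(as.matrix(Y)))
  solve(crossprod(Xc), crossprod(Xc, Yc))
}

synthetic_emotion_names <- function(spec)
  sprintf("emotion%02d", seq_len(spec$n_emotions))
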