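#' Interpolate sparse segment ratings onto the TR grid of a run
#'
#' Ratings are collected as intensities attached to short segment end-points
#' within each movie clip. Within a clip the continuous rating trace is the
#' piecewise-linear curve through the successive end-points, anchored at zero
#' at the clip's start (every scene begins emotionally "blank"); after the
#' last end-point the trace is held constant to the clip's end. Traces are
#' never interpolated across clip boundaries. The trace is sampled at the TR
#' grid's nominal times `t_i = i * TR` (left-edge convention).
#'
#' @param panel A `rating_panel`.
#' @param manifest A `run_manifest` for the run to grid.
#' @param tr Sampling interval in seconds.
#' @return An object of class `rating_grid`: per task, a
#'   time-by-emotion-by-rater array of non-negative intensities.
#' @export
interpolate_to_grid <- function(panel, manifest, tr = manifest$tr_seconds) {
  stopifnot(inherits(panel, "rating_panel"), inherits(manifest, "run_manifest"))
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  times <- (seq_len(manifest$n_timepoints) - 1L) * tr
  emotions <- panel$emotions
  raters <- panel$raters
  seg <- panel$segments[panel$segments$run == manifest$run_id, , drop = FALSE]

  series <- lapply(panel$tasks, function(task) {
    arr <- array(0, dim = c(length(times), length(emotions), length(raters)),
                 dimnames = list(NULL, emotions, raters))
    st <- seg[seg$task == task, , drop = FALSE]
    if (!nrow(st)) return(arr)
    key <- interaction(st$emotion, st$rater, st$clip, drop = TRUE)
    for (g in split(seq_len(nrow(st)), key)) {
      s <- st[g, , drop = FALSE]
      ci <- match(s$clip[1L], manifest$clips$clip)
      if (is.na(ci))
        stop("segment references unknown clip '", s$clip[1L], "' in run ",
             manifest$run_id, call. = FALSE)
      c_on <- manifest$clips$onset_s[ci]
      c_off <- manifest$clips$offset_s[ci]
      if (any(s$onset_s < c_on - 1e-9) || any(s$offset_s > c_off + 1e-9))
        stop(sprintf("segment outside clip bounds [%g, %g] in run %s, clip %s",
                     c_on, c_off, manifest$run_id, s$clip[1L]), call. = FALSE)
      s <- s[order(s$offset_s), , drop = FALSE]
      # control points: zero anchor at clip start, then segment end-points
      x <- c(c_on, s$offset_s)
      y <- c(0, s$intensity)
      keep <- !duplicated(x, fromLast = TRUE)  # later end-point wins on ties
      x <- x[keep]; y <- y[keep]
      idx <- which(times >= c_on - 1e-9 & times < c_off - 1e-9)
      if (!length(idx)) next
      vals <- if (length(x) == 1L) rep(y, length(idx)) else
        stats::approx(x, y, xout = times[idx], rule = 2)$y
      e <- match(as.character(s$emotion[1L]), emotions)
      r <- match(as.character(s$rater[1L]), raters)
      arr[idx, e, r] <- arr[idx, e, r] + vals
    }
    arr
  })
  names(series) <- panel$tasks
  structure(list(run_id = manifest$run_id, tr = tr, times = times,
                 emotions = emotions, raters = raters, series = series),
            class = "rating_grid")
}

# causal discrete convolution truncated to the input length
convolve_causal <- function(x, h) {
  n <- length(x)
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq_len(n)]
}

#' Build an HRF-convolved emotion design matrix for one run
#'
#' Applies the causal discrete convolution of each emotion's TR-gridded
#' rating series with the hemodynamic kernel, truncated to the run length.
#' By default rater series are averaged before convolution (the group-level
#' "emotion model"); per-rater designs are kept for reliability analyses.
#' Columns are left un-demeaned: centering belongs to the model fit.
#'
#' @param grid A `rating_grid` from [interpolate_to_grid()].
#' @param kernel An `hrf_kernel` on the same TR.
#' @param task Which task's series to convolve, `"perceived"` or `"felt"`.
#' @param aggregate `"mean"` (average raters first, the default) or
#'   `"per-rater"` (convolve each rater's series, returning a 3-d array).
#' @return An object of class `emotion_design` whose `matrix` is
#'   time-by-emotion (or time-by-emotion-by-rater).
#' @export
build_design <- function(grid, kernel, task = grid$tasks %||% names(grid$series)[1],
                         aggregate = c("mean", "per-rater")) {
  stopifnot(inherits(grid, "rating_grid"), inherits(kernel, "hrf_kernel"))
  aggregate <- match.arg(aggregate)
  task <- match.arg(task, names(grid$series))
  if (abs(kernel$tr - grid$tr) > 1e-9)
    stop(sprintf("kernel TR (%g s) does not match grid TR (%g s)",
                 kernel$tr, grid$tr), call. = FALSE)
  arr <- grid$series[[task]]
  h <- kernel$samples
  if (aggregate == "mean") {
    x <- apply(arr, c(1, 2), mean)
    m <- apply(x, 2, convolve_causal, h = h)
    dimnames(m) <- list(NULL, grid$emotions)
  } else {
    m <- array(0, dim = dim(arr), dimnames = dimnames(arr))
    for (r in seq_len(dim(arr)[3])) {
      x <- arr[, , r, drop = FALSE]
      dim(x) <- dim(arr)[1:2]
      m[, , r] <- apply(x, 2, convolve_causal, h = h)
    }
  }
  structure(list(run_id = grid$run_id, task = task, tr = grid$tr,
                 matrix = m, emotions = grid$emotions,
                 hrf_params = kernel[c("shape", "scale", "length_s",
                                       "normalization")],
                 aggregate = aggregate),
            class = "emotion_design")
}

#' @export
print.emotion_design <- function(x, ...) {
  cat(sprintf("Emotion design: run %s, task %s, %d timepoints x %d emotions (%s)\n",
              x$run_id, x$task, dim(x$matrix)[1], length(x$emotions),
              x$aggregate))
  invisible(x)
}

#' Grid and convolve a full rating panel
#'
#' Convenience wrapper running [interpolate_to_grid()] and [build_design()]
#' over every run and task.
#'
#' @param panel A `rating_panel`.
#' @param manifests List of `run_manifest`s, one per run.
#' @param kernel An `hrf_kernel`.
#' @return List with `grids` (per run) and `designs` (per task, per run).
#' @export
build_all_designs <- function(panel, manifests, kernel) {
  grids <- lapply(manifests, function(mf)
    interpolate_to_grid(panel, mf, tr = kernel$tr))
  names(grids) <- vapply(manifests, function(mf) as.character(mf$run_id), "")
  designs <- lapply(panel$tasks, function(task)
    lapply(grids, build_design, kernel = kernel, task = task))
  names(designs) <- panel$tasks
  list(grids = grids, designs = designs)
}
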