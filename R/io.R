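#' Construct a rating panel from a segment table
#'
#' A rating panel holds the raw dynamic emotion ratings: sparse piecewise
#' segments per rater, run, clip, task and emotion. A segment's `offset_s` is
#' the rating end-point; intensities are on the 0..`rating_scale_max` scale.
#' (rater, emotion) combinations absent from the table stand for all-zero
#' ratings.
#'
#' @param segments Data frame with columns `rater`, `run`, `clip`, `task`,
#'   `emotion`, `onset_s`, `offset_s`, `intensity`.
#' @param scale_max Maximum of the rating scale.
#' @param raters,emotions Optional full rosters (supersets of the values seen
#'   in `segments`), so that silent raters/emotions are representable.
#' @return An object of class `rating_panel`.
#' @export
rating_panel <- function(segments, scale_max = 4,
                         raters = NULL, emotions = NULL) {
  needed <- c("rater", "run", "clip", "task", "emotion",
              "onset_s", "offset_s", "intensity")
  missing_cols <- setdiff(needed, names(segments))
  if (length(missing_cols))
    stop("rating table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  segments <- as.data.frame(segments)[needed]
  bad_task <- setdiff(unique(segments$task), c("perceived", "felt"))
  if (length(bad_task))
    stop("unknown task label(s): ", paste(bad_task, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(segments$intensity)))
    stop("non-finite intensity values in rating table", call. = FALSE)
  out_of_range <- segments$intensity < 0 | segments$intensity > scale_max
  if (any(out_of_range))
    stop(sprintf("intensity out of range [0, %g] on %d row(s), first at row %d",
                 scale_max, sum(out_of_range), which(out_of_range)[1L]),
         call. = FALSE)
  structure(list(
    segments = segments,
    raters = sort(unique(c(as.character(segments$rater), raters))),
    runs = sort(unique(segments$run)),
    tasks = intersect(c("perceived", "felt"), unique(segments$task)),
    emotions = sort(unique(c(as.character(segments$emotion), emotions))),
    scale_max = scale_max
  ), class = "rating_panel")
}

#' @export
print.rating_panel <- function(x, ...) {
  cat(sprintf(
    "Rating panel: %d segments | %d raters, %d emotions, %d runs, tasks: %s\n",
    nrow(x$segments), length(x$raters), length(x$emotions), length(x$runs),
    paste(x$tasks, collapse = "/")))
  invisible(x)
}

#' Read dynamic emotion ratings from a TSV file
#'
#' @param path Path to a tab-separated file with header columns `rater`,
#'   `run`, `clip`, `task`, `emotion`, `onset_s`, `offset_s`, `intensity`.
#' @param config A [pipeline_config()]; supplies the rating scale maximum.
#' @return A `rating_panel`.
#' @export
read_ratings <- function(path, config = pipeline_config()) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse rating file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (col in c("onset_s", "offset_s", "intensity")) {
    if (!col %in% names(tab)) next
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1L]
      stop(sprintf("non-numeric value in column '%s' at data line %d of %s",
                   col, bad, path), call. = FALSE)
    }
  }
  rating_panel(tab, scale_max = config$rating_scale_max)
}

#' Write a rating panel to a TSV file
#'
#' @param panel A `rating_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(panel, path) {
  stopifnot(inherits(panel, "rating_panel"))
  write_tsv(panel$segments, path)
  invisible(path)
}

#' Read ROI time series and confounds for one run
#'
#' @param path TSV of the time-by-ROI signal matrix with ROI labels as header.
#' @param confounds_path TSV of confounds with columns `wm`, `csf`,
#'   `motion1`..`motion6` (extra columns are kept).
#' @param manifest Optional `run_manifest`; when supplied the number of rows
#'   must equal its `n_timepoints`.
#' @return A list with numeric matrices `signals` and `confounds` plus
#'   `roi_labels`, suitable as one run of a [roi_dataset()].
#' @export
read_roi_timeseries <- function(path, confounds_path, manifest = NULL) {
  sig <- utils::read.delim(path, check.names = FALSE)
  conf <- utils::read.delim(confounds_path, check.names = FALSE)
  sig_m <- as.matrix(sig)
  if (!is.numeric(sig_m)) {
    bad <- which(!vapply(sig, is.numeric, logical(1)))[1L]
    stop("non-numeric ROI column '", names(sig)[bad], "' in ", path,
         call. = FALSE)
  }
  conf_m <- as.matrix(conf)
  if (!is.numeric(conf_m))
    stop("non-numeric confound column in ", confounds_path, call. = FALSE)
  if (nrow(sig_m) != nrow(conf_m))
    stop(sprintf(
      "signal/confound row mismatch: %d timepoints in %s vs %d in %s",
      nrow(sig_m), path, nrow(conf_m), confounds_path), call. = FALSE)
  needed <- c("wm", "csf", paste0("motion", 1:6))
  missing_cols <- setdiff(needed, colnames(conf_m))
  if (length(missing_cols))
    stop("confound table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(manifest) && nrow(sig_m) != manifest$n_timepoints)
    stop(sprintf("run %s expects %d timepoints, file has %d",
                 manifest$run_id, manifest$n_timepoints, nrow(sig_m)),
         call. = FALSE)
  list(signals = sig_m, confounds = conf_m, roi_labels = colnames(sig_m))
}

#' ROI dataset container
#'
#' Per-participant, per-run ROI time-series matrices with aligned confounds,
#' and (for synthetic data) the generative ground truth.
#'
#' @param signals Nested list `signals[[participant]][[run]]`, each a
#'   time-by-ROI numeric matrix with identical ROI columns.
#' @param confounds Same shape, time-by-confound matrices (`wm`, `csf`,
#'   `motion1`..`motion6`).
#' @param roi_labels Character vector of ROI labels.
#' @param participants,runs Identifiers.
#' @param truth Optional ground-truth list (see [generate_bold_dataset()]).
#' @return An object of class `roi_dataset`.
#' @export
roi_dataset <- function(signals, confounds, roi_labels, participants, runs,
                        truth = NULL) {
  stopifnot(length(signals) == length(participants),
            length(confounds) == length(participants))
  for (p in seq_along(signals)) {
    stopifnot(length(signals[[p]]) == length(runs))
    for (r in seq_along(signals[[p]])) {
      if (nrow(signals[[p]][[r]]) != nrow(confounds[[p]][[r]]))
        stop("signal/confound row mismatch for participant ", participants[p],
             " run ", runs[r], call. = FALSE)
    }
  }
  structure(list(signals = signals, confounds = confounds,
                 roi_labels = roi_labels, participants = participants,
                 runs = runs, truth = truth),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  nt <- nrow(x$signals[[1]][[1]])
  cat(sprintf("ROI dataset: %d participants x %d runs x %d timepoints x %d ROIs%s\n",
              length(x$participants), length(x$runs), nt, length(x$roi_labels),
              if (is.null(x$truth)) "" else " (synthetic, ground truth attached)"))
  invisible(x)
}

# ---- TSV / JSON helpers (tab-separated, UTF-8, '.' decimal) ----------------

write_tsv <- function(x, path, row_names = FALSE) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# square/rectangular numeric matrix with labels on both axes
write_tsv_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m) %||% seq_len(nrow(m)),
                   m, check.names = FALSE)
  write_tsv(df, path)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write stage results to a report directory
#'
#' Serializes any collection of pipeline outputs as tab-separated matrices
#' plus a JSON summary echoing the configuration, seed and thresholds.
#'
#' @param results Named list; matrices/data frames become `<name>.tsv`,
#'   scalars and small lists are collected into `summary.json`.
#' @param path Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop("cannot create report directory ", path, call. = FALSE)
  written <- character()
  summary <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) {
      f <- file.path(path, paste0(nm, ".tsv"))
      write_tsv_matrix(x, f)
      written <- c(written, f)
    } else if (is.data.frame(x)) {
      f <- file.path(path, paste0(nm, ".tsv"))
      write_tsv(x, f)
      written <- c(written, f)
    } else {
      summary[[nm]] <- x
    }
  }
  f <- file.path(path, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  written <- c(written, f)
  invisible(written)
}
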