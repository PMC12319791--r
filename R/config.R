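#' Pipeline configuration
#'
#' Bundles the acquisition and analysis parameters shared by all pipeline
#' stages: the fMRI sampling interval (TR), run structure, the bandpass
#' passband matched to the slow dynamics of movie-evoked emotions, the rating
#' scale, and the sizes and seeds of the permutation nulls.
#'
#' @param tr_seconds Sampling interval of the BOLD series in seconds.
#' @param n_runs Number of runs in the experiment.
#' @param n_train_runs Number of runs used for training in the between-run
#'   cross-validation; the remaining runs are the test set.
#' @param passband_hz Length-2 numeric, lower and upper passband edge in Hz.
#' @param rating_scale_max Maximum of the emotion intensity rating scale
#'   (ratings run from 0 = not at all to this value = extremely much).
#' @param n_permutations Number of iterations for label-permutation nulls.
#' @param n_shift_null Number of circular-shift surrogate regressors per
#'   emotion used by the single-emotion mapping null.
#' @param min_shift_samples Minimum circular shift, in samples, forward or
#'   backward.
#' @param alpha Family-wise error rate controlled by the permutation
#'   thresholds.
#' @param rng_seed Integer seed governing every stochastic stage.
#' @param linkage_cutoff_fraction Dendrogram cut height as a fraction of the
#'   maximum linkage height.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(tr_seconds = 2.4,
                            n_runs = 5L,
                            n_train_runs = 3L,
                            passband_hz = c(0.005, 0.05),
                            rating_scale_max = 4,
                            n_permutations = 1000L,
                            n_shift_null = 100L,
                            min_shift_samples = 20L,
                            alpha = 0.05,
                            rng_seed = 1L,
                            linkage_cutoff_fraction = 0.70) {
  cfg <- list(
    tr_seconds = as.numeric(tr_seconds),
    n_runs = as.integer(n_runs),
    n_train_runs = as.integer(n_train_runs),
    passband_hz = as.numeric(passband_hz),
    rating_scale_max = as.numeric(rating_scale_max),
    n_permutations = as.integer(n_permutations),
    n_shift_null = as.integer(n_shift_null),
    min_shift_samples = as.integer(min_shift_samples),
    alpha = as.numeric(alpha),
    rng_seed = as.integer(rng_seed),
    linkage_cutoff_fraction = as.numeric(linkage_cutoff_fraction)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.finite(cfg$tr_seconds) || cfg$tr_seconds <= 0)
    stop("tr_seconds must be a positive real", call. = FALSE)
  nyquist <- 1 / (2 * cfg$tr_seconds)
  if (length(cfg$passband_hz) != 2L || any(cfg$passband_hz <= 0))
    stop("passband_hz must be two positive frequencies", call. = FALSE)
  if (!(cfg$passband_hz[1] < cfg$passband_hz[2] &&
        cfg$passband_hz[2] < nyquist))
    stop(sprintf(
      "passband must satisfy lower < upper < Nyquist (%.4f Hz)", nyquist),
      call. = FALSE)
  counts <- c(n_runs = cfg$n_runs, n_train_runs = cfg$n_train_runs,
              n_permutations = cfg$n_permutations,
              n_shift_null = cfg$n_shift_null,
              min_shift_samples = cfg$min_shift_samples)
  bad <- names(counts)[counts <= 0L]
  if (length(bad))
    stop("counts must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (cfg$n_train_runs >= cfg$n_runs)
    stop("n_train_runs must be smaller than n_runs", call. = FALSE)
  if (cfg$rating_scale_max <= 0)
    stop("rating_scale_max must be positive", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (cfg$linkage_cutoff_fraction <= 0 || cfg$linkage_cutoff_fraction > 1)
    stop("linkage_cutoff_fraction must lie in (0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Run manifest: clip timing within one run
#'
#' Records the movie-clip boundaries of a run on the continuous time axis.
#' Clips are half-open intervals `[onset_s, offset_s)` in seconds, played back
#' to back without gaps; sample `i` of the TR grid covers
#' `[i * TR, (i + 1) * TR)` with its nominal time at the left edge.
#'
#' @param run_id Identifier of the run.
#' @param clips Data frame with columns `clip`, `onset_s`, `offset_s`;
#'   non-overlapping, ordered intervals.
#' @param n_timepoints Number of TR samples in the run.
#' @param tr_seconds Sampling interval in seconds.
#' @param participants Optional character vector of participant identifiers.
#'
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(run_id, clips, n_timepoints, tr_seconds = 2.4,
                         participants = character()) {
  stopifnot(is.data.frame(clips),
            all(c("clip", "onset_s", "offset_s") %in% names(clips)))
  clips <- clips[order(clips$onset_s), , drop = FALSE]
  if (any(clips$offset_s <= clips$onset_s))
    stop("each clip must have offset_s > onset_s", call. = FALSE)
  if (nrow(clips) > 1L &&
      any(clips$onset_s[-1L] < clips$offset_s[-nrow(clips)]))
    stop("clips overlap in run ", run_id, call. = FALSE)
  run_len <- n_timepoints * tr_seconds
  if (any(clips$onset_s < 0) || any(clips$offset_s > run_len + 1e-9))
    stop("clips must lie within [0, n_timepoints * TR]", call. = FALSE)
  structure(list(run_id = run_id, clips = clips,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = as.numeric(tr_seconds),
                 participants = participants),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Run %s: %d clips, %d timepoints (TR %.2f s)\n",
              x$run_id, nrow(x$clips), x$n_timepoints, x$tr_seconds))
  invisible(x)
}

# TR-grid sample times of a run (left-edge convention)
grid_times <- function(manifest) {
  (seq_len(manifest$n_timepoints) - 1L) * manifest$tr_seconds
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the arguments of [pipeline_config()]; unknown keys other
#' than the `synthetic`, `inputs` and `output` blocks are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `config` (a `pipeline_config`), and the raw
#'   `synthetic`, `inputs` and `output` blocks (possibly `NULL`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  blocks <- c("synthetic", "inputs", "output")
  cfg_keys <- setdiff(names(raw), blocks)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(cfg_keys, known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(pipeline_config, raw[cfg_keys])
  list(config = cfg,
       synthetic = raw$synthetic,
       inputs = raw$inputs,
       output = raw$output)
}
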