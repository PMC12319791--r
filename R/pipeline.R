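#' Run the full analysis pipeline from a configuration file
#'
#' Chains all stages — data simulation (or ingestion), rating reliability,
#' felt/perceived similarity, signal conditioning, cross-validated encoding
#' and decoding with the felt-versus-perceived contrast, single-emotion
#' mapping, and similarity clustering — and writes every stage's output to
#' the report directory as tab-separated matrices plus a JSON summary.
#' Every stochastic stage derives its sub-seed deterministically from
#' `rng_seed`, so identical configurations produce identical outputs.
#'
#' @param config_path Path to a YAML configuration with [pipeline_config()]
#'   keys plus a `synthetic:` block ([simulation_spec()] arguments) and an
#'   `output:` directory.
#' @param verbose Log stage progress via `message()`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config_path, verbose = TRUE) {
  cfgfile <- read_config(config_path)
  cfg <- cfgfile$config
  out_dir <- cfgfile$output %||% "emokinetics_report"
  log <- list()
  say <- function(stage, ...) {
    msg <- sprintf(...)
    log[[length(log) + 1L]] <<- list(stage = stage, detail = msg)
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # ---- inputs ----------------------------------------------------------
  if (!is.null(cfgfile$synthetic)) {
    spec <- stage("simulate", do.call(simulation_spec, cfgfile$synthetic))
    say("simulate", "synthetic study, seed %d: %d raters, %d emotions, %d runs, %d participants, %d ROIs",
        spec$rng_seed, spec$n_raters, spec$n_emotions, spec$n_runs,
        spec$n_participants, spec$n_rois)
    sim <- stage("simulate", simulate_study(
      spec, kernel = hrf_kernel(tr = cfg$tr_seconds)))
    panel <- sim$panel; manifests <- sim$manifests
    grids <- sim$grids; designs <- sim$designs; dataset <- sim$dataset
  } else if (!is.null(cfgfile$inputs)) {
    inp <- cfgfile$inputs
    panel <- stage("read", read_ratings(inp$ratings, cfg))
    manifests <- stage("read", read_manifests(inp$manifest, cfg))
    built <- stage("design", build_all_designs(
      panel, manifests, hrf_kernel(tr = cfg$tr_seconds)))
    grids <- built$grids; designs <- built$designs
    dataset <- stage("read", read_roi_dataset(inp$roi, manifests))
    say("read", "loaded %d rating segments and %d participants",
        nrow(panel$segments), length(dataset$participants))
  } else {
    stop("configuration needs either a 'synthetic' or an 'inputs' block",
         call. = FALSE)
  }

  # ---- rating reliability ---------------------------------------------
  rel <- stage("reliability", {
    tab <- reliability_table(grids)
    reliability_threshold(tab, n_perm = cfg$n_permutations,
                          seed = cfg$rng_seed + 1L,
                          prob = 1 - cfg$alpha)
  })
  say("reliability", "threshold %.4f (seed %d); %d/%d emotions reliable",
      attr(rel, "threshold"), cfg$rng_seed + 1L,
      sum(rel$reliable[rel$task == rel$task[1]]),
      length(unique(rel$emotion)))
  fp <- stage("reliability", felt_perceived_similarity(grids))

  reliable_emotions <- unique(rel$emotion[rel$reliable])
  if (!length(reliable_emotions)) {
    say("reliability", "no emotion passed the gate; retaining all for fitting")
    reliable_emotions <- unique(rel$emotion)
  }
  gated <- lapply(designs, function(run_designs)
    lapply(run_designs, subset_design, keep = reliable_emotions))

  # ---- conditioning ----------------------------------------------------
  filt <- stage("conditioning", design_bandpass(
    sampling_rate_hz = 1 / cfg$tr_seconds, passband_hz = cfg$passband_hz))
  say("conditioning", "FIR order %d: ripple %.3f dB, stopband %.1f dB",
      filt$order, filt$passband_ripple_db, filt$stopband_atten_db)
  dataset <- stage("conditioning", condition_dataset(dataset, filt))
  gated <- stage("conditioning", lapply(gated, filter_designs, spec = filt))

  # ---- cross-validated fits -------------------------------------------
  tasks <- names(gated)
  enc <- lapply(tasks, function(tk) {
    res <- stage("fit", between_run_cv(dataset, gated[[tk]], "encode",
                                       n_train = cfg$n_train_runs))
    say("fit", "encode %s: mean test r %.3f over %d splits", tk,
        mean(res$fit), length(res$splits))
    res
  })
  names(enc) <- tasks
  dec <- lapply(tasks, function(tk) {
    res <- stage("fit", between_run_cv(
      dataset, gated[[tk]], "decode", n_train = cfg$n_train_runs,
      n_perm = cfg$n_permutations, seed = cfg$rng_seed + 2L,
      alpha = cfg$alpha))
    say("fit", "decode %s: %d/%d emotions above the shuffled-label null",
        tk, sum(res$significant), length(res$fit))
    res
  })
  names(dec) <- tasks
  contrast <- NULL
  if (all(c("felt", "perceived") %in% tasks)) {
    contrast <- stage("contrast", contrast_tasks(
      enc[["felt"]]$fit, enc[["perceived"]]$fit,
      n_perm = cfg$n_permutations, seed = cfg$rng_seed + 3L,
      alpha = cfg$alpha))
    say("contrast", "felt vs perceived: |t| > %.3f, %d ROIs significant",
        contrast$threshold, sum(contrast$mask != 0))
  }

  # ---- single-emotion mapping -----------------------------------------
  maps <- lapply(tasks, function(tk) {
    res <- stage("map", shiftnull_fwer_test(
      dataset, gated[[tk]], n_shift = cfg$n_shift_null,
      n_perm = cfg$n_permutations, min_shift = cfg$min_shift_samples,
      seed = cfg$rng_seed + 4L, alpha = cfg$alpha))
    say("map", "%s: |t| > %.3f, %d significant run-average cells", tk,
        res$threshold, sum(res$mask_avg != 0))
    res
  })
  names(maps) <- tasks

  # ---- similarity and clustering --------------------------------------
  splits <- enumerate_run_splits(cfg$n_runs, cfg$n_train_runs)
  sim_neural <- stage("cluster", cluster_similarity(
    cross_run_similarity(lapply(maps, `[[`, "r"), splits),
    cutoff_fraction = cfg$linkage_cutoff_fraction))
  sim_ratings <- stage("cluster", cluster_similarity(
    rating_similarity(gated),
    cutoff_fraction = cfg$linkage_cutoff_fraction))
  say("cluster", "neural: %d clusters; ratings: %d clusters",
      max(sim_neural$clusters), max(sim_ratings$clusters))

  # ---- report ----------------------------------------------------------
  results <- list(
    reliability = as.data.frame(rel),
    reliability_null = data.frame(null_combined = attr(rel, "null")),
    felt_perceived_similarity = fp,
    filter_taps = data.frame(tap = seq_along(filt$coefficients),
                             coefficient = filt$coefficients),
    filter_response = data.frame(freq_hz = filt$freqs,
                                 magnitude = filt$magnitude),
    similarity_neural = sim_neural$matrix,
    similarity_ratings = sim_ratings$matrix,
    linkage_neural = linkage_table(sim_neural$tree),
    clusters_neural = data.frame(condition = sim_neural$conditions,
                                 cluster = sim_neural$clusters),
    clusters_ratings = data.frame(condition = sim_ratings$conditions,
                                  cluster = sim_ratings$clusters),
    config = unclass(cfg),
    stages = log
  )
  for (tk in tasks) {
    results[[paste0("beta_", tk)]] <- enc[[tk]]$beta
    results[[paste0("cv_fit_between_runs_", tk)]] <- enc[[tk]]$fit
    results[[paste0("cv_fit_decode_", tk)]] <-
      data.frame(emotion = names(dec[[tk]]$fit), r = dec[[tk]]$fit,
                 threshold = dec[[tk]]$threshold,
                 significant = dec[[tk]]$significant)
    results[[paste0("emotion_roi_t_", tk)]] <- maps[[tk]]$t_avg
    results[[paste0("emotion_roi_mask_", tk)]] <- maps[[tk]]$mask_avg
    results[[paste0("map_threshold_", tk)]] <- maps[[tk]]$threshold
  }
  if (!is.null(contrast)) {
    results$contrast_t <- data.frame(roi = names(contrast$t) %||%
                                       dataset$roi_labels,
                                     t = contrast$t, mask = contrast$mask)
    results$contrast_threshold <- contrast$threshold
  }
  files <- write_report(results, out_dir)
  say("report", "wrote %d files to %s", length(files), out_dir)
  invisible(out_dir)
}

# keep only the given emotions (columns) of a design
subset_design <- function(design, keep) {
  keep <- intersect(design$emotions, keep)
  design$matrix <- design$matrix[, keep, drop = FALSE]
  design$emotions <- keep
  design
}

# hclust merge table in left/right/height/size form
linkage_table <- function(tree) {
  n <- nrow(tree$merge) + 1L
  sizes <- integer(n - 1L)
  for (v in seq_len(n - 1L)) {
    a <- tree$merge[v, 1]; b <- tree$merge[v, 2]
    sizes[v] <- (if (a < 0) 1L else sizes[a]) + (if (b < 0) 1L else sizes[b])
  }
  data.frame(left = tree$merge[, 1], right = tree$merge[, 2],
             height = tree$height, size = sizes)
}

# manifest TSV: run, clip, onset_s, offset_s, n_timepoints
read_manifests <- function(path, cfg) {
  tab <- utils::read.delim(path)
  lapply(split(tab, tab$run), function(df)
    run_manifest(df$run[1],
                 df[, c("clip", "onset_s", "offset_s")],
                 n_timepoints = df$n_timepoints[1],
                 tr_seconds = cfg$tr_seconds))
}

# roi input block: list of {participant, run, signals, confounds} entries
read_roi_dataset <- function(entries, manifests) {
  parts <- unique(vapply(entries, `[[`, "", "participant"))
  runs <- vapply(manifests, function(m) as.character(m$run_id), "")
  signals <- confounds <- stats::setNames(
    replicate(length(parts), vector("list", length(runs)), simplify = FALSE),
    parts)
  labels <- NULL
  for (e in entries) {
    ri <- match(as.character(e$run), runs)
    one <- read_roi_timeseries(e$signals, e$confounds, manifests[[ri]])
    signals[[e$participant]][[ri]] <- one$signals
    confounds[[e$participant]][[ri]] <- one$confounds
    labels <- labels %||% one$roi_labels
  }
  roi_dataset(signals, confounds, labels, parts, runs)
}

#' Export a dendrogram in Newick format
#'
#' @param tree An `hclust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export needs the 'ape' package", call. = FALSE)
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
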