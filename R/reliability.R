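#' Rater coverage of each emotion in one run
#'
#' Fraction of raters that gave a non-zero rating for the emotion at any
#' time point of the run, per task.
#'
#' @param grid A `rating_grid` for one run.
#' @return Matrix emotion-by-task of fractions in `[0, 1]`.
#' @export
rater_coverage <- function(grid) {
  stopifnot(inherits(grid, "rating_grid"))
  n_raters <- length(grid$raters)
  if (n_raters == 0L) stop("panel contains no raters", call. = FALSE)
  component_matrix(grid, function(em) mean(apply(em > 0, 2, any)))
}

# evaluate f on each emotion's time-by-rater slice, per task
component_matrix <- function(grid, f) {
  out <- vapply(grid$series, function(arr) {
    vapply(seq_along(grid$emotions), function(e) {
      em <- arr[, e, , drop = FALSE]
      dim(em) <- dim(arr)[c(1, 3)]
      f(em)
    }, numeric(1))
  }, numeric(length(grid$emotions)))
  matrix(out, nrow = length(grid$emotions),
         dimnames = list(grid$emotions, names(grid$series)))
}

#' Time-point coverage of each emotion in one run
#'
#' Fraction of TR samples at which at least one rater gave a non-zero
#' rating, per task.
#'
#' @param grid A `rating_grid` for one run.
#' @return Matrix emotion-by-task of fractions in `[0, 1]`.
#' @export
timepoint_coverage <- function(grid) {
  stopifnot(inherits(grid, "rating_grid"))
  if (length(grid$times) == 0L) stop("empty time grid", call. = FALSE)
  component_matrix(grid, function(em) mean(apply(em > 0, 1, any)))
}

#' Mean pairwise intersubject correlation of rating series in one run
#'
#' Pearson correlation of the TR-gridded (pre-convolution) rating series
#' between every unordered pair of raters, averaged per emotion and task.
#' Pairs in which either series is constant have no defined correlation and
#' are dropped from the mean; an emotion with no defined pair scores 0.
#'
#' @param grid A `rating_grid` for one run.
#' @return Matrix emotion-by-task of mean correlations in `[-1, 1]`.
#' @export
pairwise_isc <- function(grid) {
  stopifnot(inherits(grid, "rating_grid"))
  n_raters <- length(grid$raters)
  if (n_raters < 2L)
    stop("at least two raters are required for intersubject correlation",
         call. = FALSE)
  ut <- upper.tri(diag(n_raters))
  component_matrix(grid, function(em) {
    cc <- suppressWarnings(stats::cor(em))  # NA for constant raters
    rs <- cc[ut]
    if (all(is.na(rs))) 0 else mean(rs, na.rm = TRUE)
  })
}

#' Combined reliability: geometric mean of three component measures
#'
#' Joins rater coverage, time-point coverage and mean intersubject
#' correlation into a single value per emotion. All three components live on
#' `[0, 1]`-comparable scales (coverages are fractions; the correlation is
#' clamped at zero before the product so a non-positive component yields a
#' combined value of exactly 0, never a complex or negative number).
#'
#' @param a,b,c Numeric vectors (recycled) of the three components.
#' @return `(a * b * c)^(1/3)` where all components are positive, else 0.
#' @export
combined_reliability <- function(a, b, c) {
  out <- (pmax(a, 0) * pmax(b, 0) * pmax(c, 0))^(1 / 3)
  out[a <= 0 | b <= 0 | c <= 0] <- 0
  out
}

#' Reliability table for all emotions and tasks
#'
#' Computes the three component measures per run, averages them across runs
#' with equal weights, and takes the geometric mean of the run-averaged
#' components. Each emotion's selection value is the larger of its two tasks'
#' combined values, so an emotion consistently rated in at least one task
#' is retained.
#'
#' @param grids List of `rating_grid`s, one per run.
#' @return A data frame of class `reliability_table` with one row per
#'   emotion and task: `pct_raters`, `pct_timepoints`, `mean_isc`,
#'   `combined`, `selection` (per-emotion max over tasks). Reliability flags
#'   are added by [reliability_threshold()].
#' @export
reliability_table <- function(grids) {
  stopifnot(length(grids) >= 1L)
  fns <- list(pct_raters = rater_coverage,
              pct_timepoints = timepoint_coverage,
              mean_isc = pairwise_isc)
  # per_run[[measure]][[run]]: emotion x task matrix
  per_run <- lapply(fns, function(f) lapply(grids, f))
  comp <- lapply(per_run, function(runs) Reduce(`+`, runs) / length(runs))
  emotions <- grids[[1]]$emotions
  tasks <- colnames(comp[[1]])
  tab <- expand.grid(emotion = emotions, task = tasks,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (nm in names(comp))
    tab[[nm]] <- as.vector(comp[[nm]])
  tab$combined <- combined_reliability(tab$pct_raters, tab$pct_timepoints,
                                       tab$mean_isc)
  sel <- tapply(tab$combined, tab$emotion, max)
  tab$selection <- as.numeric(sel[tab$emotion])
  class(tab) <- c("reliability_table", class(tab))
  attr(tab, "per_run") <- per_run
  attr(tab, "tasks") <- tasks
  tab
}

#' Permutation threshold for the combined reliability statistic
#'
#' Chance level of the combined reliability: on each iteration the values of
#' each of the three component measures are shuffled between emotions —
#' independently for each measure, run and task — and the reliability
#' (across-run mean of each component, then geometric mean) is recomputed.
#' The threshold is the 95th percentile of the pooled null values across
#' iterations, emotions and tasks; emotions whose selection value exceeds
#' it are flagged reliable. Shuffling before the across-run average lets
#' the null concentrate around chance-level component combinations instead
#' of reproducing the observed upper tail.
#'
#' For small panels (`method = "exhaustive"`, single run) all distinct
#' permutation triples are enumerated instead of sampled, giving an exact
#' null distribution.
#'
#' @param tab A `reliability_table`.
#' @param n_perm Number of shuffling iterations (ignored for exhaustive).
#' @param seed Integer seed.
#' @param prob Percentile of the pooled null distribution (default 0.95).
#' @param method `"sample"` (Monte Carlo) or `"exhaustive"` (all
#'   permutation triples; single-run panels with few emotions only).
#' @return The input table with `threshold` and `reliable` columns, plus
#'   attributes `threshold` and `null` (the pooled null values).
#' @export
reliability_threshold <- function(tab, n_perm = 1000L, seed = 1L,
                                  prob = 0.95,
                                  method = c("sample", "exhaustive")) {
  stopifnot(inherits(tab, "reliability_table"))
  method <- match.arg(method)
  per_run <- attr(tab, "per_run")
  if (is.null(per_run))
    stop("table lacks per-run components; rebuild with reliability_table()",
         call. = FALSE)
  tasks <- attr(tab, "tasks")
  n_runs <- length(per_run[[1]])
  nE <- length(unique(tab$emotion))

  null_for_perms <- function(perm_fn) {
    # perm_fn(measure, run, task) -> permutation of seq_len(nE)
    vals <- lapply(seq_along(tasks), function(ti) {
      avg <- lapply(names(per_run), function(m) {
        rowMeans(vapply(seq_len(n_runs), function(r)
          per_run[[m]][[r]][perm_fn(m, r, ti), ti], numeric(nE)))
      })
      combined_reliability(avg[[1]], avg[[2]], avg[[3]])
    })
    unlist(vals, use.names = FALSE)
  }

  if (method == "exhaustive") {
    if (n_runs > 1L)
      stop("exhaustive enumeration is supported for single-run panels only",
           call. = FALSE)
    perms <- all_permutations(nE)
    np <- nrow(perms)
    idx <- expand.grid(a = seq_len(np), b = seq_len(np), c = seq_len(np))
    null_pool <- unlist(lapply(seq_len(nrow(idx)), function(i) {
      pm <- list(pct_raters = perms[idx$a[i], ],
                 pct_timepoints = perms[idx$b[i], ],
                 mean_isc = perms[idx$c[i], ])
      null_for_perms(function(m, r, ti) pm[[m]])
    }))
  } else {
    if (n_perm < 20L)
      warning("fewer than 20 permutations: percentile estimate is unstable")
    rng <- local_rng(seed)
    null_pool <- unlist(lapply(seq_len(n_perm), function(it)
      null_for_perms(function(m, r, ti) rng$sample(nE))))
  }
  threshold <- percentile(null_pool, prob)
  tab$threshold <- threshold
  tab$reliable <- tab$selection > threshold
  attr(tab, "threshold") <- threshold
  attr(tab, "null") <- null_pool
  tab
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Temporal similarity of felt and perceived ratings per emotion
#'
#' Pearson correlation between the mean-over-raters felt and perceived
#' rating series of the same emotion, concatenated across runs; the squared
#' correlation is reported as shared variance.
#'
#' @param grids List of `rating_grid`s, one per run; both tasks must be
#'   present.
#' @return Data frame per emotion with `r`, `shared_variance` (r^2), and a
#'   `defined` flag (`FALSE` when either concatenated series is constant, in
#'   which case `r` is `NA`).
#' @export
felt_perceived_similarity <- function(grids) {
  tasks <- names(grids[[1]]$series)
  if (!all(c("perceived", "felt") %in% tasks))
    stop("both perceived and felt series are required", call. = FALSE)
  emotions <- grids[[1]]$emotions
  series <- lapply(c("perceived", "felt"), function(tk) {
    do.call(rbind, lapply(grids, function(g)
      apply(g$series[[tk]], c(1, 2), mean)))
  })
  r <- vapply(seq_along(emotions), function(e) {
    x <- series[[1]][, e]; y <- series[[2]][, e]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  data.frame(emotion = emotions, r = r, shared_variance = r^2,
             defined = !is.na(r))
}

# percentile with linear interpolation between order statistics (type 7),
# fixed package-wide so permutation thresholds are reproducible
percentile <- function(x, prob) {
  unname(stats::quantile(x, probs = prob, type = 7, names = FALSE))
}

# private RNG stream: draws do not disturb (or depend on) the global RNG state
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    sample = function(n, size = n, replace = FALSE)
      with_state(sample.int(n, size = size, replace = replace)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(stats::rbinom(n, size, prob)),
    int_seed = function() with_state(sample.int(.Machine$integer.max, 1L))
  )
}
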