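#' Group-level spatial response pattern per emotion
#'
#' Collapses the per-emotion correlation tensor to one spatial pattern per
#' emotion within a set of runs: the mean over participants and over the
#' runs in the set of the Fisher-z-transformed correlations, per ROI.
#'
#' @param r Participant x ROI x emotion x run correlation tensor from
#'   [emotion_roi_correlation()].
#' @param runs Integer vector of run indices (non-empty).
#' @param use_fisher_z Average on the Fisher-z scale (default).
#' @return Emotion-by-ROI pattern matrix.
#' @export
emotion_pattern <- function(r, runs, use_fisher_z = TRUE) {
  if (!length(runs)) stop("empty run set", call. = FALSE)
  sub <- r[, , , runs, drop = FALSE]
  if (use_fisher_z) sub <- fisher_z(sub)
  pat <- apply(sub, c(3, 2), mean, na.rm = TRUE)  # emotion x ROI
  pat
}

#' Cross-run spatial similarity of emotion response patterns
#'
#' For every train/test partition of the runs, correlates (across ROIs) the
#' response pattern of each condition in the training runs with the pattern
#' of each condition in the non-overlapping test runs, then averages the
#' resulting matrices over all partitions. Comparing patterns only between
#' disjoint run sets avoids the circularity of within-run pattern
#' correlations, which are driven directly by rating correlations. The
#' diagonal is the between-run reliability of each condition's pattern
#' (not forced to 1); the matrix is symmetrized as `(M + t(M)) / 2` and the
#' asymmetric original is kept.
#'
#' @param r_by_task Named list of correlation tensors (one per task), or a
#'   single tensor. Conditions are labeled `task:emotion`.
#' @param splits Run splits from [enumerate_run_splits()].
#' @param use_fisher_z Build patterns from Fisher-z maps (default).
#' @return An object of class `similarity_structure` with the symmetrized
#'   `matrix`, the `asymmetric` mean matrix, `reliability` (diagonal), and
#'   condition labels. Clustering fields are added by [hcluster()] /
#'   [cluster_cut()] via [cluster_similarity()].
#' @export
cross_run_similarity <- function(r_by_task, splits, use_fisher_z = TRUE) {
  if (!is.list(r_by_task)) r_by_task <- list(r_by_task)
  if (is.null(names(r_by_task)))
    names(r_by_task) <- if (length(r_by_task) == 1L) "" else
      paste0("task", seq_along(r_by_task))
  cond_labels <- unlist(lapply(names(r_by_task), function(tk) {
    ems <- dimnames(r_by_task[[tk]])[[3]]
    if (nzchar(tk)) paste(tk, ems, sep = ":") else ems
  }))
  pattern_set <- function(runs) {
    do.call(rbind, lapply(r_by_task, emotion_pattern, runs = runs,
                          use_fisher_z = use_fisher_z))
  }
  acc <- 0
  for (sp in splits) {
    Ptr <- pattern_set(sp$train)
    Pte <- pattern_set(sp$test)
    M <- suppressWarnings(stats::cor(t(Ptr), t(Pte)))
    if (any(!is.finite(M)))
      warning("constant pattern(s): undefined similarity cells set to NA")
    acc <- acc + M
  }
  asym <- acc / length(splits)
  dimnames(asym) <- list(cond_labels, cond_labels)
  sym <- (asym + t(asym)) / 2
  structure(list(conditions = cond_labels, matrix = sym, asymmetric = asym,
                 reliability = diag(sym)),
            class = "similarity_structure")
}

#' Cross-run similarity of jointly fitted response patterns
#'
#' Alternative to [cross_run_similarity()] in which each condition's spatial
#' pattern is its row of the full-model least-squares weights, fitted
#' separately on the training and the test runs of every split. Because all
#' conditions are fitted jointly, shared variance between correlated
#' regressors is attributed by the model instead of bleeding into every
#' single-condition correlation map; block structure planted in the weights
#' is therefore recovered much more cleanly.
#'
#' @param dataset_by_task Named list of conditioned `roi_dataset`s (or a
#'   single dataset) — one entry per task.
#' @param designs_by_task Matching named list of per-run design lists.
#' @param splits Run splits from [enumerate_run_splits()].
#' @return A `similarity_structure` (same contract as
#'   [cross_run_similarity()]).
#' @export
cross_run_beta_similarity <- function(dataset_by_task, designs_by_task,
                                      splits) {
  if (inherits(dataset_by_task, "roi_dataset"))
    dataset_by_task <- list(dataset_by_task)
  if (!is.list(designs_by_task[[1]]) ||
      inherits(designs_by_task[[1]], "emotion_design"))
    designs_by_task <- list(designs_by_task)
  tasks <- names(designs_by_task) %||% rep("", length(designs_by_task))
  if (length(dataset_by_task) == 1L && length(designs_by_task) > 1L)
    dataset_by_task <- rep(dataset_by_task, length(designs_by_task))
  cond_labels <- unlist(lapply(seq_along(designs_by_task), function(i) {
    ems <- designs_by_task[[i]][[1]]$emotions
    if (nzchar(tasks[i])) paste(tasks[i], ems, sep = ":") else ems
  }))
  fit_patterns <- function(runs) {
    do.call(rbind, lapply(seq_along(designs_by_task), function(i) {
      ds <- dataset_by_task[[i]]
      X_run <- design_matrices(designs_by_task[[i]])
      Ybar <- mean_standardized_activity(ds, scale_runs = runs)
      fit_linear_map(stack_runs(X_run, runs), stack_runs(Ybar, runs))
    }))
  }
  acc <- 0
  for (sp in splits) {
    M <- suppressWarnings(stats::cor(t(fit_patterns(sp$train)),
                                     t(fit_patterns(sp$test))))
    acc <- acc + M
  }
  asym <- acc / length(splits)
  dimnames(asym) <- list(cond_labels, cond_labels)
  sym <- (asym + t(asym)) / 2
  structure(list(conditions = cond_labels, matrix = sym, asymmetric = asym,
                 reliability = diag(sym)),
            class = "similarity_structure")
}

#' Generalized two-sided Dice overlap of signed activation maps
#'
#' Overlap of two thresholded, signed maps counting positive and negative
#' suprathreshold agreement jointly:
#' `2 (|P_a cap P_b| + |N_a cap N_b|) / (|P_a| + |P_b| + |N_a| + |N_b|)`.
#' When both maps are empty the index is defined as 0 (flagged in the
#' `empty` attribute).
#'
#' @param map_a,map_b Signed masks over the same ROI set, values in
#'   `{-1, 0, 1}`.
#' @return Similarity in `[0, 1]`.
#' @export
generalized_dice <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stop("maps must cover the same ROI set", call. = FALSE)
  if (!all(map_a %in% c(-1, 0, 1)) || !all(map_b %in% c(-1, 0, 1)))
    stop("maps must be ternary (-1/0/1)", call. = FALSE)
  num <- 2 * (sum(map_a == 1 & map_b == 1) + sum(map_a == -1 & map_b == -1))
  den <- sum(map_a != 0) + sum(map_b != 0)
  if (den == 0) return(structure(0, empty = TRUE))
  num / den
}

#' Average-linkage hierarchical clustering with optimal leaf ordering
#'
#' Converts the similarity matrix to distances `d = 1 - s`, agglomerates
#' with average linkage (UPGMA), and orders the dendrogram leaves to
#' maximize the sum of similarities between adjacent leaves, by dynamic
#' programming over the tree (ties broken lexicographically).
#'
#' @param similarity Symmetric condition-by-condition similarity matrix
#'   without `NA`s.
#' @return List with `tree` (an `hclust` object), `leaf_order` (integer
#'   permutation), and `order_score` (the maximized adjacent-similarity
#'   sum).
#' @export
hcluster <- function(similarity) {
  s <- as.matrix(similarity)
  if (any(is.na(s))) {
    bad <- unique(rownames(s)[which(is.na(s), arr.ind = TRUE)[, 1]])
    stop("similarity matrix has NA entries for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (max(abs(s - t(s))) > 1e-8)
    stop("similarity matrix must be symmetric", call. = FALSE)
  d <- stats::as.dist(1 - s)
  tree <- stats::hclust(d, method = "average")
  ord <- optimal_leaf_order(tree, s)
  tree$order <- ord$order
  list(tree = tree, leaf_order = ord$order, order_score = ord$score)
}

# Optimal leaf ordering (maximize sum of similarities of adjacent leaves,
# subject to the dendrogram), O(n^3) dynamic programming.
optimal_leaf_order <- function(tree, s) {
  n <- nrow(s)
  if (n == 1L) return(list(order = 1L, score = 0))
  merges <- tree$merge
  # M[[node]]: matrix over (left endpoint, right endpoint) of best score
  node_leaves <- vector("list", n - 1L)
  node_M <- vector("list", n - 1L)
  get_leaves <- function(id) if (id < 0) -id else node_leaves[[id]]
  get_M <- function(id) {
    if (id < 0) return(matrix(0, 1, 1, dimnames = list(-id, -id)))
    node_M[[id]]
  }
  maxplus <- function(A, B) {
    # (max, +) product: out[i, j] = max_k A[i, k] + B[k, j]
    out <- matrix(-Inf, nrow(A), ncol(B))
    for (i in seq_len(nrow(A)))
      out[i, ] <- apply(A[i, ] + B, 2, max)
    out
  }
  for (v in seq_len(n - 1L)) {
    la <- get_leaves(merges[v, 1]); lb <- get_leaves(merges[v, 2])
    MA <- get_M(merges[v, 1]); MB <- get_M(merges[v, 2])
    SAB <- s[la, lb, drop = FALSE]
    # best score with left endpoint in A, right endpoint in B
    T_ <- maxplus(SAB, MB)        # over boundary pair: T[m, r]
    Mab <- maxplus(MA, T_)        # Mab[l, r], l in A, r in B
    leaves <- c(la, lb)
    M <- matrix(-Inf, length(leaves), length(leaves),
                dimnames = list(leaves, leaves))
    ia <- seq_along(la); ib <- length(la) + seq_along(lb)
    M[ia, ib] <- Mab
    M[ib, ia] <- t(Mab)
    node_leaves[[v]] <- leaves
    node_M[[v]] <- M
  }
  root <- n - 1L
  Mroot <- node_M[[root]]
  best <- max(Mroot)
  ends <- which(Mroot >= best - 1e-12, arr.ind = TRUE)
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE][1, ]
  leaves_r <- node_leaves[[root]]
  trace <- function(id, l, r) {
    if (id < 0) return(-id)
    la <- get_leaves(merges[id, 1]); lb <- get_leaves(merges[id, 2])
    a_id <- merges[id, 1]; b_id <- merges[id, 2]
    if (l %in% lb) { tmp <- la; la <- lb; lb <- tmp
                     tmp <- a_id; a_id <- b_id; b_id <- tmp }
    MA <- get_M(a_id); MB <- get_M(b_id)
    li <- match(l, la); ri <- match(r, lb)
    target <- node_M[[id]][match(l, node_leaves[[id]]),
                           match(r, node_leaves[[id]])]
    # lexicographically first boundary pair achieving the optimum
    for (m in seq_along(la)) {
      for (m2 in seq_along(lb)) {
        val <- MA[li, m] + s[la[m], lb[m2]] + MB[m2, ri]
        if (val >= target - 1e-12)
          return(c(trace(a_id, l, la[m]), trace(b_id, lb[m2], r)))
      }
    }
    stop("leaf-order traceback failed")  # nocov
  }
  order <- trace(root, leaves_r[ends[1]], leaves_r[ends[2]])
  list(order = as.integer(order), score = best)
}

#' Cut a dendrogram at a fraction of its maximum linkage height
#'
#' Conditions joined by merges strictly below `fraction * max(height)` form
#' clusters; merges at or above the cutoff are excluded, so at
#' `fraction = 1` the top-height merges do not join. Conditions that remain
#' alone are labeled 0 (unclustered); clusters are numbered by the smallest
#' member index.
#'
#' @param tree An `hclust` object (e.g. `hcluster(...)$tree`).
#' @param fraction Cut height as a fraction of the maximum merge height,
#'   in `(0, 1]`.
#' @return Integer vector of cluster labels per condition (0 =
#'   unclustered singleton).
#' @export
cluster_cut <- function(tree, fraction = 0.70) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  n <- nrow(tree$merge) + 1L
  cutoff <- fraction * max(tree$height)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  comp_of_node <- integer(n - 1L)
  for (v in seq_len(n - 1L)) {
    a <- tree$merge[v, 1]; b <- tree$merge[v, 2]
    ra <- if (a < 0) find(-a) else find(comp_of_node[a])
    rb <- if (b < 0) find(-b) else find(comp_of_node[b])
    if (tree$height[v] < cutoff) parent[rb] <- ra
    comp_of_node[v] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  labels <- integer(n)
  next_id <- 0L
  for (root in sort(unique(roots))) {
    members <- which(roots == root)
    if (length(members) >= 2L) {
      next_id <- next_id + 1L
      labels[members] <- next_id
    }
  }
  labels
}

#' Cluster a similarity structure
#'
#' Runs [hcluster()] and [cluster_cut()] on a similarity matrix — the same
#' code path serves the rating-space correlation matrix and the neural
#' cross-run similarity matrix.
#'
#' @param sim A `similarity_structure` or a plain symmetric matrix.
#' @param cutoff_fraction Cut height as a fraction of the maximum linkage.
#' @return The input `similarity_structure` (constructed if needed) with
#'   `tree`, `leaf_order`, `order_score` and `clusters` fields added.
#' @export
cluster_similarity <- function(sim, cutoff_fraction = 0.70) {
  if (!inherits(sim, "similarity_structure")) {
    m <- as.matrix(sim)
    sim <- structure(list(conditions = rownames(m) %||%
                            as.character(seq_len(nrow(m))),
                          matrix = m, asymmetric = m,
                          reliability = diag(m)),
                     class = "similarity_structure")
  }
  hc <- hcluster(sim$matrix)
  sim$tree <- hc$tree
  sim$leaf_order <- hc$leaf_order
  sim$order_score <- hc$order_score
  sim$clusters <- cluster_cut(hc$tree, cutoff_fraction)
  names(sim$clusters) <- sim$conditions
  sim
}

#' Temporal similarity matrix of emotion model time series
#'
#' Correlation between the HRF-convolved model time series of every pair of
#' (task, emotion) conditions, concatenated across runs — the rating-space
#' counterpart of the neural cross-run similarity, clustered through the
#' same code path.
#'
#' @param designs_by_task Named list (per task) of per-run
#'   `emotion_design` lists.
#' @return Condition-by-condition correlation matrix.
#' @export
rating_similarity <- function(designs_by_task) {
  cols <- list()
  for (tk in names(designs_by_task)) {
    concat <- do.call(rbind, lapply(designs_by_task[[tk]],
                                    function(d) d$matrix))
    colnames(concat) <- paste(tk, designs_by_task[[tk]][[1]]$emotions,
                              sep = ":")
    cols[[tk]] <- concat
  }
  m <- do.call(cbind, cols)
  suppressWarnings(stats::cor(m))
}

#' @export
print.similarity_structure <- function(x, ...) {
  cat(sprintf("Similarity structure: %d conditions, mean reliability %.3f\n",
              length(x$conditions), mean(x$reliability, na.rm = TRUE)))
  if (!is.null(x$clusters))
    cat(sprintf("  %d clusters at cutoff (%d conditions unclustered)\n",
                max(x$clusters), sum(x$clusters == 0)))
  invisible(x)
}
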