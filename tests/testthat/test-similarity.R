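test_that("emotion patterns are nested means of Fisher-z maps", {
  set.seed(41)
  r <- array(runif(3 * 4 * 2 * 3, -0.5, 0.5), c(3, 4, 2, 3),
             dimnames = list(paste0("p", 1:3), paste0("roi", 1:4),
                             c("joy", "fear"), 1:3))
  pat <- emotion_pattern(r, runs = c(1, 3))
  oracle <- matrix(0, 2, 4)
  for (e in 1:2) for (roi in 1:4)
    oracle[e, roi] <- mean(atanh(r[, roi, e, c(1, 3)]))
  expect_equal(unname(pat), oracle, tolerance = 1e-12)
  # single participant, single run: the pattern is that z-map
  pat1 <- emotion_pattern(r[1, , , 2, drop = FALSE], runs = 1)
  expect_equal(unname(pat1), unname(t(atanh(r[1, , , 2]))),
               tolerance = 1e-12)
  # duplicated runs leave the mean unchanged
  expect_equal(emotion_pattern(r[, , , c(2, 2), drop = FALSE], runs = 1:2),
               emotion_pattern(r[, , , 2, drop = FALSE], runs = 1),
               tolerance = 1e-12)
  expect_error(emotion_pattern(r, runs = integer()), "empty")
})

test_that("cross-run similarity matches a correlation-by-formula oracle", {
  set.seed(42)
  # 3 conditions x 4 ROIs, 4 runs, 2 participants
  r <- array(runif(2 * 4 * 3 * 4, -0.6, 0.6), c(2, 4, 3, 4),
             dimnames = list(NULL, paste0("roi", 1:4),
                             paste0("e", 1:3), 1:4))
  splits <- list(list(train = c(1, 2), test = c(3, 4)),
                 list(train = c(3, 4), test = c(1, 2)))
  sim <- cross_run_similarity(list(felt = r), splits)
  oracle <- 0
  for (sp in splits) {
    Ptr <- emotion_pattern(r, sp$train); Pte <- emotion_pattern(r, sp$test)
    M <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) M[i, j] <- cor(Ptr[i, ], Pte[j, ])
    oracle <- oracle + M / length(splits)
  }
  expect_equal(unname(sim$asymmetric), oracle, tolerance = 1e-12)
  expect_equal(sim$matrix, (sim$asymmetric + t(sim$asymmetric)) / 2)
  expect_equal(sim$reliability, diag(sim$matrix))
  expect_equal(sim$conditions, paste0("felt:e", 1:3))

  # identical train and test patterns give diagonal exactly 1
  r_same <- r; r_same[, , , 3:4] <- r[, , , 1:2]
  sim2 <- cross_run_similarity(list(felt = r_same),
                               list(list(train = 1:2, test = 3:4)))
  expect_equal(unname(diag(sim2$matrix)), rep(1, 3), tolerance = 1e-12)
  # a sign-flipped pattern correlates at -1
  r_neg <- r_same
  r_neg[, , 2, 3:4] <- -r_same[, , 1, 3:4]
  sim3 <- cross_run_similarity(list(felt = r_neg),
                               list(list(train = 1:2, test = 3:4)))
  expect_equal(unname(sim3$asymmetric[1, 2]), -1, tolerance = 1e-12)
})

test_that("generalized Dice counts signed overlap", {
  a <- c(1, 1, 0, 0, -1)
  b <- c(0, 1, 1, 0, -1)
  expect_equal(generalized_dice(a, b), 2 * (1 + 1) / (3 + 3))
  expect_equal(generalized_dice(a, a), 1)
  expect_equal(generalized_dice(c(1, 0, 0), c(0, 1, 1)), 0)
  # P_a = {1,2}, P_b = {2,3}, no negatives -> 2*1/4 = 0.5
  expect_equal(generalized_dice(c(1, 1, 0, 0), c(0, 1, 1, 0)), 0.5)
  empty <- generalized_dice(c(0, 0), c(0, 0))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "empty"))
  expect_error(generalized_dice(c(2, 0), c(0, 0)), "ternary")
})

test_that("average-linkage merges match a hand-computed UPGMA", {
  # 4 conditions with hand-computed merge heights
  s <- matrix(c(1.0, 0.9, 0.2, 0.1,
                0.9, 1.0, 0.3, 0.2,
                0.2, 0.3, 1.0, 0.8,
                0.1, 0.2, 0.8, 1.0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- hcluster(s)
  # d(a,b)=0.1, d(c,d)=0.2, then d({a,b},{c,d}) = mean(0.8,0.9,0.7,0.8)=0.8
  expect_equal(hc$tree$height, c(0.1, 0.2, 0.8), tolerance = 1e-12)
  expect_equal(cluster_cut(hc$tree, 0.70), c(1, 1, 2, 2))
  # block structure: the last merge joins the two blocks
  last <- hc$tree$merge[3, ]
  expect_true(all(last > 0))
  expect_error(hcluster(matrix(c(1, NA, NA, 1), 2, 2,
                               dimnames = list(c("x", "y"), c("x", "y")))),
               "NA")
})

test_that("optimal leaf order matches exhaustive search over tree-consistent orders", {
  set.seed(44)
  for (rep in 1:5) {
    m <- matrix(runif(25, -1, 1), 5, 5)
    s <- (m + t(m)) / 2; diag(s) <- 1
    dimnames(s) <- list(paste0("c", 1:5), paste0("c", 1:5))
    hc <- hcluster(s)
    score <- function(ord) sum(s[cbind(ord[-5], ord[-1])])
    # enumerate all orders consistent with the tree by flipping subtrees
    orders <- list()
    expand <- function(id) {
      if (id < 0) return(list(-id))
      kids <- hc$tree$merge[id, ]
      la <- expand(kids[1]); lb <- expand(kids[2])
      out <- list()
      for (x in la) for (y in lb) {
        out <- c(out, list(c(x, y)), list(c(y, x)))
      }
      out
    }
    all_orders <- expand(nrow(hc$tree$merge))
    best <- max(vapply(all_orders, score, 0))
    expect_equal(hc$order_score, best, tolerance = 1e-12)
    expect_equal(score(hc$leaf_order), best, tolerance = 1e-12)
  }
})

test_that("cluster_cut boundaries and singleton labeling behave as documented", {
  s <- matrix(0.05, 6, 6)
  s[1:2, 1:2] <- 0.9; s[3:4, 3:4] <- 0.85
  diag(s) <- 1
  dimnames(s) <- list(paste0("c", 1:6), paste0("c", 1:6))
  cl <- cluster_similarity(s, cutoff_fraction = 0.70)
  expect_equal(max(cl$clusters), 2L)               # two planted pairs
  expect_true(all(cl$clusters[5:6] == 0L))         # singletons unclustered
  # at fraction 1 the top-height merges are excluded (strict inequality)
  hc <- hcluster(s)
  cl1 <- cluster_cut(hc$tree, 1)
  expect_lt(max(table(cl1[cl1 > 0])), 6L)
  # a cutoff below the first merge height leaves everything unclustered
  expect_true(all(cluster_cut(hc$tree, 1e-6) == 0L))
  expect_error(cluster_cut(hc$tree, 0), "fraction")
})

test_that("rating and neural similarity share one clustering code path", {
  spec <- small_spec(n_participants = 4L, snr = 3)
  sim <- quick_study(spec)
  rs <- rating_similarity(sim$designs)
  expect_equal(dim(rs), c(12L, 12L))
  expect_true(isSymmetric(rs, tol = 1e-12))
  out <- cluster_similarity(rs, cutoff_fraction = 0.7)
  expect_s3_class(out$tree, "hclust")
  expect_length(out$clusters, 12L)
  # perceived and felt series of the same reliable emotion are coupled, so
  # their rating similarity should exceed that of unrelated emotion pairs
  same <- diag(rs[paste0("perceived:emotion0", 1:4),
                  paste0("felt:emotion0", 1:4)])
  cross <- rs["perceived:emotion01", "felt:emotion03"]
  expect_gt(mean(same), cross)
})
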