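test_that("averaged-ratio overlap matches hand-enumerated cases", {
  expect_equal(kmeans_overlap(c("a", "b"), c("a", "b"))$score, 1)
  expect_equal(kmeans_overlap(c("a", "b"), c("c", "d"))$score, 0)
  res <- kmeans_overlap(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(res$ratio1, 2 / 4)
  expect_equal(res$ratio2, 2 / 3)
  expect_equal(res$score, (2 / 4 + 2 / 3) / 2)
  expect_error(kmeans_overlap(character(0), "a"), "non-empty")
})

test_that("the IoU identity links the two ratios to the overlap", {
  # |I|/|U| = 1/(1/r1 + 1/r2 - 1) whenever |I| > 0; checked on random sets
  set.seed(4)
  for (i in 1:50) {
    univ <- sprintf("o%02d", 1:30)
    a <- sample(univ, sample(3:12, 1))
    b <- sample(univ, sample(3:12, 1))
    inter <- length(intersect(a, b))
    if (inter == 0) next
    iou <- inter / length(union(a, b))
    expect_equal(overlap_from_ratios(inter / length(b), inter / length(a)),
                 iou)
  }
})

test_that("k-means overlap permutation test hits its extreme p-values", {
  univ <- sprintf("o%02d", 1:24)
  clusters <- list(c1 = univ[1:8], c2 = univ[9:16], c3 = univ[17:24])
  scheme <- category_scheme("shape_based",
                            list(planted = univ[1:8],
                                 spread = univ[c(1, 9, 17)]))
  res <- kmeans_overlap_test(clusters, scheme, n_perm = 1000, seed = 2)
  planted <- res[res$cluster == "c1" & res$category == "planted", ]
  expect_equal(planted$score, 1)
  expect_equal(planted$p, 1 / 1001)
  expect_true(planted$significant)

  # one cluster holding everything: score invariant under permutation
  res1 <- kmeans_overlap_test(list(all = univ), scheme, n_perm = 200,
                              seed = 1)
  expect_true(all(res1$p == 1))
  expect_error(kmeans_overlap_test(clusters, scheme, n_perm = 0), "n_perm")
})

test_that("k-means overlap test is calibrated on random categories", {
  set.seed(6)
  univ <- sprintf("o%02d", 1:40)
  clusters <- split(univ, rep(1:4, each = 10))
  rej <- 0L
  n_rep <- 150L
  for (i in seq_len(n_rep)) {
    scheme <- category_scheme("low_level",
                              list(rnd = sample(univ, 10)))
    res <- kmeans_overlap_test(clusters, scheme, n_perm = 400, seed = i)
    # per-pair level (no correction): count any pair rejected at 0.05
    rej <- rej + sum(res$p < 0.05)
  }
  rate <- rej / (n_rep * 4)
  ci <- 3 * sqrt(0.05 * 0.95 / (n_rep * 4))
  expect_lt(abs(rate - 0.05), ci + 0.02)     # permutation p is discrete
})

test_that("best connected subtree maximizes the IoU exactly", {
  #          1
  #        / | \
  #       2  3  4
  #      /|     |
  #     5 6     7
  parent <- c(0, 1, 1, 1, 2, 2, 4)
  f <- toy_forest(parent)
  # category equals a connected subtree -> perfect overlap
  res <- best_subtree_overlap(f, c("o2", "o5", "o6"))
  expect_equal(res$score, 1)
  expect_setequal(res$best_subtree, c("o2", "o5", "o6"))
  expect_equal(res$ratio1, 1)
  expect_equal(res$ratio2, 1)

  # category disjoint from the universe is an error; disjoint from the tree
  # is a 0 score
  expect_error(best_subtree_overlap(f, c("zz")), "disjoint")
  f2 <- toy_forest(c(0, 1, 0, 3))
  res2 <- best_subtree_overlap(f2, c("o3", "o4"), tree = 1)
  expect_equal(res2$score, 0)
  expect_length(res2$best_subtree, 0)
})

test_that("Dinkelbach search equals exhaustive enumeration on random trees", {
  # reduced version of the subtree-search oracle criterion
  set.seed(11)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    parent <- random_tree_parent(n, d_max = sample(3:6, 1), seed = 200 + i)
    ids <- paste0("o", seq_len(n))
    members <- sample(ids, sample(2:n, 1))
    f <- toy_forest(parent, ids)
    got <- best_subtree_overlap(f, members)$score
    want <- brute_best_iou(parent, members, ids)
    expect_equal(got, want)
  }
})

test_that("identity holds on every computed forest-overlap result", {
  set.seed(21)
  parent <- random_tree_parent(10, d_max = 4, seed = 3)
  f <- toy_forest(parent)
  for (i in 1:20) {
    members <- sample(f$object_ids, sample(2:8, 1))
    res <- best_subtree_overlap(f, members)
    if (res$ratio1 > 0) {
      expect_equal(res$score,
                   overlap_from_ratios(res$ratio1, res$ratio2))
    }
  }
})

test_that("forest overlap test: extreme category and p-value bounds", {
  # forest of two trees; category = one intact tree
  parent <- c(0, 1, 1, 0, 4, 4)
  f <- toy_forest(parent, d_max = 3)
  twin <- stats::setNames(1:6, f$object_ids)     # all twins are singletons
  scheme <- category_scheme("shape_based",
                            list(tree1 = c("o1", "o2", "o3")))
  res <- dmst_overlap_test(f, scheme, twin, n_perm = 500, seed = 2)
  expect_equal(res$overlap, 1)
  # minimum attainable p under both modes
  expect_equal(res$p_twin, res$p_object, tolerance = 0.2)
  expect_lt(res$p_twin, 0.12)
  expect_true(all(res$p_twin >= 1 / 501 & res$p_twin <= 1))
})

test_that("twin-mode permutation discounts co-located twin pairs", {
  # category = 3 twin pairs, each pair adjacent in a tree but the pairs are
  # scattered across trees: object-mode finds this surprising, twin-mode
  # (which moves pairs as units) much less so
  parent <- c(0, 1, 1, 3,   0, 5, 5, 7,   0, 9, 9, 11)
  ids <- paste0("o", 1:12)
  f <- toy_forest(parent, ids, d_max = 4)
  twin <- stats::setNames(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6), ids)
  # pairs (o1,o2), (o5,o6), (o9,o10) are parent-child pairs in the trees
  scheme <- category_scheme("semantic",
                            list(pairs = c("o1", "o2", "o5", "o6",
                                           "o9", "o10")))
  res <- suppressWarnings(
    dmst_overlap_test(f, scheme, twin, n_perm = 2000, seed = 4))
  expect_lt(res$p_object, res$p_twin)
})

test_that("forest overlap test is calibrated on random categories", {
  set.seed(8)
  parent <- random_tree_parent(16, d_max = 5, seed = 7)
  f <- toy_forest(parent, d_max = 5)
  twin <- stats::setNames(rep(1:8, each = 2), f$object_ids)
  rej_obj <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    members <- sample(f$object_ids, 6)
    scheme <- category_scheme("low_level", list(rnd = members))
    res <- dmst_overlap_test(f, scheme, twin, n_perm = 300,
                             mode = "object", seed = i)
    if (res$p_object < 0.05) rej_obj <- rej_obj + 1L
  }
  expect_lt(rej_obj / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Holm flags follow the published notation", {
  p <- c(0.0005, 0.004, 0.03, 0.2)
  flags <- popcode:::.holm_flags(p)
  expect_equal(flags[1], "**")     # 0.0005 < 0.01/4
  expect_equal(flags[4], "")
  expect_true(flags[2] %in% c("**", "*+", "++"))
  expect_true(flags[3] %in% c("*+", "+", ""))
})
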