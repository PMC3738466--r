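test_that("lambda = 0 yields all-singleton clusters (forced optimum)", {
  d <- random_dissimilarity(7, seed = 1) + 0.05
  diag(d) <- 0
  f <- build_forest(d, dmst_params(lambda = 0, d_max = 3, n_iter = 100,
                                   seed = 1))
  expect_true(all(f$parent == 0))
  expect_equal(f$cost, 0)
  f2 <- exact_forest(d, 0, 3)
  expect_equal(f2$cost, 0)
})

test_that("two tight groups are recovered as two trees", {
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  # exhaustive-oracle version
  fe <- exact_forest(d, 0.5, 3)
  expect_equal(sum(fe$parent == 0), 2L)
  expect_equal(length(unique(forest_clusters(fe)[1:3])), 1L)
  expect_equal(length(unique(forest_clusters(fe)[4:6])), 1L)
  # message-passing version agrees
  fm <- build_forest(d, dmst_params(0.5, 3, n_iter = 200, seed = 3))
  expect_equal(fm$cost, fe$cost)
  expect_equal(sort(forest_clusters(fm)), sort(forest_clusters(fe)))
})

test_that("forests always satisfy their structural invariants", {
  for (s in 1:6) {
    n <- 5 + s
    d <- random_dissimilarity(n, seed = s)
    dmax <- sample(2:4, 1)
    f <- build_forest(d, dmst_params(lambda = runif(1, 0.2, 1), d_max = dmax,
                                     n_iter = 100, seed = s))
    expect_false(any(is.na(f$depth)))          # every object reaches ROOT
    expect_true(all(f$depth >= 1 & f$depth <= dmax))
    expect_true(all(f$parent %in% 0:n))
    expect_equal(f$cost, popcode:::.forest_cost(f$parent, d, f$lambda))
  }
})

test_that("message passing matches the exact solver on random instances", {
  # reduced version of the oracle-equivalence acceptance criterion
  set.seed(42)
  ok <- 0L
  n_inst <- 12L
  for (i in seq_len(n_inst)) {
    d <- random_dissimilarity(8, seed = 100 + i)
    e <- exact_forest(d, 0.6, 3)
    m <- build_forest(d, dmst_params(0.6, 3, seed = i))
    expect_gte(m$cost, e$cost - 1e-9)          # exact is a lower bound
    if (abs(e$cost - m$cost) < 1e-9) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.9 * n_inst))
})

test_that("input validation catches malformed dissimilarities", {
  d <- random_dissimilarity(5, seed = 2)
  bad <- d
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(build_forest(bad, dmst_params(0.5)), "symmetric")
  bad2 <- d
  bad2[1, 1] <- 0.5
  expect_error(build_forest(bad2, dmst_params(0.5)), "diagonal")
  expect_error(build_forest(-d, dmst_params(0.5)), "non-negative")
  expect_error(dmst_params(-1), "lambda")
})

test_that("expected cluster count is non-increasing in lambda", {
  d <- random_dissimilarity(14, seed = 9)
  lambdas <- c(0.1, 0.3, 0.6, 1.0, 1.5)
  mean_k <- vapply(lambdas, function(lam) {
    mean(vapply(1:8, function(s) {
      f <- build_forest(d, dmst_params(lam, 4, n_iter = 150, n_restarts = 1,
                                       seed = s))
      sum(f$parent == 0)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_k) <= 1e-9))
})

test_that("stability scan reports a stable region for planted structure", {
  d <- matrix(1.2, 10, 10)
  d[1:5, 1:5] <- 0.1
  d[6:10, 6:10] <- 0.1
  diag(d) <- 0
  rep <- stability_scan(d, lambda_grid = c(0.4, 0.5, 0.6), dmax_grid = 3,
                        n_runs = 6, seed = 2, n_iter = 100)
  expect_s3_class(rep, "StabilityReport")
  expect_equal(nrow(rep$cells), 3L)
  expect_true(all(rep$cells$mean_clusters == 2))
  expect_true(all(rep$cells$sd_clusters < 0.1))
  expect_true(all(rep$cells$overlap > 0.99))
  expect_equal(rep$stable_regions[["3"]], c(0.4, 0.6))

  # degenerate single-cell grid
  rep1 <- stability_scan(d, lambda_grid = 0.5, dmax_grid = 3, n_runs = 3,
                         seed = 1, n_iter = 80)
  expect_equal(nrow(rep1$cells), 1L)
})

test_that("consensus forest respects link frequencies", {
  # all runs identical -> consensus equals any run with unit weights
  f1 <- toy_forest(c(0, 1, 1, 0, 4))
  cf <- consensus_forest(list(f1, f1, f1), link_threshold = 0.5)
  expect_equal(cf$parent, f1$parent)
  expect_true(all(cf$weights == 1))

  # two runs disagreeing on one leaf's parent: that link has weight 0.5
  f2 <- toy_forest(c(0, 1, 1, 0, 1))
  cf2 <- consensus_forest(list(f1, f2), link_threshold = 0.25)
  expect_equal(sort(unique(cf2$weights)), c(0.5, 1))
  expect_equal(sum(cf2$weights == 0.5), 1L)

  # an over-aggressive threshold strands objects as singletons
  expect_message(cf3 <- consensus_forest(list(f1, f2), link_threshold = 0.9),
                 "singleton")
  expect_equal(cf3$parent[5], 0L)
})

test_that("threshold-0 consensus matches a maximum-weight spanning structure", {
  # runs over 4 objects with varying structure; with threshold 0 the greedy
  # construction must match Kruskal on the link-frequency graph
  runs <- list(toy_forest(c(0, 1, 2, 1)), toy_forest(c(0, 1, 2, 3)),
               toy_forest(c(0, 1, 2, 1)))
  cf <- consensus_forest(runs, link_threshold = 0)
  # link frequencies: 0-1: 3/3, 1-2: 3/3, 2-3: 3/3... build expected by hand
  # 1-2 (1.0), 2-3 (1.0), 1-4 (2/3), 3-4 (1/3), root-1 (1.0)
  expect_equal(cf$parent[2], 1L)
  expect_equal(cf$parent[3], 2L)
  expect_equal(cf$parent[4], 1L)   # the 2/3 link beats the 1/3 link
  expect_equal(cf$weights[4], 2 / 3)
})

test_that("forest serialization round-trips through the edge list", {
  f <- toy_forest(c(0, 1, 1, 3, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_forest(f, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$parent[tab$child == "o1"], "ROOT")
  expect_equal(tab$parent[tab$child == "o4"], "o3")
})
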