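test_that("normalization z-scores each neuron across objects", {
  rates <- rbind(c(10, 20, 30), c(40, 50, 60), c(5, 40, 15))
  ds <- planted_dataset(rates * 0 + 1, n_rep = 1, seed = 1)  # placeholder
  ds$counts <- array(rates, c(3, 3, 1))                      # exact means
  expect_warning(pm <- normalize_responses(ds), NA)
  expect_equal(unname(pm[, 1]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(pm)) < 1e-9))
  expect_true(all(abs(apply(pm, 2, sd) - 1) < 1e-9))

  # a constant neuron is non-informative and dropped
  ds$counts[2, , 1] <- 7
  expect_warning(pm2 <- normalize_responses(ds), "zero-variance")
  expect_equal(ncol(pm2), 2L)
})

test_that("similarity matrix follows r and d = 1 - r", {
  pm <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  sm <- similarity_matrix(pm)
  expect_equal(sm$r["a", "b"], 1)
  expect_equal(sm$d["a", "b"], 0)
  expect_equal(sm$r["a", "c"], -1)
  expect_equal(sm$d["a", "c"], 2)
  expect_equal(sm$r, t(sm$r))
  expect_true(all(diag(sm$r) == 1))
  expect_true(all(sm$d >= 0 & sm$d <= 2))
  # invariant to neuron order
  sm2 <- similarity_matrix(pm[, c(3, 1, 4, 2)])
  expect_equal(sm2$r, sm$r)
})

test_that("independent 94-neuron population vectors rarely exceed |r| = 0.5", {
  set.seed(31)
  n_draws <- 300
  over <- 0L
  for (i in seq_len(n_draws)) {
    x <- rnorm(94)
    y <- rnorm(94)
    if (abs(cor(x, y)) >= 0.5) over <- over + 1L
  }
  expect_lte(over / n_draws, 0.01)
})

test_that("PCA recovers a planted area gradient and calibrates on noise", {
  ss <- generate_stimulus_set(
    stim_config(n_twin_pairs = 30, n_cars = 0, n_faces = 0,
                n_silhouettes = 0, n_textures = 0, n_blank = 0,
                n_lowcontrast = 0), seed = 6)
  pr <- property_table(ss)
  w <- matrix(0, 30, 4, dimnames = list(NULL, c("area", "luminance",
                                                "contrast", "aspect_ratio")))
  w[, "area"] <- rnorm(30, 0, 6)             # area-driven population
  tc <- tuning_config(n_neurons = 30, weights = w, baseline = 12)
  ds <- simulate_population(ss, tc, n_rep = 20, seed = 7)
  pm <- suppressWarnings(normalize_responses(ds))
  res <- pca_property_correlation(pm, pr[ds$object_ids, ])
  r_area <- res$cor$abs_r[res$cor$component == 1 & res$cor$property == "area"]
  expect_gt(r_area, 0.8)
  expect_equal(sum(res$explained), 1, tolerance = 1e-6)

  # a property independent of the responses stays within the permutation null
  fake <- pr
  set.seed(8)
  fake$aspect_ratio <- rnorm(nrow(fake))
  res2 <- pca_property_correlation(pm, fake[ds$object_ids, ])
  r_fake <- res2$cor$abs_r[res2$cor$component == 1 &
                             res2$cor$property == "aspect_ratio"]
  null_r <- replicate(500, abs(cor(sample(fake$aspect_ratio),
                                   seq_len(nrow(fake)))))
  expect_lt(r_fake, quantile(null_r, 0.999))

  expect_error(pca_property_correlation(pm, pr, components = 1:1000),
               "components")
})

test_that("branch test separates planted blocks and flags degenerate labels", {
  # two well-separated blocks in dissimilarity space
  n <- 40
  d <- matrix(1.6, n, n)
  d[1:20, 1:20] <- 0.2
  d[21:40, 21:40] <- 0.2
  diag(d) <- 0
  sm <- structure(list(r = 1 - d, d = d), class = "SimilarityMatrix")
  labels <- rep(c(TRUE, FALSE), each = 20)
  res <- hierarchical_branch_test(sm, labels)
  expect_lt(res$p, 0.001)
  expect_equal(length(unique(res$branch)), 2L)
  expect_match(res$newick, "^\\(.*\\);$")

  expect_message(res2 <- hierarchical_branch_test(sm, rep(TRUE, n)),
                 "constant")
  expect_true(is.na(res2$p))
})

test_that("branch-test type-I error is controlled under random labels", {
  # balanced planted branches, labels drawn independently of them: the
  # chi-squared p is discrete (hypergeometric support), so uniformity is
  # checked through rejection rates, which must not exceed the nominal
  # level (mild conservatism from discreteness is expected)
  set.seed(77)
  n <- 40
  ps <- replicate(200, {
    centers <- rbind(rep(0, 4), rep(6, 4))
    X <- centers[rep(1:2, each = n / 2), ] + matrix(rnorm(n * 4), n, 4)
    d <- as.matrix(dist(X)) / max(dist(X))
    sm <- structure(list(r = 1 - d, d = d), class = "SimilarityMatrix")
    hierarchical_branch_test(sm, sample(rep(c(TRUE, FALSE), n / 2)))$p
  })
  rej <- mean(ps < 0.05)
  expect_lt(rej, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  expect_gt(mean(ps < 0.2), 0.02)
})

test_that("BIC/AIC select the planted number of clusters", {
  set.seed(5)
  # five well-separated isotropic blobs
  centers <- matrix(rnorm(5 * 4, sd = 12), 5, 4)
  X <- centers[rep(1:5, each = 12), ] + matrix(rnorm(60 * 4), 60, 4)
  res <- select_k(X, k_range = 1:8, seed = 3)
  expect_equal(res$k_bic, 5L)

  # a single Gaussian wants k = 1
  X1 <- matrix(rnorm(60 * 4), 60, 4)
  res1 <- select_k(X1, k_range = 1:6, seed = 3)
  expect_equal(res1$k_bic, 1L)

  # a forced range returns the only candidate
  expect_equal(select_k(X, k_range = 3, seed = 1)$k_bic, 3L)
  expect_error(select_k(X, k_range = 0:3), "k_range")
})

test_that("animate segregation statistic behaves at the extremes", {
  set.seed(9)
  # two clusters with a pure animate/inanimate split -> large statistic,
  # small p
  X <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 8), 20, 2))
  labels <- rep(c(TRUE, FALSE), each = 20)
  res <- animate_segregation_test(X, labels, n_runs = 20, n_perm = 200,
                                  seed = 2)
  expect_gt(res$statistic, 0.9)
  expect_lt(res$p, 0.05)

  # labels orthogonal to the structure -> moderate p
  res2 <- animate_segregation_test(X, rep(c(TRUE, FALSE), 20), n_runs = 20,
                                   n_perm = 200, seed = 2)
  expect_gt(res2$p, 0.05)
  expect_error(animate_segregation_test(X, rep(TRUE, 40)), "non-empty")
})

test_that("face selectivity index follows its defining formula", {
  rates <- rbind(c(10, 10, 5, 5), c(7, 7, 7, 7), c(3, 3, 0, 0))
  ds <- planted_dataset(rates, n_rep = 1, seed = 1,
                        object_ids = c("f1", "f2", "x1", "x2"))
  ds$counts <- array(rates * 0.1, c(3, 4, 1))   # exact rates
  fsi <- face_selectivity_index(ds, c("f1", "f2"))
  expect_equal(unname(fsi), c((10 - 5) / (10 + 5), 0, 1))
  expect_error(face_selectivity_index(ds, c("zz")), "non-empty")
})
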