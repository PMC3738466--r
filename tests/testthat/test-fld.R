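# a small dataset whose rates carry a planted binary category signal
category_dataset <- function(gain, n_neu = 16, n_obj = 16, n_rep = 7,
                             seed = 1) {
  pos <- sprintf("obj%03d", seq_len(n_obj / 2))
  withr::with_seed(seed, {
    base <- matrix(runif(n_neu * n_obj, 5, 15), n_neu, n_obj)
    pref <- rnorm(n_neu)                       # signed preference per neuron
    base[, seq_len(n_obj / 2)] <- base[, seq_len(n_obj / 2)] +
      gain * pmax(pref, 0)
  })
  ds <- planted_dataset(base, n_rep = n_rep, seed = seed + 1)
  list(ds = ds, positive = pos)
}

test_that("pseudo-population vectors resample observed trial counts", {
  rates <- matrix(c(10, 40, 80, 20, 60, 30), 2, 3)
  ds <- planted_dataset(rates, n_rep = 5, seed = 2)
  pps <- build_pseudopopulation(ds, n_vectors = 7, seed = 3)
  expect_equal(dim(pps$vectors), c(2L, 3L, 7L))
  # closure: every component comes from that neuron/object's observed trials
  for (i in 1:2) for (j in 1:3) {
    expect_true(all(pps$vectors[i, j, ] %in% ds$counts[i, j, ]))
  }
  # a single-trial cell forces identical components across vectors
  ds1 <- ds
  ds1$counts <- ds$counts[, , 1, drop = FALSE]
  pps1 <- build_pseudopopulation(ds1, n_vectors = 7, seed = 4)
  expect_true(all(apply(pps1$vectors, c(1, 2), function(v) length(unique(v))) == 1))
})

test_that("resampling is unbiased for the trial mean", {
  rates <- matrix(c(30, 70), 1, 2)
  ds <- planted_dataset(rates, n_rep = 9, seed = 5)
  draws <- replicate(600, build_pseudopopulation(ds, 3, seed = sample.int(1e6, 1))$vectors)
  m <- mean(draws[1, 1, , ])
  mu <- mean(ds$counts[1, 1, ])
  se <- sd(ds$counts[1, 1, ]) / sqrt(length(draws[1, 1, , ]))
  expect_lt(abs(m - mu), 4 * se)
})

test_that("FLD decodes a separable planted category and not shuffled labels", {
  cd <- category_dataset(gain = 40, seed = 7)
  res <- run_fld_task(cd$ds, cd$positive, n_runs = 15, n_null = 15, seed = 2)
  expect_gte(res$performance, 0.95)
  # null performance sits at chance
  expect_lt(abs(res$null_mean - 0.5), 3 * max(res$null_sd, 0.02))
  expect_lt(res$p, 0.1)
})

test_that("chance-level decoding when the signal is absent", {
  cd <- category_dataset(gain = 0, seed = 9)
  res <- run_fld_task(cd$ds, cd$positive, n_runs = 15, n_null = 15, seed = 3)
  expect_lt(abs(res$performance - 0.5), 3 * max(sd(res$runs), 0.02))
})

test_that("task preconditions are enforced", {
  cd <- category_dataset(gain = 10, seed = 1)
  expect_error(run_fld_task(cd$ds, cd$positive[1]), ">= 2")
  expect_error(run_fld_task(cd$ds, cd$ds$object_ids), ">= 2")
})

test_that("no left-out object information leaks into training", {
  # every object gets its own unique strong rate pattern and labels are
  # arbitrary, so generalization to a left-out object is impossible: if the
  # left-out vectors leaked into training, both the observed and the null
  # performance would sit near 1 instead of chance. A single dataset has
  # real pattern variance, so average over several datasets.
  n_obj <- 12
  perfs <- nulls <- numeric(5)
  for (k in 1:5) {
    withr::with_seed(33 + k, {
      rates <- matrix(runif(10 * n_obj, 2, 60), 10, n_obj)
      ds <- planted_dataset(rates, n_rep = 7, seed = 340 + k)
      pos <- sample(ds$object_ids, n_obj / 2)
    })
    res <- run_fld_task(ds, pos, n_runs = 10, n_null = 10, seed = 5 + k)
    perfs[k] <- res$performance
    nulls[k] <- res$null_mean
  }
  expect_lt(abs(mean(perfs) - 0.5), 0.12)
  expect_lt(abs(mean(nulls) - 0.5), 0.12)
})

test_that("pruning selects a maximum conflict-free subset", {
  twin <- stats::setNames(c(1, 2, 3, 4, 4, 5), sprintf("o%d", 1:6))
  schemes <- list(category_scheme("low_level", list(
    A = c("o1", "o6"), B = c("o2"), C = c("o3"), D = c("o4"), E = c("o5"))))
  # o1..o4 conflict-free: all four selected
  pr <- prune_category(sprintf("o%d", 1:4), schemes, twin,
                       universe = sprintf("o%d", 1:6), seed = 1)
  expect_setequal(pr$positive, sprintf("o%d", 1:4))
  expect_false(pr$too_small)

  # a twin pair contributes at most one member, under every seed
  for (s in 1:20) {
    pr2 <- prune_category(c("o4", "o5", "o1"), schemes, twin,
                          universe = sprintf("o%d", 1:6), seed = s)
    expect_lte(sum(twin[pr2$positive] == 4), 1L)
    expect_equal(length(pr2$positive), 2L)
  }
  # different seeds sample different maximal solutions
  picks <- unique(vapply(1:20, function(s) {
    paste(sort(prune_category(c("o4", "o5", "o1"), schemes, twin,
                              universe = sprintf("o%d", 1:6),
                              seed = s)$positive), collapse = "+")
  }, character(1)))
  expect_gt(length(picks), 1L)
})

test_that("the exact solver matches brute force on random fixtures", {
  # brute-force oracle: maximum independent set by subset enumeration
  brute_mis <- function(adj) {
    n <- nrow(adj)
    best <- 0L
    for (mask in 0:(2^n - 1)) {
      idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0L)
      if (length(idx) <= best) next
      if (!any(adj[idx, idx])) best <- length(idx)
    }
    best
  }
  set.seed(12)
  for (i in 1:12) {
    n <- sample(8:14, 1)
    ids <- sprintf("o%02d", 1:n)
    twin <- stats::setNames(sample(ceiling(n / 2), n, replace = TRUE), ids)
    cats <- split(ids, sample(4, n, replace = TRUE))
    names(cats) <- paste0("c", seq_along(cats))
    cats2 <- split(ids, sample(3, n, replace = TRUE))
    names(cats2) <- paste0("d", seq_along(cats2))
    schemes <- list(category_scheme("low_level", cats),
                    category_scheme("shape_based", cats2))
    adj <- popcode:::.conflict_adjacency(ids, schemes, twin)
    want <- brute_mis(adj)
    pr <- prune_category(ids, schemes, twin, universe = ids, seed = i)
    expect_equal(length(pr$positive), want)
    expect_true(satisfies_pruning_constraints(pr$positive, schemes, twin))
  }
})

test_that("null pruned categories hit the requested size and constraints", {
  set.seed(3)
  ids <- sprintf("o%02d", 1:30)
  twin <- stats::setNames(rep(1:15, each = 2), ids)
  schemes <- list(category_scheme("low_level",
                                  split(ids, rep(1:6, 5))))
  nl <- build_null_pruned(schemes, twin, size_positive = 5,
                          size_negative = 5, universe = ids, seed = 4)
  expect_length(nl$positive, 5L)
  expect_length(nl$negative, 5L)
  expect_length(intersect(nl$positive, nl$negative), 0L)
  # an infeasible size errors after bounded retries
  expect_error(build_null_pruned(schemes, twin, size_positive = 20,
                                 universe = ids, seed = 1, max_retries = 3),
               "infeasible")
})
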