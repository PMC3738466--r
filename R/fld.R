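#' Build pseudo-population response vectors
#'
#' Since neurons are recorded sequentially, simultaneity is emulated by
#' resampling: each component of a pseudo-population vector is the spike
#' count of that neuron in a randomly sampled (with replacement) trial of
#' the given object. `n_vectors` vectors are built per object; the whole set
#' is rebuilt anew for each cross-validation run of the decoder.
#'
#' @param ds a `ResponseDataset`.
#' @param n_vectors vectors per object (default 7, the median repetition
#'   count).
#' @param seed integer seed.
#' @return a `PseudoPopulationSet`: list with `vectors` (array neurons x
#'   objects x n_vectors) and `object_ids`.
#' @export
build_pseudopopulation <- function(ds, n_vectors = 7L, seed = 1L) {
  stopifnot(inherits(ds, "ResponseDataset"), n_vectors >= 1)
  dm <- dim(ds$counts)
  n_trial_cell <- apply(!is.na(ds$counts), c(1, 2), sum)
  if (any(n_trial_cell == 0)) {
    stop("every (neuron, object) pair needs at least one trial", call. = FALSE)
  }
  with_seed(seed, {
    idx <- array(0L, c(dm[1], dm[2], n_vectors))
    for (v in seq_len(n_vectors)) {
      idx[, , v] <- matrix(
        sapply(as.vector(n_trial_cell), function(nt) sample.int(nt, 1)),
        dm[1], dm[2])
    }
    vectors <- array(
      ds$counts[cbind(rep(seq_len(dm[1]), dm[2] * n_vectors),
                      rep(rep(seq_len(dm[2]), each = dm[1]), n_vectors),
                      as.vector(idx))],
      c(dm[1], dm[2], n_vectors))
    structure(list(vectors = vectors, object_ids = ds$object_ids),
              class = "PseudoPopulationSet")
  })
}

# binary Fisher discriminant on columns-as-features matrix; shrinkage is
# applied when the within-class scatter is (near-)singular
.fit_fld <- function(X1, X0) {
  mu1 <- colMeans(X1)
  mu0 <- colMeans(X0)
  S <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X0, 2, mu0))) /
    max(1, nrow(X1) + nrow(X0) - 2)
  w <- NULL
  for (gamma in c(0, 0.01, 0.1, 0.5)) {
    Sreg <- (1 - gamma) * S + (gamma * mean(diag(S)) + 1e-10) * diag(ncol(S))
    w <- tryCatch(solve(Sreg, mu1 - mu0), error = function(e) NULL)
    if (!is.null(w)) break
  }
  list(w = w, threshold = sum(w * (mu1 + mu0)) / 2)
}

# one cross-validation run: fresh pseudo-population, n_loops leave-two-
# objects-out loops; labels: pos[object] logical (possibly shuffled per loop)
.fld_run <- function(ds, pos_set, n_vectors, n_loops, seed, shuffle) {
  pps <- build_pseudopopulation(ds, n_vectors, seed)
  ids <- pps$object_ids
  n_obj <- length(ids)
  V <- pps$vectors                          # neurons x objects x vectors
  with_seed(derive_seed(seed, "loops"), {
    correct <- numeric(n_loops)
    for (l in seq_len(n_loops)) {
      pos <- ids %in% pos_set
      if (shuffle) pos <- sample(pos)
      ipos <- which(pos)
      ineg <- which(!pos)
      out_p <- sample(ipos, 1)
      out_n <- sample(ineg, 1)
      tr_p <- setdiff(ipos, out_p)
      tr_n <- setdiff(ineg, out_n)
      X1 <- t(matrix(V[, tr_p, ], nrow = dim(V)[1]))
      X0 <- t(matrix(V[, tr_n, ], nrow = dim(V)[1]))
      fld <- .fit_fld(X1, X0)
      vp <- V[, out_p, sample(dim(V)[3], 1)]
      vn <- V[, out_n, sample(dim(V)[3], 1)]
      correct[l] <- ((sum(fld$w * vp) > fld$threshold) +
                       (sum(fld$w * vn) <= fld$threshold)) / 2
    }
    mean(correct)
  })
}

#' Cross-validated Fisher-discriminant decoding of a binary category task
#'
#' Trains binary Fisher linear discriminants to separate the positive
#' category from all other objects, on pseudo-population spike-count
#' vectors. Each cross-validation loop leaves out all vectors of one
#' positive and one negative object and tests one left-out vector of each;
#' a run is `n_loops` such loops on a freshly resampled pseudo-population,
#' and performance is averaged over `n_runs` runs. A permutation null
#' shuffles object labels before each loop.
#'
#' @param ds a `ResponseDataset`.
#' @param positive object ids of the positive category (>= 2; the
#'   complementary set must also have >= 2 objects).
#' @param negative object ids of the complementary set; `NULL` (default)
#'   uses every other object. Pruned tasks pass the pruned negative set, so
#'   that excluded twins do not re-enter through the complement.
#' @param n_vectors pseudo-population vectors per object (default 7).
#' @param n_loops cross-validation loops per run (default 30).
#' @param n_runs runs (the full-scale analysis uses 3500; default here is
#'   desk-scale).
#' @param n_null null runs with shuffled labels.
#' @param seed integer seed.
#' @return list with `performance`, `sd`, `null_mean`, `null_sd`, `p`
#'   (`(1 + #null >= obs) / (1 + n_null)`), and the per-run values.
#' @export
run_fld_task <- function(ds, positive, negative = NULL, n_vectors = 7L,
                         n_loops = 30L, n_runs = 200L, n_null = n_runs,
                         seed = 1L) {
  stopifnot(inherits(ds, "ResponseDataset"))
  if (!is.null(negative)) {
    keep <- match(intersect(c(positive, negative), ds$object_ids),
                  ds$object_ids)
    ds$counts <- ds$counts[, keep, , drop = FALSE]
    ds$object_ids <- ds$object_ids[keep]
  }
  pos <- intersect(positive, ds$object_ids)
  if (length(pos) < 2 || length(ds$object_ids) - length(pos) < 2) {
    stop("positive and complementary sets must each have >= 2 objects",
         call. = FALSE)
  }
  runs <- vapply(seq_len(n_runs), function(r) {
    .fld_run(ds, pos, n_vectors, n_loops,
             derive_seed(seed, paste0("run", r)), shuffle = FALSE)
  }, numeric(1))
  null_runs <- vapply(seq_len(n_null), function(r) {
    .fld_run(ds, pos, n_vectors, n_loops,
             derive_seed(seed, paste0("null", r)), shuffle = TRUE)
  }, numeric(1))
  obs <- mean(runs)
  list(performance = obs, sd = stats::sd(runs),
       null_mean = mean(null_runs), null_sd = stats::sd(null_runs),
       p = (1 + sum(null_runs >= obs)) / (1 + n_null),
       runs = runs, null_runs = null_runs)
}

## ----------------------------------------------------- constrained pruning

# conflict graph over a set of objects: an edge joins two objects that share
# a category of any conflicting scheme or belong to the same twin set
.conflict_adjacency <- function(objects, conflicting_schemes, twin_sets) {
  n <- length(objects)
  adj <- matrix(FALSE, n, n)
  mark <- function(members) {
    idx <- which(objects %in% members)
    if (length(idx) > 1) adj[idx, idx] <<- TRUE
  }
  for (scheme in conflicting_schemes) {
    for (cat in scheme$categories) mark(cat)
  }
  ts <- twin_sets[objects]
  for (s in unique(ts)) mark(objects[!is.na(ts) & ts == s])
  diag(adj) <- FALSE
  adj
}

# exact maximum-weight independent set by branch and bound with a greedy
# clique-cover bound (the conflict graphs here are unions of cliques, for
# which the bound is nearly tight); node_budget guards against pathological
# instances
.max_weight_independent_set <- function(adj, w, node_budget = 2e6) {
  n <- length(w)
  best <- list(weight = -Inf, set = integer(0))
  nodes_used <- 0L
  clique_bound <- function(cand) {
    # greedy clique partition; bound = sum over cliques of the max weight
    remaining <- cand[order(-w[cand])]
    bound <- 0
    while (length(remaining) > 0) {
      v <- remaining[1]
      clique <- v
      for (u in remaining[-1]) {
        if (all(adj[u, clique])) clique <- c(clique, u)
      }
      bound <- bound + max(w[clique])
      remaining <- setdiff(remaining, clique)
    }
    bound
  }
  rec <- function(cand, cur_set, cur_w) {
    nodes_used <<- nodes_used + 1L
    if (nodes_used > node_budget) {
      stop("independent-set solver budget exceeded", call. = FALSE)
    }
    if (length(cand) == 0) {
      if (cur_w > best$weight) best <<- list(weight = cur_w, set = cur_set)
      return(invisible())
    }
    if (cur_w + clique_bound(cand) <= best$weight) return(invisible())
    v <- cand[which.max(w[cand])]
    # include v
    rec(cand[!adj[v, cand] & cand != v], c(cur_set, v), cur_w + w[v])
    # exclude v
    rec(setdiff(cand, v), cur_set, cur_w)
  }
  rec(seq_len(n), integer(0), 0)
  best$set
}

#' Prune a category to decouple semantic and visual information
#'
#' Finds a maximum subset of the target category — and, separately, of its
#' complement (the negative set) — such that (1) no two selected objects
#' share a category of any conflicting scheme, (2) symmetrically for the
#' complement, and (3) no twin set contributes more than one object. The
#' underlying integer program (maximum independent set on the conflict
#' graph) is solved exactly; a small seeded random perturbation of the
#' objective samples different maximum-size solutions across calls, as many
#' distinct prunings exist.
#'
#' @param target object ids of the category to prune.
#' @param conflicting_schemes list of `CategoryScheme`s whose categories
#'   must not contribute more than one selected object each.
#' @param twin_sets named vector mapping object ids to twin-set ids.
#' @param universe all object ids (defaults to the names of `twin_sets`).
#' @param seed integer seed for the objective perturbation.
#' @param min_size minimum usable size; smaller results are flagged.
#' @return a `PrunedCategory`: list with `positive`, `negative`,
#'   `too_small` flag and `log`.
#' @export
prune_category <- function(target, conflicting_schemes, twin_sets,
                           universe = names(twin_sets), seed = 1L,
                           min_size = 3L) {
  stopifnot(length(target) > 0, is.list(conflicting_schemes))
  negative_pool <- setdiff(universe, target)
  with_seed(seed, {
    pick <- function(objects) {
      if (length(objects) == 0) return(character(0))
      adj <- .conflict_adjacency(objects, conflicting_schemes, twin_sets)
      w <- 1 + stats::runif(length(objects)) * (0.5 / length(objects))
      objects[.max_weight_independent_set(adj, w)]
    }
    positive <- pick(target)
    negative <- pick(negative_pool)
    structure(list(positive = positive, negative = negative,
                   too_small = length(positive) < min_size,
                   log = sprintf("pruned %d/%d positive, %d/%d negative",
                                 length(positive), length(target),
                                 length(negative), length(negative_pool))),
              class = "PrunedCategory")
  })
}

#' Build a size-matched null pruned category
#'
#' Shuffles the twin-set indices over the whole stimulus set, then samples a
#' null positive (and negative) set under the same three constraint families
#' as [prune_category()], forced to the same sizes as the corresponding
#' pruned category. If the size is infeasible after a shuffle, new shuffles
#' are drawn (bounded retries) before failing.
#'
#' @param conflicting_schemes list of `CategoryScheme`s.
#' @param twin_sets named vector mapping object ids to twin-set ids.
#' @param size_positive,size_negative required sizes.
#' @param universe all object ids.
#' @param seed integer seed.
#' @param max_retries shuffle retries.
#' @return a `PrunedCategory` with the requested sizes.
#' @export
build_null_pruned <- function(conflicting_schemes, twin_sets,
                              size_positive, size_negative = 0L,
                              universe = names(twin_sets), seed = 1L,
                              max_retries = 50L) {
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      shuffled <- twin_sets
      names(shuffled) <- sample(names(twin_sets))
      shuffled <- shuffled[universe]
      sel <- .sample_constrained(universe, conflicting_schemes, shuffled,
                                 size_positive)
      if (is.null(sel)) next
      neg <- if (size_negative > 0) {
        .sample_constrained(setdiff(universe, sel), conflicting_schemes,
                            shuffled, size_negative)
      } else character(0)
      if (size_negative > 0 && is.null(neg)) next
      return(structure(list(positive = sel, negative = neg,
                            too_small = FALSE,
                            log = sprintf("null category after %d shuffle(s)",
                                          try)),
                       class = "PrunedCategory"))
    }
    stop("requested null-category size infeasible under the constraints",
         call. = FALSE)
  })
}

# random greedy constrained sampling to an exact size (NULL if stuck)
.sample_constrained <- function(pool, conflicting_schemes, twin_sets, size) {
  if (size == 0) return(character(0))
  if (length(pool) < size) return(NULL)
  adj <- .conflict_adjacency(pool, conflicting_schemes, twin_sets)
  avail <- seq_along(pool)
  sel <- integer(0)
  while (length(sel) < size && length(avail) > 0) {
    v <- if (length(avail) == 1) avail else sample(avail, 1)
    sel <- c(sel, v)
    avail <- avail[!adj[v, avail] & avail != v]
  }
  if (length(sel) < size) NULL else pool[sel]
}

#' Check the pruning constraints of an object set
#'
#' @param objects selected object ids.
#' @param conflicting_schemes list of `CategoryScheme`s.
#' @param twin_sets named vector of twin-set ids.
#' @return `TRUE` if no two objects share a conflicting category or twin
#'   set.
#' @export
satisfies_pruning_constraints <- function(objects, conflicting_schemes,
                                          twin_sets) {
  if (length(objects) < 2) return(TRUE)
  adj <- .conflict_adjacency(objects, conflicting_schemes, twin_sets)
  !any(adj)
}
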