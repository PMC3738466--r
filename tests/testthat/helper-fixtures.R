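# Shared fixture builders (everything generated in code; no stored data).

# small stimulus set: fast to render, still has twins and special classes
small_stimset <- function(seed = 1, n_twin_pairs = 10, ...) {
  generate_stimulus_set(
    stim_config(n_twin_pairs = n_twin_pairs, n_cars = 2, n_faces = 2,
                n_silhouettes = 1, n_textures = 1, n_blank = 1,
                n_lowcontrast = 2, ...),
    seed = seed)
}

# response dataset with planted rate structure: rates matrix (neurons x
# objects) -> Poisson counts; background at `baseline`
planted_dataset <- function(rates, n_rep = 7, baseline = 10, seed = 1,
                            object_ids = NULL) {
  n_neu <- nrow(rates)
  n_obj <- ncol(rates)
  if (is.null(object_ids)) object_ids <- sprintf("obj%03d", seq_len(n_obj))
  withr::with_seed(seed, {
    counts <- array(rpois(n_neu * n_obj * n_rep, rep(rates * 0.1, n_rep)),
                    c(n_neu, n_obj, n_rep))
    background <- matrix(rpois(n_neu * n_obj * n_rep, baseline * 0.1),
                         n_neu, n_obj * n_rep)
    structure(list(counts = counts, background = background,
                   window = c(start_ms = 100, end_ms = 200),
                   neuron_ids = sprintf("n%03d", seq_len(n_neu)),
                   object_ids = object_ids),
              class = "ResponseDataset")
  })
}

# hand-built forest from a parent vector (0 = ROOT)
toy_forest <- function(parent, ids = NULL, d_max = 6, lambda = 0.5) {
  if (is.null(ids)) ids <- paste0("o", seq_along(parent))
  structure(list(parent = as.integer(parent),
                 depth = popcode:::.forest_depths(as.integer(parent)),
                 weights = rep(1, length(parent)), object_ids = ids,
                 d_max = d_max, lambda = lambda, cost = NA_real_,
                 converged = TRUE),
            class = "Forest")
}

# random symmetric dissimilarity matrix
random_dissimilarity <- function(n, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d + t(d)
  })
}

# random tree over n nodes (node 1 is the centre), depth-bounded
random_tree_parent <- function(n, d_max = 6, seed = 1) {
  withr::with_seed(seed, {
    parent <- integer(n)
    depth <- integer(n)
    depth[1] <- 1L
    for (v in seq_len(n)[-1]) {
      cand <- which(depth[seq_len(v - 1)] < d_max)
      p <- if (length(cand) == 1) cand else sample(cand, 1)
      parent[v] <- p
      depth[v] <- depth[p] + 1L
    }
    parent
  })
}

# brute-force maximum IoU over all connected subtrees (oracle)
brute_best_iou <- function(parent, members, ids = NULL, cat_size = NULL) {
  if (is.null(ids)) ids <- paste0("o", seq_along(parent))
  z <- ids %in% members
  if (is.null(cat_size)) cat_size <- length(members)
  subsets <- popcode:::.enumerate_subtrees(as.integer(parent))
  best <- 0
  for (s in subsets) {
    i <- sum(z[s])
    best <- max(best, i / (length(s) + cat_size - i))
  }
  best
}
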