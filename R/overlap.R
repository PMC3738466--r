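#' Overlap score between a cluster and a category (averaged-ratio form)
#'
#' `Ratio 1` is the fraction of the category overlapping the cluster
#' (`|I|/|category|`); `Ratio 2` is the fraction of the cluster overlapping
#' the category (`|I|/|cluster|`); the score is their average.
#'
#' @param cluster,category character vectors of object ids from the same
#'   universe (non-empty).
#' @return list with `score`, `ratio1`, `ratio2`.
#' @export
kmeans_overlap <- function(cluster, category) {
  if (length(cluster) == 0 || length(category) == 0) {
    stop("cluster and category must be non-empty", call. = FALSE)
  }
  i <- length(intersect(cluster, category))
  r1 <- i / length(category)
  r2 <- i / length(cluster)
  list(score = (r1 + r2) / 2, ratio1 = r1, ratio2 = r2)
}

#' Intersection-over-union overlap from the two ratios
#'
#' For `|I| > 0`, the intersection-over-union score satisfies
#' `IoU = 1 / (1/ratio1 + 1/ratio2 - 1)`; this identity lets published
#' overlap tables be checked from their printed ratios alone.
#'
#' @param ratio1,ratio2 the two ratios (in `(0, 1]`).
#' @return the implied intersection-over-union score.
#' @export
overlap_from_ratios <- function(ratio1, ratio2) {
  stopifnot(all(ratio1 > 0), all(ratio2 > 0))
  1 / (1 / ratio1 + 1 / ratio2 - 1)
}

#' Permutation test of k-means cluster/category overlap
#'
#' For every (cluster, category) pair, computes the averaged-ratio overlap
#' score and a permutation p-value obtained by reshuffling the objects among
#' the clusters (preserving cluster sizes) `n_perm` times. Significance
#' flags are Bonferroni-corrected over the whole tested family.
#'
#' @param clusters named list of object-id vectors partitioning the universe
#'   (or an object-named vector of cluster labels).
#' @param scheme a `CategoryScheme`.
#' @param n_perm number of permutations.
#' @param alpha family-wise significance level (default 0.05).
#' @param seed integer seed.
#' @return data frame: cluster, category, ratio1, ratio2, score, p,
#'   significant (Bonferroni at `alpha`).
#' @export
kmeans_overlap_test <- function(clusters, scheme, n_perm = 1000L,
                                alpha = 0.05, seed = 1L) {
  stopifnot(inherits(scheme, "CategoryScheme"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.list(clusters)) {
    clusters <- split(names(clusters), clusters)
  }
  universe <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(universe) > 0) {
    stop("clusters must partition the universe", call. = FALSE)
  }
  n <- length(universe)
  k <- length(clusters)
  sizes <- vapply(clusters, length, 1L)
  assign0 <- rep(seq_len(k), sizes)        # cluster index per universe slot
  # category indicator matrix over the universe ordering
  Z <- vapply(scheme$categories, function(cat) universe %in% cat,
              logical(n))
  csize <- colSums(Z)
  score_mat <- function(assignment) {
    inter <- rowsum(Z + 0, assignment)     # k x ncat intersection counts
    (sweep(inter, 2, pmax(csize, 1), "/") + inter / sizes) / 2
  }
  obs <- score_mat(assign0)
  with_seed(seed, {
    exceed <- matrix(0, k, ncol(Z))
    for (p in seq_len(n_perm)) {
      exceed <- exceed + (score_mat(sample(assign0)) >= obs)
    }
    pval <- (1 + exceed) / (1 + n_perm)
    inter <- rowsum(Z + 0, assign0)
    out <- data.frame(
      cluster = rep(names(clusters), times = ncol(Z)),
      category = rep(colnames(Z), each = k),
      ratio1 = as.vector(sweep(inter, 2, pmax(csize, 1), "/")),
      ratio2 = as.vector(inter / sizes),
      score = as.vector(obs),
      p = as.vector(pval))
    out$significant <- out$p < alpha / nrow(out)
    out
  })
}

## ------------------------------------------------- connected-subtree search

# maximum IoU over connected subtrees of every tree of the forest, by
# Dinkelbach iteration; z is the 0/1 membership of the category over the
# forest's objects and cat_size the full category size (members outside the
# forest still count in the union)
.max_iou_forest <- function(forest, z, cat_size, order_desc) {
  if (sum(z) == 0 || cat_size == 0) return(0)
  parent <- forest$parent
  r <- 0
  repeat {
    best <- (1 + r) * z - r
    iv <- z                 # category members in the best subtree topped here
    sv <- rep(1L, length(z))
    for (v in order_desc) {
      p <- parent[v]
      if (p > 0 && best[v] > 0) {
        best[p] <- best[p] + best[v]
        iv[p] <- iv[p] + iv[v]
        sv[p] <- sv[p] + sv[v]
      }
    }
    v0 <- which.max(best)
    i <- iv[v0]
    s <- sv[v0]
    f <- i / (s + cat_size - i)
    if (f > r + 1e-12) r <- f else break
  }
  r
}

# nodes of the max-weight subtree topped at v0 (descend, keeping children
# with positive DP value)
.recover_subtree <- function(parent, order_desc, z, r, v0) {
  best <- (1 + r) * z - r
  keep <- logical(length(parent))
  for (v in order_desc) {
    p <- parent[v]
    keep[v] <- best[v] > 0
    if (p > 0 && best[v] > 0) best[p] <- best[p] + best[v]
  }
  # walk down from v0 through kept children
  inc <- v0
  frontier <- v0
  children <- split(seq_along(parent), parent)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      ch <- children[[as.character(v)]]
      ch <- ch[keep[ch]]
      nxt <- c(nxt, ch)
    }
    inc <- c(inc, nxt)
    frontier <- nxt
  }
  inc
}

#' Best connected-subtree overlap between a forest tree and a category
#'
#' Maximizes the intersection-over-union `|S ∩ C| / |S ∪ C|` over all
#' connected subtrees `S` of a tree, where `C` is the category (members
#' outside the tree still count in the union). Solved exactly by Dinkelbach
#' fractional programming: for a candidate ratio `r`, each node gets weight
#' `(1 + r)·[v ∈ C] − r` and the max-weight connected subtree is found by
#' tree dynamic programming.
#'
#' @param forest a `Forest`.
#' @param category character vector of object ids (non-empty, drawn from the
#'   forest's universe).
#' @param tree which tree (cluster index as in [forest_clusters()]) to
#'   search; `NULL` searches every tree and reports the best.
#' @return list with `score`, `ratio1` (`|I|/|C|`), `ratio2` (`|I|/|S|`),
#'   `best_subtree` (object ids) and `tree` (index of the best tree). A
#'   category with no member in the searched tree(s) yields score 0 and an
#'   empty subtree.
#' @export
best_subtree_overlap <- function(forest, category, tree = NULL) {
  stopifnot(inherits(forest, "Forest"))
  if (length(category) == 0) stop("category must be non-empty", call. = FALSE)
  if (!any(category %in% forest$object_ids)) {
    stop("category is disjoint from the object universe", call. = FALSE)
  }
  cl <- forest_clusters(forest)
  trees <- if (is.null(tree)) sort(unique(cl)) else tree
  z_all <- as.numeric(forest$object_ids %in% category)
  cat_size <- length(category)
  best <- list(score = 0, ratio1 = 0, ratio2 = 0,
               best_subtree = character(0), tree = NA_integer_)
  for (tr in trees) {
    sel <- which(cl == tr)
    sub <- .subforest(forest, sel)
    z <- z_all[sel]
    if (sum(z) == 0) next
    ord <- order(sub$depth, decreasing = TRUE)
    r <- .max_iou_forest(sub, z, cat_size, ord)
    if (r > best$score) {
      v0 <- .best_top_node(sub, z, r, ord)
      inc <- .recover_subtree(sub$parent, ord, z, r, v0)
      i <- sum(z[inc])
      best <- list(score = r, ratio1 = i / cat_size, ratio2 = i / length(inc),
                   best_subtree = sub$object_ids[sort(inc)], tree = tr)
    }
  }
  best
}

# restriction of a forest to a node subset (a full tree), reindexed
.subforest <- function(forest, sel) {
  remap <- match(forest$parent[sel], sel)
  parent <- ifelse(is.na(remap), 0L, remap)
  list(parent = parent, depth = .forest_depths(parent),
       object_ids = forest$object_ids[sel])
}

.best_top_node <- function(sub, z, r, order_desc) {
  best <- (1 + r) * z - r
  for (v in order_desc) {
    p <- sub$parent[v]
    if (p > 0 && best[v] > 0) best[p] <- best[p] + best[v]
  }
  which.max(best)
}

# exhaustive enumeration of all connected subtrees (test oracle for small
# trees): returns a list of integer node sets
.enumerate_subtrees <- function(parent) {
  n <- length(parent)
  children <- lapply(seq_len(n), function(v) which(parent == v))
  rooted <- function(v) {
    # all subtrees rooted (topped) at v
    sets <- list(v)
    for (ch in children[[v]]) {
      ch_sets <- rooted(ch)
      sets <- unlist(lapply(sets, function(s) {
        c(list(s), lapply(ch_sets, function(cs) c(s, cs)))
      }), recursive = FALSE)
    }
    sets
  }
  unlist(lapply(seq_len(n), rooted), recursive = FALSE)
}

## ------------------------------------------------- twin-aware forest test

#' Twin-aware permutation test of forest/category overlap
#'
#' The observed statistic per category is the best connected-subtree
#' intersection-over-union over all trees of the forest
#' ([best_subtree_overlap()]). The null permutes category membership either
#' over whole twin sets (`mode = "twin"`: near-identical exemplars move
#' together, discounting their pixel-level similarity) or over individual
#' objects (`mode = "object"`). p-values are
#' `(1 + #{null >= observed}) / (1 + n_perm)`, Holm-Bonferroni corrected
#' within the scheme.
#'
#' @param forest a `Forest`.
#' @param scheme a `CategoryScheme`.
#' @param twin_sets mapping of objects to twin sets: named vector (names =
#'   object ids) or vector aligned with `forest$object_ids`. Singletons are
#'   allowed.
#' @param n_perm permutations per category (the full-scale analysis uses
#'   1e6; tests use much less).
#' @param mode `"twin"`, `"object"` or both (default: both).
#' @param alpha significance level for the Holm-corrected flags.
#' @param seed integer seed.
#' @return data frame with one row per category: tree, ratio1, ratio2,
#'   overlap, and (per requested mode) `p_twin`/`sig_twin`,
#'   `p_object`/`sig_object`. Holm flags: `"**"` p<0.01, `"*"` p<0.05
#'   corrected; `"++"`/`"+"` the same uncorrected; `""` otherwise.
#' @export
dmst_overlap_test <- function(forest, scheme, twin_sets,
                              n_perm = 10000L, mode = c("twin", "object"),
                              alpha = 0.05, seed = 1L) {
  stopifnot(inherits(forest, "Forest"), inherits(scheme, "CategoryScheme"))
  mode <- match.arg(mode, several.ok = TRUE)
  ids <- forest$object_ids
  if (!is.null(names(twin_sets))) twin_sets <- twin_sets[ids]
  stopifnot(length(twin_sets) == length(ids))
  # semantic twins never straddle categories by construction; warn if they do
  if (scheme$kind == "semantic") {
    for (nm in names(scheme$categories)) {
      cat_ids <- scheme$categories[[nm]]
      ts <- twin_sets[ids %in% cat_ids]
      full <- twin_sets %in% ts
      if (any(full & !(ids %in% cat_ids)) && length(cat_ids) > 0) {
        warning(sprintf("twin set split across category boundary in '%s'", nm),
                call. = FALSE)
      }
    }
  }
  cl <- forest_clusters(forest)
  trees <- sort(unique(cl))
  subs <- lapply(trees, function(tr) {
    sel <- which(cl == tr)
    sub <- .subforest(forest, sel)
    list(sub = sub, sel = sel, ord = order(sub$depth, decreasing = TRUE))
  })
  n_univ <- length(ids)
  twin_idx <- split(seq_len(n_univ), twin_sets)
  max_iou_idx <- function(idx, cat_size) {
    z_all <- numeric(n_univ)
    z_all[idx] <- 1
    best <- 0
    for (s in subs) {
      z <- z_all[s$sel]
      if (sum(z) == 0) next
      best <- max(best, .max_iou_forest(s$sub, z, cat_size, s$ord))
    }
    best
  }
  sample_null_idx <- function(target, md) {
    if (md == "object") return(sample.int(n_univ, target))
    ord <- sample.int(length(twin_idx))
    picked <- integer(0)
    for (s in ord) {
      if (length(picked) >= target) break
      picked <- c(picked, twin_idx[[s]])
    }
    picked
  }
  rows <- list()
  with_seed(seed, {
    for (nm in names(scheme$categories)) {
      members <- intersect(scheme$categories[[nm]], ids)
      obs <- best_subtree_overlap(forest, members)
      row <- data.frame(category = nm, tree = obs$tree, ratio1 = obs$ratio1,
                        ratio2 = obs$ratio2, overlap = obs$score)
      for (md in mode) {
        null_ge <- 0L
        for (p in seq_len(n_perm)) {
          nc <- sample_null_idx(length(members), md)
          if (max_iou_idx(nc, length(nc)) >= obs$score - 1e-12) {
            null_ge <- null_ge + 1L
          }
        }
        row[[paste0("p_", md)]] <- (1 + null_ge) / (1 + n_perm)
      }
      rows[[nm]] <- row
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (md in mode) {
    p <- out[[paste0("p_", md)]]
    out[[paste0("sig_", md)]] <- .holm_flags(p, alpha)
  }
  out
}

# Holm-Bonferroni significance flags matching the published table notation
.holm_flags <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  holm_sig01 <- holm_sig05 <- logical(m)
  blocked01 <- blocked05 <- FALSE
  for (i in seq_len(m)) {
    j <- ord[i]
    thr <- m - i + 1
    if (!blocked01 && p[j] < 0.01 / thr) holm_sig01[j] <- TRUE else blocked01 <- TRUE
    if (!blocked05 && p[j] < alpha / thr) holm_sig05[j] <- TRUE else blocked05 <- TRUE
  }
  ifelse(holm_sig01, "**",
         ifelse(holm_sig05, "*+",
                ifelse(p < 0.01, "++", ifelse(p < 0.05, "+", ""))))
}

#' Write an overlap results table
#'
#' @param results data frame from [dmst_overlap_test()] or
#'   [kmeans_overlap_test()].
#' @param path file path.
#' @export
write_overlap_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
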