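#' Normalize responses into a population matrix
#'
#' Mean firing rate per (neuron, object) over the response window, then each
#' neuron's responses across the object set are z-scored (mean subtracted,
#' divided by the sample SD). Each object is then represented by the vector
#' of normalized responses of all neurons (one row per object). Neurons with
#' zero variance across objects are non-informative and dropped with a
#' warning.
#'
#' @param ds a `ResponseDataset`.
#' @return a `PopulationMatrix`: numeric matrix objects x neurons with each
#'   column mean 0 and SD 1.
#' @export
normalize_responses <- function(ds) {
  stopifnot(inherits(ds, "ResponseDataset"))
  m <- t(mean_rates(ds))                    # objects x neurons
  if (nrow(m) < 2) stop("need >= 2 objects", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance neuron(s)", sum(drop)))
    m <- m[, !drop, drop = FALSE]
  }
  pm <- scale(m)
  attr(pm, "scaled:center") <- NULL
  attr(pm, "scaled:scale") <- NULL
  class(pm) <- c("PopulationMatrix", class(pm))
  pm
}

#' Pearson similarity and dissimilarity of population vectors
#'
#' The similarity of two objects is the Pearson correlation `r_ij` of their
#' population vectors; the dissimilarity is `d_ij = 1 - r_ij`.
#'
#' @param pm a `PopulationMatrix` (objects x neurons).
#' @return a `SimilarityMatrix`: list with `r` and `d` (objects x objects).
#' @export
similarity_matrix <- function(pm) {
  stopifnot(is.matrix(pm), ncol(pm) >= 2)
  sds <- apply(pm, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(pm)))
  if (any(sds == 0)) r[sds == 0, ] <- r[, sds == 0] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, d = 1 - r), class = "SimilarityMatrix")
}

#' PCA of the population matrix with property correlations
#'
#' Principal component analysis of the objects x neurons matrix. For each
#' requested (component, property) pair, reports the Pearson correlation
#' between the property values and the object ranking along that component,
#' with its t-test p-value. The sign of a principal component axis is
#' arbitrary; both the signed r (under the convention that each component's
#' loading vector has positive sum) and |r| are reported.
#'
#' @param pm a `PopulationMatrix`.
#' @param props property table ([property_table()]) row-aligned with `pm`.
#' @param components integer vector of components to test.
#' @param properties character vector of property columns to test.
#' @return list with `explained` (fraction of variance per component) and
#'   `cor` (data frame: component, property, r, abs_r, p).
#' @export
pca_property_correlation <- function(pm, props, components = 1:2,
                                     properties = c("area", "luminance",
                                                    "contrast",
                                                    "aspect_ratio")) {
  stopifnot(is.matrix(pm), nrow(pm) >= 2)
  if (max(components) > min(dim(pm))) {
    stop("more components requested than min(objects, neurons)",
         call. = FALSE)
  }
  pc <- stats::prcomp(pm, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  rows <- list()
  for (comp in components) {
    # fix the arbitrary sign so results are reproducible across BLAS builds
    sgn <- if (sum(pc$rotation[, comp]) < 0) -1 else 1
    score_rank <- rank(sgn * pc$x[, comp])
    for (prop in properties) {
      v <- props[[prop]]
      ok <- !is.na(v)
      r <- safe_cor(v[ok], score_rank[ok])
      n <- sum(ok)
      p <- if (is.na(r) || n < 3) NA_real_ else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, property = prop, r = r, abs_r = abs(r), p = p)
    }
  }
  list(explained = explained, cor = do.call(rbind, rows))
}

# serialize an hclust tree as a Newick string (display interface)
hclust_to_newick <- function(hc) {
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_len(nrow(hc$merge) + 1))
  rec <- function(i, parent_h) {
    if (i < 0) return(paste0(lab[-i], ":", format(parent_h)))
    ch <- hc$merge[i, ]
    h <- hc$height[i]
    paste0("(", rec(ch[1], h), ",", rec(ch[2], h), "):",
           format(parent_h - h))
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", rec(hc$merge[root, 1], h), ",", rec(hc$merge[root, 2], h),
         ");")
}

#' Hierarchical clustering with a chi-squared test on the first two branches
#'
#' Average-linkage agglomerative clustering of the dissimilarity matrix,
#' cut at the root into two branches; a Pearson chi-squared test on the
#' 2 x 2 branch-by-label contingency table asks whether a binary object
#' label (e.g. animate/inanimate, large/small) segregates between them.
#'
#' @param sm a `SimilarityMatrix`.
#' @param labels logical or two-level vector of object labels, aligned with
#'   the matrix rows.
#' @return list with `hclust`, `branch` (1/2 per object), `table`,
#'   `statistic`, `p` (`NA` with a message if the label is constant), and
#'   `newick`.
#' @export
hierarchical_branch_test <- function(sm, labels) {
  stopifnot(inherits(sm, "SimilarityMatrix"))
  n <- nrow(sm$d)
  stopifnot(length(labels) == n)
  hc <- stats::hclust(stats::as.dist(sm$d), method = "average")
  branch <- stats::cutree(hc, k = 2)
  if (length(unique(labels)) < 2) {
    message("constant labels: chi-squared test undefined")
    return(list(hclust = hc, branch = branch, table = table(branch, labels),
                statistic = NA_real_, p = NA_real_,
                newick = hclust_to_newick(hc)))
  }
  tab <- table(branch, labels)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(hclust = hc, branch = branch, table = tab,
       statistic = unname(ct$statistic), p = ct$p.value,
       newick = hclust_to_newick(hc))
}

# spherical-Gaussian log-likelihood of a k-means solution (X-means style:
# one variance shared across clusters)
.kmeans_loglik <- function(X, km) {
  n <- nrow(X)
  d <- ncol(X)
  k <- nrow(km$centers)
  rss <- km$tot.withinss
  if (n <= k) return(-Inf)
  sigma2 <- rss / (d * (n - k))
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  nc <- as.vector(table(factor(km$cluster, levels = seq_len(k))))
  sum(nc * log(pmax(nc, 1) / n)) - n * d / 2 * log(2 * pi * sigma2) -
    d * (n - k) / 2
}

#' Select the number of k-means clusters by BIC and AIC
#'
#' For each k in `k_range`, keeps the best of `n_restarts` seeded k-means
#' solutions and scores it with a spherical-Gaussian log-likelihood; the
#' number of free parameters is `k*dim + k + 1` (centres, mixing weights,
#' shared variance). Returns the argmin of BIC and of AIC.
#'
#' @param pm numeric matrix (objects x dimensions).
#' @param k_range integer vector of candidate k.
#' @param n_restarts random restarts per k (default 20).
#' @param seed integer seed.
#' @return list with `k_bic`, `k_aic` and the score table `scores`.
#' @export
select_k <- function(pm, k_range = 1:20, n_restarts = 20L, seed = 1L) {
  stopifnot(is.matrix(pm))
  n <- nrow(pm)
  if (any(k_range < 1) || any(k_range > n - 1)) {
    stop("k_range must lie within [1, n_objects - 1]", call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(k_range, function(k) {
      km <- tryCatch(
        stats::kmeans(pm, centers = k, nstart = n_restarts, iter.max = 100),
        error = function(e) NULL)
      if (is.null(km)) {
        warning(sprintf("k = %d skipped (empty cluster in all restarts)", k))
        return(NULL)
      }
      ll <- .kmeans_loglik(pm, km)
      p <- k * ncol(pm) + k + 1
      data.frame(k = k, loglik = ll,
                 bic = -2 * ll + p * log(n), aic = -2 * ll + 2 * p)
    })
    scores <- do.call(rbind, rows)
    list(k_bic = scores$k[which.min(scores$bic)],
         k_aic = scores$k[which.min(scores$aic)],
         scores = scores)
  })
}

#' Animate/inanimate segregation test with k = 2 k-means
#'
#' Runs `n_runs` k-means partitions with k = 2 and computes the average
#' absolute difference between the fraction of animate objects in the two
#' clusters. Significance is assessed by randomly shuffling the labels among
#' the clusters of each run and recomputing the statistic.
#'
#' @param pm a `PopulationMatrix`.
#' @param animate_labels logical vector (TRUE = animate) aligned with rows.
#' @param n_runs number of k-means runs (default 100).
#' @param n_perm number of label shuffles (default 1000).
#' @param seed integer seed.
#' @return list with `statistic` (mean |difference of fractions|), `p`, and
#'   the per-run differences `runs`.
#' @export
animate_segregation_test <- function(pm, animate_labels, n_runs = 100L,
                                     n_perm = 1000L, seed = 1L) {
  stopifnot(is.matrix(pm), length(animate_labels) == nrow(pm))
  animate_labels <- as.logical(animate_labels)
  if (!any(animate_labels) || all(animate_labels)) {
    stop("both label classes must be non-empty", call. = FALSE)
  }
  n <- nrow(pm)
  n_anim <- sum(animate_labels)
  with_seed(seed, {
    membership <- matrix(FALSE, n_runs, n)   # cluster-1 indicator per run
    for (r in seq_len(n_runs)) {
      repeat {
        km <- stats::kmeans(pm, centers = 2, iter.max = 100)
        if (min(km$size) > 0) break
        message("empty cluster in a k = 2 run; rerunning")
      }
      membership[r, ] <- km$cluster == 1
    }
    s1 <- rowSums(membership)
    stat_for <- function(lab) {
      a1 <- membership %*% lab
      mean(abs(a1 / s1 - (n_anim - a1) / (n - s1)))
    }
    diffs <- abs(membership %*% animate_labels / s1 -
                   (n_anim - membership %*% animate_labels) / (n - s1))
    observed <- stat_for(animate_labels)
    # one label shuffle per permutation, evaluated across all stored runs
    # (the runs are correlated through the shared labels; shuffling
    # independently per run would understate the null variance)
    null_stat <- vapply(seq_len(n_perm), function(p) {
      stat_for(sample(animate_labels))
    }, numeric(1))
    list(statistic = observed,
         p = (1 + sum(null_stat >= observed)) / (1 + n_perm),
         runs = as.vector(diffs))
  })
}

#' Face selectivity index
#'
#' `FSI = (mean face response - mean non-face response) /
#'        (mean face response + mean non-face response)`
#' per neuron, on mean firing rates. `NA` where the denominator is 0.
#'
#' @param ds a `ResponseDataset`.
#' @param face_ids object ids of the face stimuli.
#' @return named numeric vector of per-neuron FSI.
#' @export
face_selectivity_index <- function(ds, face_ids) {
  stopifnot(inherits(ds, "ResponseDataset"), length(face_ids) > 0)
  rates <- mean_rates(ds)
  is_face <- colnames(rates) %in% face_ids
  if (!any(is_face) || all(is_face)) {
    stop("face and non-face sets must both be non-empty", call. = FALSE)
  }
  mf <- rowMeans(rates[, is_face, drop = FALSE])
  mn <- rowMeans(rates[, !is_face, drop = FALSE])
  fsi <- (mf - mn) / (mf + mn)
  fsi[mf + mn == 0] <- NA_real_
  fsi
}
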