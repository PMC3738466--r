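#' Parameters for bounded-depth minimum-spanning-forest clustering
#'
#' The dissimilarity graph is augmented with a ROOT node connected to every
#' object at cost `lambda`; the clustering seeks the minimum-cost spanning
#' tree of the augmented graph in which every object lies within `d_max`
#' links of ROOT (objects attached directly to ROOT are cluster centres, at
#' depth 1; members of their trees sit at most `d_max - 1` links below the
#' centre). A larger `lambda` yields fewer clusters.
#'
#' @param lambda root-attachment cost (same units as the dissimilarities).
#' @param d_max maximum node depth counted from ROOT (>= 1).
#' @param n_iter max-sum message-passing iterations.
#' @param seed seed for the message initialization.
#' @param n_restarts independent message-passing restarts; the best valid
#'   configuration over all restarts and iterations is returned.
#' @param reinforce reinforcement rate (the external field grows linearly
#'   as `reinforce * t`).
#' @param damping message damping in `[0, 1)`.
#' @return a `dmst_params` list.
#' @export
dmst_params <- function(lambda, d_max = 6L, n_iter = 600L, seed = 1L,
                        n_restarts = 3L, reinforce = 0.001, damping = 0.3) {
  stopifnot(lambda >= 0, d_max >= 1, n_iter >= 1, n_restarts >= 1)
  structure(list(lambda = lambda, d_max = as.integer(d_max),
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 reinforce = reinforce, damping = damping),
            class = "dmst_params")
}

.check_dissimilarity <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("dissimilarity must be a square matrix", call. = FALSE)
  }
  if (any(d < 0)) stop("dissimilarity must be non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("dissimilarity must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) {
    stop("dissimilarity must have a zero diagonal", call. = FALSE)
  }
  invisible(TRUE)
}

# depths from a parent vector (0 = ROOT); NA for nodes not reaching ROOT
.forest_depths <- function(parent) {
  n <- length(parent)
  depth <- rep(NA_integer_, n)
  depth[parent == 0] <- 1L
  repeat {
    frontier <- which(is.na(depth) & parent > 0 & !is.na(depth[pmax(parent, 1)]))
    if (length(frontier) == 0) break
    depth[frontier] <- depth[parent[frontier]] + 1L
  }
  depth
}

# repair an arbitrary parent proposal into a valid depth-bounded forest:
# nodes in cycles or beyond d_max are re-attached to ROOT
.repair_parents <- function(parent, d_max) {
  n <- length(parent)
  repeat {
    depth <- .forest_depths(parent)
    bad_depth <- which(!is.na(depth) & depth > d_max)
    if (length(bad_depth) > 0) {
      parent[bad_depth] <- 0L
      next
    }
    unresolved <- which(is.na(depth))
    if (length(unresolved) == 0) break
    parent[unresolved[1]] <- 0L
  }
  parent
}

# greedy single-link improvement: repeatedly move one node (with its
# subtree) under a cheaper parent while respecting acyclicity and the depth
# bound; polishes the configuration decoded from the messages
.polish_parents <- function(parent, d, lambda, d_max) {
  n <- length(parent)
  recompute <- function() {
    depth <- .forest_depths(parent)
    ord <- order(depth)
    height <- rep(0L, n)
    for (v in rev(ord)) {
      p <- parent[v]
      if (p > 0) height[p] <- max(height[p], height[v] + 1L)
    }
    list(depth = depth, ord = ord, height = height)
  }
  st <- recompute()
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      # descendants of i (forbidden as new parents)
      desc <- rep(FALSE, n)
      desc[i] <- TRUE
      for (v in st$ord) {
        if (parent[v] > 0 && desc[parent[v]]) desc[v] <- TRUE
      }
      cur <- if (parent[i] == 0) lambda else d[i, parent[i]]
      cand_cost <- ifelse(desc | st$depth + 1L + st$height[i] > d_max,
                          Inf, d[i, ])
      best_j <- which.min(cand_cost)
      best <- min(cand_cost[best_j], lambda)
      if (best < cur - 1e-12) {
        parent[i] <- if (lambda <= cand_cost[best_j]) 0L else best_j
        st <- recompute()
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  parent
}

# re-root the tree containing r so that r becomes the centre (root child);
# the undirected edge set (and so the cost) is unchanged, but depths change
.reroot_at <- function(parent, r) {
  path <- r
  v <- r
  while (parent[v] > 0) {
    v <- parent[v]
    path <- c(path, v)
  }
  for (t in seq_along(path)[-1]) parent[path[t]] <- path[t - 1]
  parent[r] <- 0L
  parent
}

# single-move descent plus cost-neutral re-rooting plateau moves
.polish_full <- function(parent, d, lambda, d_max) {
  parent <- .polish_parents(parent, d, lambda, d_max)
  cost <- .forest_cost(parent, d, lambda)
  repeat {
    improved <- FALSE
    for (r in which(parent > 0)) {
      p2 <- .repair_parents(.reroot_at(parent, r), d_max)
      p3 <- .polish_parents(p2, d, lambda, d_max)
      c3 <- .forest_cost(p3, d, lambda)
      if (c3 < cost - 1e-12) {
        parent <- p3
        cost <- c3
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  parent
}

.forest_cost <- function(parent, d, lambda) {
  ch <- which(parent > 0)
  sum(d[cbind(ch, parent[ch])]) + lambda * sum(parent == 0)
}

.make_forest <- function(parent, d, lambda, d_max, object_ids,
                         weights = NULL, converged = TRUE) {
  depth <- .forest_depths(parent)
  if (is.null(weights)) weights <- rep(1, length(parent))
  structure(list(parent = parent, depth = depth, weights = weights,
                 object_ids = object_ids, d_max = d_max, lambda = lambda,
                 cost = .forest_cost(parent, d, lambda),
                 converged = converged),
            class = "Forest")
}

#' @export
print.Forest <- function(x, ...) {
  cat(sprintf("Forest: %d objects, %d trees, d_max %d, cost %.4f%s\n",
              length(x$parent), sum(x$parent == 0), x$d_max, x$cost,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Cluster membership of a forest
#'
#' @param forest a `Forest`.
#' @return integer vector assigning each object to its tree (cluster).
#' @export
forest_clusters <- function(forest) {
  parent <- forest$parent
  n <- length(parent)
  anc <- seq_len(n)
  repeat {
    up <- parent[anc]
    move <- up > 0
    if (!any(move)) break
    anc[move] <- up[move]
  }
  match(anc, sort(unique(anc)))
}

## ------------------------------------------------------- max-sum solver

# One max-sum run with reinforcement; decodes every iteration and returns the
# best valid configuration seen.
.maxsum_run <- function(d, lambda, d_max, n_iter, reinforce, damping, seed,
                        d_msg = d) {
  n <- nrow(d)
  with_seed(seed, {
    # messages indexed [sender, receiver, depth-of-receiver-context]
    A <- array(stats::rnorm(n * n * d_max, sd = 1e-3), c(n, n, d_max))
    B <- array(stats::rnorm(n * n * d_max, sd = 1e-3), c(n, n, d_max))
    Hroot <- numeric(n)                    # reinforcement fields
    Hn <- array(0, c(n, n, d_max))         # [parent, node, depth]
    best_cost <- Inf
    best_parent <- NULL
    negC <- -d_msg
    for (it in seq_len(n_iter)) {
      # D[k, j, dep]: message from k to j when j is at depth dep and
      # neither is the other's parent
      Amax <- A[, , 1]
      if (d_max >= 2) for (dep in 2:d_max) Amax <- pmax(Amax, A[, , dep])
      D <- array(Amax, c(n, n, d_max))
      if (d_max >= 2) {
        for (dep in seq_len(d_max - 1)) {
          D[, , dep] <- pmax(Amax, B[, , dep + 1])
        }
      }
      SD <- colSums(D)                     # [j, dep]
      newA <- array(-Inf, c(n, n, d_max))
      newB <- array(-Inf, c(n, n, d_max))
      u <- array(-Inf, c(n, n, d_max))     # value of j taking parent pi at dep
      # depth 1: only ROOT can be the parent
      val_root <- -lambda + SD[, 1] + Hroot
      for (dep in seq_len(d_max)) {
        if (dep == 1) {
          # A[j, i, 1] = val_root[j] - D[i, j, 1]
          newA[, , 1] <- matrix(val_root, n, n) - t(D[, , 1])
        } else {
          u[, , dep] <- negC + A[, , dep - 1] - D[, , dep] + Hn[, , dep]
          diag(u[, , dep]) <- -Inf
          # top-2 over parents pi for each j
          uj <- u[, , dep]
          max1 <- apply(uj, 2, max)
          arg1 <- apply(uj, 2, which.max)
          uj2 <- uj
          uj2[cbind(arg1, seq_len(n))] <- -Inf
          max2 <- apply(uj2, 2, max)
          # A[j, i, dep] = (i == arg1[j] ? max2[j] : max1[j]) + SD[j, dep]
          #                 - D[i, j, dep]
          mx <- matrix(max1, n, n)                 # rows j
          mx[cbind(seq_len(n), arg1)] <- max2      # exclude i = arg1[j]
          newA[, , dep] <- mx + SD[, dep] - t(D[, , dep])
        }
        if (dep >= 2) {
          # B[j, i, dep] = -c(j, i) + H + SD[j, dep] - D[i, j, dep]
          newB[, , dep] <- negC + t(Hn[, , dep]) + SD[, dep] - t(D[, , dep])
        }
      }
      # normalize each directed edge's message vector by one shared constant
      # (A and B components must keep their relative values)
      nrm <- newA[, , 1]
      for (dep in seq_len(d_max)) {
        nrm <- pmax(nrm, newA[, , dep])
        if (dep >= 2) nrm <- pmax(nrm, newB[, , dep])
      }
      for (dep in seq_len(d_max)) {
        newA[, , dep] <- newA[, , dep] - nrm
        if (dep >= 2) newB[, , dep] <- newB[, , dep] - nrm
      }
      A <- damping * A + (1 - damping) * newA
      B <- damping * B + (1 - damping) * newB
      # decode beliefs: b(j, root) and b(j, pi, dep)
      b_root <- val_root
      parent <- integer(n)
      b_best <- b_root
      for (dep in 2:max(2, d_max)) {
        if (dep > d_max) break
        bj <- u[, , dep] + matrix(SD[, dep], n, n, byrow = TRUE)
        mx <- apply(bj, 2, max)
        ag <- apply(bj, 2, which.max)
        upd <- mx > b_best
        parent[upd] <- ag[upd]
        b_best[upd] <- mx[upd]
      }
      # reinforcement field grows linearly
      g <- reinforce * it
      Hroot <- Hroot + g * (b_root - b_best)
      for (dep in 2:max(2, d_max)) {
        if (dep > d_max) break
        bj <- u[, , dep] + matrix(SD[, dep], n, n, byrow = TRUE)
        Hn[, , dep] <- Hn[, , dep] + g * (bj - matrix(b_best, n, n, byrow = TRUE))
      }
      fixed <- .repair_parents(parent, d_max)
      if (n <= 32) fixed <- .polish_parents(fixed, d, lambda, d_max)
      cost <- .forest_cost(fixed, d, lambda)
      if (cost < best_cost) {
        best_cost <- cost
        best_parent <- fixed
      }
    }
    best_parent <- if (n <= 64) {
      .polish_full(best_parent, d, lambda, d_max)
    } else {
      .polish_parents(best_parent, d, lambda, d_max)
    }
    list(parent = best_parent, cost = .forest_cost(best_parent, d, lambda))
  })
}

#' Build a depth-bounded minimum-spanning forest by max-sum message passing
#'
#' Approximates the minimum-cost spanning tree of the ROOT-augmented graph
#' under the depth bound (see [dmst_params()]). The solver is max-sum
#' message passing with linear reinforcement and seeded random
#' initialization; each iteration's decoded configuration is repaired into a
#' valid forest and the best one found is returned. For small instances
#' [exact_forest()] provides the exact reference solution.
#'
#' @param d symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param params a [dmst_params()].
#' @return a `Forest` (per-object parent pointers, 0 = ROOT; link weights 1).
#' @export
build_forest <- function(d, params) {
  stopifnot(inherits(params, "dmst_params"))
  .check_dissimilarity(d)
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1) {
    return(.make_forest(0L, d, params$lambda, params$d_max, ids))
  }
  best <- NULL
  for (r in seq_len(params$n_restarts)) {
    rs <- derive_seed(params$seed, paste0("restart", r))
    # restarts beyond the first perturb the costs seen by the messages
    # (never the costs used to score configurations) to escape a shared basin
    d_msg <- if (r == 1) d else with_seed(rs, {
      eps <- matrix(stats::rnorm(n * n, sd = 0.03 * stats::median(d[d > 0])),
                    n, n)
      pmax(d + (eps + t(eps)) / 2, 0) * (1 - diag(n))
    })
    run <- .maxsum_run(d, params$lambda, params$d_max, params$n_iter,
                       params$reinforce, params$damping,
                       derive_seed(rs, "run"), d_msg = d_msg)
    if (is.null(best) || run$cost < best$cost) best <- run
  }
  .make_forest(best$parent, d, params$lambda, params$d_max, ids)
}

## ------------------------------------------------------------ exact solver

#' Exact depth-bounded minimum-spanning forest (small instances)
#'
#' Exact dynamic program over node subsets; feasible for n <= 12 or so,
#' intended as the reference oracle for [build_forest()].
#'
#' @param d dissimilarity matrix (see [build_forest()]).
#' @param lambda root-attachment cost.
#' @param d_max maximum node depth from ROOT.
#' @return a `Forest` with the optimal cost.
#' @export
exact_forest <- function(d, lambda, d_max = 6L) {
  .check_dissimilarity(d)
  n <- nrow(d)
  if (n > 14) stop("exact solver limited to n <= 14", call. = FALSE)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  nmask <- bitwShiftL(1L, n)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  depth_levels <- min(d_max - 1L, n - 1L)  # levels available below a centre

  # f[[dep]][c, mask]: min cost of hanging node set `mask` strictly below c
  # within dep more levels
  f <- vector("list", depth_levels + 1L)
  f0 <- matrix(Inf, n, nmask)
  f0[, 1] <- 0
  f[[1]] <- f0
  lowbit <- integer(nmask)
  for (m in seq_len(nmask - 1L)) lowbit[m + 1L] <- bitwAnd(m, -m)
  lowidx <- match(lowbit, bits)

  if (depth_levels >= 1) {
    for (dep in seq_len(depth_levels)) {
      fprev <- f[[dep]]
      # t[r, S]: cost of covering S as ONE child branch of r (child c in S)
      tmat <- matrix(Inf, n, nmask)
      tmat[, 1] <- Inf
      for (m in seq_len(nmask - 1L)) {
        S <- m + 1L
        members <- which(bitwAnd(m, bits) > 0L)
        best <- rep(Inf, n)
        for (c in members) {
          rest <- bitwXor(m, bits[c]) + 1L
          fc <- fprev[c, rest]
          if (is.finite(fc)) best <- pmin(best, d[, c] + fc)
        }
        tmat[, S] <- best
      }
      fcur <- matrix(Inf, n, nmask)
      fcur[, 1] <- 0
      for (m in seq_len(nmask - 1L)) {
        v <- lowbit[m + 1L]
        restm <- bitwXor(m, v)
        best <- rep(Inf, n)
        # submasks T of restm; S = T | v
        Tm <- restm
        repeat {
          S <- bitwOr(Tm, v)
          cand <- tmat[, S + 1L] + fcur[, bitwXor(m, S) + 1L]
          best <- pmin(best, cand)
          if (Tm == 0L) break
          Tm <- bitwAnd(Tm - 1L, restm)
        }
        fcur[, m + 1L] <- best
      }
      f[[dep + 1L]] <- fcur
    }
  }

  ftop <- f[[depth_levels + 1L]]
  # troot[S]: cost of one tree covering S (centre c in S attached to ROOT)
  troot <- rep(Inf, nmask)
  for (m in seq_len(nmask - 1L)) {
    members <- which(bitwAnd(m, bits) > 0L)
    best <- Inf
    for (c in members) {
      fc <- ftop[c, bitwXor(m, bits[c]) + 1L]
      best <- min(best, lambda + fc)
    }
    troot[m + 1L] <- best
  }
  FF <- rep(Inf, nmask)
  FF[1] <- 0
  for (m in seq_len(nmask - 1L)) {
    v <- lowbit[m + 1L]
    restm <- bitwXor(m, v)
    best <- Inf
    Tm <- restm
    repeat {
      S <- bitwOr(Tm, v)
      best <- min(best, troot[S + 1L] + FF[bitwXor(m, S) + 1L])
      if (Tm == 0L) break
      Tm <- bitwAnd(Tm - 1L, restm)
    }
    FF[m + 1L] <- best
  }

  # ---- reconstruction by re-deriving the argmins top-down
  parent <- integer(n)
  eps <- 1e-9
  split_tree <- function(c, mask, dep) {
    # assign parents for nodes in `mask`, all below c within dep levels
    if (mask == 0L) return(invisible())
    v <- lowbit[mask + 1L]
    restm <- bitwXor(mask, v)
    target <- f[[dep + 1L]][c, mask + 1L]
    Tm <- restm
    repeat {
      S <- bitwOr(Tm, v)
      rem <- bitwXor(mask, S)
      # branch S under some child cc, remainder rem stays under c
      members <- which(bitwAnd(S, bits) > 0L)
      for (cc in members) {
        rest <- bitwXor(S, bits[cc])
        val <- d[c, cc] + f[[dep]][cc, rest + 1L] + f[[dep + 1L]][c, rem + 1L]
        if (is.finite(val) && val <= target + eps) {
          parent[cc] <<- c
          split_tree(cc, rest, dep - 1L)
          split_tree(c, rem, dep)
          return(invisible())
        }
      }
      if (Tm == 0L) break
      Tm <- bitwAnd(Tm - 1L, restm)
    }
    stop("internal error: reconstruction failed", call. = FALSE)
  }
  split_forest <- function(mask) {
    if (mask == 0L) return(invisible())
    v <- lowbit[mask + 1L]
    restm <- bitwXor(mask, v)
    target <- FF[mask + 1L]
    Tm <- restm
    repeat {
      S <- bitwOr(Tm, v)
      rem <- bitwXor(mask, S)
      members <- which(bitwAnd(S, bits) > 0L)
      for (c in members) {
        rest <- bitwXor(S, bits[c])
        val <- lambda + ftop[c, rest + 1L] + FF[rem + 1L]
        if (is.finite(val) && val <= target + eps) {
          parent[c] <<- 0L
          split_tree(c, rest, depth_levels)
          split_forest(rem)
          return(invisible())
        }
      }
      if (Tm == 0L) break
      Tm <- bitwAnd(Tm - 1L, restm)
    }
    stop("internal error: reconstruction failed", call. = FALSE)
  }
  split_forest(nmask - 1L)
  .make_forest(parent, d, lambda, d_max, ids)
}

## ------------------------------------------------------- stability analysis

# fraction of object pairs whose co-clustering status agrees in two partitions
.pair_agreement <- function(cl1, cl2) {
  co1 <- outer(cl1, cl1, "==")
  co2 <- outer(cl2, cl2, "==")
  ut <- upper.tri(co1)
  mean(co1[ut] == co2[ut])
}

#' Scan D-MST parameter space for stability
#'
#' Runs the forest builder `n_runs` times (distinct seeds) for every
#' (lambda, d_max) grid cell, recording the mean and SD of the cluster count
#' and the mean pairwise co-clustering agreement between runs. The overlap is
#' additionally smoothed over lambda with a sliding window, and a stable
#' region (contiguous lambda span where the cluster-count SD and
#' 1 - smoothed overlap fall below the thresholds) is reported per d_max.
#'
#' @param d dissimilarity matrix.
#' @param lambda_grid,dmax_grid parameter grids (non-empty).
#' @param n_runs runs per cell (default 50).
#' @param seed master seed (per-run seeds are derived from it; pass the same
#'   seed to reproduce the scan).
#' @param window sliding-window width on lambda for overlap smoothing.
#' @param sd_threshold,overlap_threshold stability thresholds.
#' @param n_iter,n_restarts forwarded to [dmst_params()].
#' @return a `StabilityReport`: list with `cells` (data frame) and
#'   `stable_regions` (per d_max lambda span or NULL).
#' @export
stability_scan <- function(d, lambda_grid, dmax_grid, n_runs = 50L, seed = 1L,
                           window = 0.15, sd_threshold = 0.5,
                           overlap_threshold = 0.1,
                           n_iter = 100L, n_restarts = 1L) {
  stopifnot(length(lambda_grid) > 0, length(dmax_grid) > 0)
  rows <- list()
  for (dm in dmax_grid) {
    for (lam in lambda_grid) {
      cls <- vector("list", n_runs)
      ncl <- numeric(n_runs)
      for (r in seq_len(n_runs)) {
        pr <- dmst_params(lambda = lam, d_max = dm, n_iter = n_iter,
                          n_restarts = n_restarts,
                          seed = derive_seed(seed, sprintf("scan_%g_%d_%d",
                                                           lam, dm, r)))
        fo <- build_forest(d, pr)
        cls[[r]] <- forest_clusters(fo)
        ncl[r] <- sum(fo$parent == 0)
      }
      ov <- if (n_runs < 2) 1 else {
        pairs <- utils::combn(n_runs, 2)
        mean(vapply(seq_len(ncol(pairs)), function(i) {
          .pair_agreement(cls[[pairs[1, i]]], cls[[pairs[2, i]]])
        }, numeric(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lambda = lam, d_max = dm, mean_clusters = mean(ncl),
        sd_clusters = stats::sd(ncl), overlap = ov)
    }
  }
  cells <- do.call(rbind, rows)
  cells$sd_clusters[is.na(cells$sd_clusters)] <- 0
  cells$overlap_smooth <- NA_real_
  regions <- list()
  for (dm in dmax_grid) {
    sel <- cells$d_max == dm
    lam <- cells$lambda[sel]
    cells$overlap_smooth[sel] <- vapply(lam, function(l) {
      mean(cells$overlap[sel][abs(lam - l) <= window / 2])
    }, numeric(1))
    ok <- cells$sd_clusters[sel] <= sd_threshold &
      (1 - cells$overlap_smooth[sel]) <= overlap_threshold
    regions[[as.character(dm)]] <- if (any(ok)) {
      range(lam[ok])
    } else NULL
  }
  structure(list(cells = cells, stable_regions = regions),
            class = "StabilityReport")
}

#' Consensus forest from repeated runs
#'
#' Link weight is the frequency of each (undirected) link — including
#' root attachments — across runs. Links with weight below `link_threshold`
#' are dropped; the rest are added greedily in descending weight while the
#' result remains a forest, then oriented away from ROOT and repaired to the
#' depth bound. Objects left disconnected become singleton trees.
#'
#' @param runs list of `Forest` objects over the same object set.
#' @param link_threshold minimum link frequency in `[0, 1]`.
#' @return a `Forest` whose `weights` hold each kept link's frequency
#'   (weight of the link from each object to its parent).
#' @export
consensus_forest <- function(runs, link_threshold = 0.5) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "Forest")))
  n <- length(runs[[1]]$parent)
  ids <- runs[[1]]$object_ids
  stopifnot(all(vapply(runs, function(f) length(f$parent) == n, TRUE)))
  d_max <- runs[[1]]$d_max
  lambda <- runs[[1]]$lambda
  # undirected link counts over node pairs and root attachments (node 0)
  counts <- new.env(hash = TRUE)
  for (f in runs) {
    for (i in seq_len(n)) {
      a <- min(i, f$parent[i]); b <- max(i, f$parent[i])
      key <- paste0(a, "_", b)
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- ls(counts)
  w <- vapply(keys, function(k) counts[[k]], numeric(1)) / length(runs)
  ends <- do.call(rbind, strsplit(keys, "_"))
  links <- data.frame(a = as.integer(ends[, 1]), b = as.integer(ends[, 2]),
                      w = w)
  links <- links[links$w >= link_threshold, , drop = FALSE]
  links <- links[order(-links$w, links$a, links$b), , drop = FALSE]
  # greedy maximum-weight forest (union-find over nodes 0..n; 0 = ROOT)
  comp <- 0:n
  find <- function(x) { while (comp[x + 1L] != x) x <- comp[x + 1L]; x }
  adj <- vector("list", n + 1L)
  lw <- numeric(0)
  for (i in seq_len(nrow(links))) {
    ra <- find(links$a[i]); rb <- find(links$b[i])
    if (ra != rb) {
      comp[ra + 1L] <- rb
      adj[[links$a[i] + 1L]] <- c(adj[[links$a[i] + 1L]], links$b[i])
      adj[[links$b[i] + 1L]] <- c(adj[[links$b[i] + 1L]], links$a[i])
      lw[paste0(links$a[i], "_", links$b[i])] <- links$w[i]
    }
  }
  # orient away from ROOT
  parent <- rep(NA_integer_, n)
  queue <- adj[[1]]
  for (v in queue) parent[v] <- 0L
  visited <- c(0L, queue)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v + 1L]]) {
      if (!(u %in% visited)) {
        parent[u] <- v
        visited <- c(visited, u)
        queue <- c(queue, u)
      }
    }
  }
  orphan <- which(is.na(parent))
  if (length(orphan) > 0) {
    message(sprintf("%d object(s) disconnected at threshold %.2f; made singletons",
                    length(orphan), link_threshold))
    parent[orphan] <- 0L
  }
  parent <- .repair_parents(parent, d_max)
  weights <- vapply(seq_len(n), function(i) {
    key <- paste0(min(i, parent[i]), "_", max(i, parent[i]))
    if (key %in% names(lw)) lw[[key]] else 0
  }, numeric(1))
  # cost bookkeeping needs a dissimilarity matrix; rebuild from the first run
  # is impossible here, so report cost NA
  depth <- .forest_depths(parent)
  structure(list(parent = parent, depth = depth, weights = weights,
                 object_ids = ids, d_max = d_max, lambda = lambda,
                 cost = NA_real_, converged = TRUE),
            class = "Forest")
}

#' Serialize a forest as a delimited edge list
#'
#' Columns: `child`, `parent` (object id or `"ROOT"`), `weight`.
#'
#' @param forest a `Forest`.
#' @param path file path.
#' @export
write_forest <- function(forest, path) {
  ids <- forest$object_ids
  pid <- ifelse(forest$parent == 0, "ROOT", ids[pmax(forest$parent, 1)])
  utils::write.table(
    data.frame(child = ids, parent = pid, weight = forest$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
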