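#' Configuration of the simplified shape-feature model
#'
#' A reduced HMAX-style four-layer feedforward hierarchy: S1 Gabor filtering
#' (orientations x scales), C1 local OR-like max pooling over position and
#' adjacent scales, S2 Gaussian radial-basis template matching against C1
#' patches sampled from the stimulus set itself, and C2 global max pooling
#' over positions and scale bands. The full-scale published instantiations
#' use tens of thousands of C2 units; the default here is desk-scale
#' (`n_templates = 200`) and configurable.
#'
#' @param n_orientations number of Gabor orientations.
#' @param scales odd Gabor filter sizes in pixels (one per scale).
#' @param bands list of scale-index groups pooled together by C1.
#' @param c1_pool spatial pooling size per band.
#' @param c1_stride pooling stride per band; the overlapping default (3 px)
#'   keeps C2 nearly invariant to translations that are not multiples of the
#'   pooling grid.
#' @param n_templates number of S2/C2 templates.
#' @param patch_size C1 patch side length of each template.
#' @param sigma S2 radial-basis tuning width.
#' @return a `shapefeat_config` list.
#' @export
shapefeat_config <- function(n_orientations = 4L, scales = c(7L, 9L, 11L, 13L),
                             bands = list(1:2, 3:4), c1_pool = c(8L, 10L),
                             c1_stride = c(3L, 3L),
                             n_templates = 200L, patch_size = 4L, sigma = 1) {
  stopifnot(n_orientations >= 1, n_templates >= 1,
            length(c1_pool) == length(bands),
            length(c1_stride) == length(bands))
  structure(list(n_orientations = n_orientations, scales = scales,
                 bands = bands, c1_pool = c1_pool,
                 c1_stride = as.integer(c1_stride),
                 n_templates = as.integer(n_templates),
                 patch_size = as.integer(patch_size), sigma = sigma),
            class = "shapefeat_config")
}

# Gabor filter (zero mean, unit norm); sizing constants follow common
# published HMAX settings
.gabor <- function(size, theta) {
  sigma <- 0.0036 * size^2 + 0.35 * size + 0.18
  lambda <- sigma / 0.8
  gamma <- 0.3
  half <- (size - 1) / 2
  g <- outer(-half:half, -half:half, function(y, x) {
    X <- x * cos(theta) + y * sin(theta)
    Y <- -x * sin(theta) + y * cos(theta)
    exp(-(X^2 + gamma^2 * Y^2) / (2 * sigma^2)) * cos(2 * pi * X / lambda)
  })
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

# 'same' 2-D convolution via FFT
.conv2_same <- function(img, kern) {
  n <- nrow(img)
  m <- ncol(img)
  kn <- nrow(kern)
  pn <- n + kn - 1
  pm <- m + kn - 1
  pi_ <- matrix(0, pn, pm)
  pk <- matrix(0, pn, pm)
  pi_[1:n, 1:m] <- img
  pk[1:kn, 1:kn] <- kern
  full <- Re(stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE)) /
    (pn * pm)
  off <- (kn - 1) / 2
  full[(1 + off):(n + off), (1 + off):(m + off)]
}

# local max pooling with pool size p
.max_pool <- function(mat, p, stride = max(1L, floor(p / 2))) {
  rs <- seq(1, max(1, nrow(mat) - p + 1), by = stride)
  cs <- seq(1, max(1, ncol(mat) - p + 1), by = stride)
  out <- matrix(0, length(rs), length(cs))
  for (i in seq_along(rs)) {
    for (j in seq_along(cs)) {
      out[i, j] <- max(mat[rs[i]:min(rs[i] + p - 1, nrow(mat)),
                           cs[j]:min(cs[j] + p - 1, ncol(mat))])
    }
  }
  out
}

# C1 maps of one image: list over bands of (rows x cols x orientations)
.c1_maps <- function(img, cfg, gabors) {
  x <- img / 255 - 0.5
  s1 <- lapply(gabors, function(g) abs(.conv2_same(x, g)))
  lapply(seq_along(cfg$bands), function(b) {
    band <- cfg$bands[[b]]
    maps <- lapply(seq_len(cfg$n_orientations), function(o) {
      acc <- NULL
      for (s in band) {
        m <- s1[[(s - 1) * cfg$n_orientations + o]]
        acc <- if (is.null(acc)) m else pmax(acc, m)
      }
      .max_pool(acc, cfg$c1_pool[b], cfg$c1_stride[b])
    })
    array(unlist(maps), dim = c(dim(maps[[1]]), cfg$n_orientations))
  })
}

# all patch_size-square patches of a C1 band, unrolled to rows
.c1_patches <- function(c1, ps) {
  nr <- dim(c1)[1] - ps + 1
  nc <- dim(c1)[2] - ps + 1
  if (nr < 1 || nc < 1) return(NULL)
  no <- dim(c1)[3]
  out <- matrix(0, nr * nc, ps * ps * no)
  k <- 1L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      out[k, ] <- as.vector(c1[i:(i + ps - 1), j:(j + ps - 1), ])
      k <- k + 1L
    }
  }
  out
}

#' Extract C2 shape features for a stimulus set
#'
#' Runs the S1 -> C1 -> S2 -> C2 hierarchy (see [shapefeat_config()]).
#' Templates are C1 patches sampled (seeded) from the stimulus set itself;
#' each C2 unit is the best radial-basis match of its template anywhere in
#' the image, so the representation is tolerant to position and scale.
#'
#' @param stimset a `StimulusSet`.
#' @param config a [shapefeat_config()].
#' @param seed integer seed for template sampling.
#' @return a `FeatureMatrix`: numeric matrix objects x templates, with the
#'   configuration in attribute `"config"`.
#' @export
extract_c2_features <- function(stimset, config = shapefeat_config(),
                                seed = 1L) {
  stopifnot(inherits(stimset, "StimulusSet"),
            inherits(config, "shapefeat_config"))
  thetas <- (seq_len(config$n_orientations) - 1) * pi / config$n_orientations
  gabors <- list()
  for (s in config$scales) {
    for (th in thetas) gabors[[length(gabors) + 1L]] <- .gabor(s, th)
  }
  c1 <- lapply(stimset$images, .c1_maps, cfg = config, gabors = gabors)
  for (b in seq_along(config$bands)) {
    if (dim(c1[[1]][[b]])[1] < config$patch_size ||
        dim(c1[[1]][[b]])[2] < config$patch_size) {
      stop("template patch larger than C1 map; reduce patch_size or c1_pool",
           call. = FALSE)
    }
  }
  n_img <- length(c1)
  # seeded template sampling from the set's own C1 maps
  templates <- with_seed(seed, {
    lapply(seq_len(config$n_templates), function(t) {
      im <- sample(n_img, 1)
      b <- sample(length(config$bands), 1)
      m <- c1[[im]][[b]]
      ps <- config$patch_size
      i <- sample(dim(m)[1] - ps + 1, 1)
      j <- sample(dim(m)[2] - ps + 1, 1)
      as.vector(m[i:(i + ps - 1), j:(j + ps - 1), ])
    })
  })
  Tm <- do.call(rbind, templates)               # templates x dim
  t_sq <- rowSums(Tm^2)
  fm <- matrix(0, n_img, config$n_templates)
  for (im in seq_len(n_img)) {
    best <- rep(-Inf, config$n_templates)
    for (b in seq_along(config$bands)) {
      P <- .c1_patches(c1[[im]][[b]], config$patch_size)
      if (is.null(P)) next
      d2 <- outer(rowSums(P^2), t_sq, "+") - 2 * P %*% t(Tm)
      best <- pmax(best, apply(d2, 2, min))
    }
    fm[im, ] <- exp(-pmax(best, 0) / (2 * config$sigma^2))
  }
  rownames(fm) <- stimset$objects$object_id
  attr(fm, "config") <- config
  class(fm) <- c("FeatureMatrix", class(fm))
  fm
}

# k-means++ seeding
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample(n, 1)
  d2 <- colSums((t(X) - X[centers[1], ])^2)
  for (i in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    if (all(d2 == 0)) probs <- rep(1 / n, n)
    centers[i + 1] <- sample(n, 1, prob = probs)
    d2 <- pmin(d2, colSums((t(X) - X[centers[i + 1], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Build shape-based categories by k-means on C2 features
#'
#' Euclidean k-means (k-means++ initialization, seeded) on the rows of the
#' feature matrix; categories are labelled `#1..#k`.
#'
#' @param fm a `FeatureMatrix` (objects x features).
#' @param k number of categories (default 15).
#' @param seed integer seed.
#' @return a `CategoryScheme` of kind `shape_based`, with the cluster
#'   assignment vector in attribute `"assignment"`.
#' @export
build_shape_categories <- function(fm, k = 15L, seed = 1L) {
  stopifnot(is.matrix(fm))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(fm)) stop("k exceeds the number of objects", call. = FALSE)
  X <- unclass(fm)
  attr(X, "config") <- NULL
  with_seed(seed, {
    cl <- if (k == nrow(X)) {
      seq_len(nrow(X))
    } else {
      init <- .kmeanspp_init(X, k)
      stats::kmeans(X, centers = init, iter.max = 100)$cluster
    }
    cats <- split(rownames(fm), cl)
    names(cats) <- paste0("#", names(cats))
    sc <- category_scheme("shape_based", cats)
    attr(sc, "assignment") <- cl
    sc
  })
}
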