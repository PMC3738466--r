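#' Tuning configuration for a simulated population
#'
#' Each simulated neuron's mean firing rate for an object is
#' `baseline + weights %*% z(properties) + semantic_gain[label]`, clipped at
#' zero, where the property channels are the four global image properties
#' (z-scored across the object set, undefined values at 0) plus one indicator
#' channel per shape family. Trial-to-trial variability is Poisson.
#'
#' @param n_neurons number of neurons (default 94).
#' @param channels character vector of property channels.
#' @param weights optional `n_neurons x length(channels)` matrix of rate
#'   weights in spikes/s per z-unit; if `NULL`, drawn i.i.d. normal with SD
#'   `weight_sd` under `seed`.
#' @param weight_sd SD of random weights (spikes/s).
#' @param semantic_gain named numeric vector of additive rate terms
#'   (spikes/s) per semantic label; unnamed labels get 0.
#' @param baseline baseline rate in spikes/s.
#' @param seed seed for random weight generation.
#' @return a `TuningConfig`.
#' @export
tuning_config <- function(n_neurons = 94L,
                          channels = c("area", "luminance", "contrast",
                                       "aspect_ratio"),
                          weights = NULL, weight_sd = 5,
                          semantic_gain = numeric(0),
                          baseline = 10, seed = 1L) {
  stopifnot(n_neurons >= 1, baseline >= 0)
  if (is.null(weights)) {
    weights <- with_seed(seed, matrix(stats::rnorm(n_neurons * length(channels),
                                                   sd = weight_sd),
                                      n_neurons, length(channels)))
  }
  stopifnot(nrow(weights) == n_neurons, ncol(weights) == length(channels))
  colnames(weights) <- channels
  structure(list(n_neurons = as.integer(n_neurons), channels = channels,
                 weights = weights, semantic_gain = semantic_gain,
                 baseline = baseline),
            class = "TuningConfig")
}

# z-scored property/indicator design matrix (objects x channels)
.design_matrix <- function(stimset, channels, props = NULL) {
  if (is.null(props)) props <- property_table(stimset)
  fams <- unique(stimset$objects$shape_family)
  cols <- lapply(channels, function(ch) {
    if (ch %in% names(props)) {
      v <- props[[ch]]
    } else if (startsWith(ch, "family_")) {
      v <- as.numeric(stimset$objects$shape_family == sub("family_", "", ch))
    } else if (ch %in% fams) {
      v <- as.numeric(stimset$objects$shape_family == ch)
    } else {
      stop("unknown tuning channel: ", ch, call. = FALSE)
    }
    v[is.na(v)] <- 0
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- channels
  mat
}

#' Simulate a spiking population probed with a stimulus set
#'
#' Draws Poisson spike counts in a 100-ms response window (100-200 ms after
#' stimulus onset by convention) around each neuron's mean rate for each
#' object, plus background counts in an equal-duration pre-stimulus window at
#' the baseline rate (one background trial per stimulus presentation).
#'
#' @param stimset a `StimulusSet`.
#' @param tuning a [tuning_config()].
#' @param n_rep repetitions per object (default 7, the median repetition
#'   count the analysis assumes; 5-30 is the realistic range).
#' @param seed integer seed; the same seed gives an identical dataset.
#' @param props optional precomputed [property_table()].
#' @return a `ResponseDataset`: list with `counts` (array neurons x objects
#'   x trials), `background` (matrix neurons x background trials), `window`
#'   (ms), `neuron_ids`, `object_ids`, and `rates` (the underlying mean
#'   rates, spikes/s).
#' @export
simulate_population <- function(stimset, tuning = tuning_config(),
                                n_rep = 7L, seed = 1L, props = NULL) {
  stopifnot(inherits(stimset, "StimulusSet"), inherits(tuning, "TuningConfig"))
  n_obj <- length(stimset$images)
  if (n_obj == 0) stop("empty stimulus set", call. = FALSE)
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  X <- .design_matrix(stimset, tuning$channels, props)
  rates <- tuning$baseline + tuning$weights %*% t(X)   # neurons x objects
  if (length(tuning$semantic_gain) > 0) {
    g <- tuning$semantic_gain[stimset$objects$semantic_label]
    g[is.na(g)] <- 0
    rates <- sweep(rates, 2, g, "+")
  }
  rates <- pmax(rates, 0)
  n_neu <- tuning$n_neurons
  dur <- 0.1  # 100-ms window, so rate = count / 0.1 s
  with_seed(seed, {
    counts <- array(stats::rpois(n_neu * n_obj * n_rep,
                                 lambda = rep(rates * dur, times = n_rep)),
                    dim = c(n_neu, n_obj, n_rep))
    background <- matrix(stats::rpois(n_neu * n_obj * n_rep,
                                      lambda = tuning$baseline * dur),
                         n_neu, n_obj * n_rep)
    structure(list(counts = counts, background = background,
                   window = c(start_ms = 100, end_ms = 200),
                   neuron_ids = sprintf("n%03d", seq_len(n_neu)),
                   object_ids = stimset$objects$object_id,
                   rates = rates),
              class = "ResponseDataset")
  })
}

#' @export
print.ResponseDataset <- function(x, ...) {
  cat(sprintf("ResponseDataset: %d neurons x %d objects x %d trials (window %g-%g ms)\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              x$window[1], x$window[2]))
  invisible(x)
}

#' Mean firing rates of a dataset
#'
#' @param ds a `ResponseDataset`.
#' @return matrix neurons x objects of mean rates in spikes/s (count / 0.1 s
#'   averaged over trials).
#' @export
mean_rates <- function(ds) {
  stopifnot(inherits(ds, "ResponseDataset"))
  m <- apply(ds$counts, c(1, 2), mean, na.rm = TRUE) / 0.1
  dimnames(m) <- list(ds$neuron_ids, ds$object_ids)
  m
}

# vectorised one-sided Welch t-test of each object's counts vs background
.welch_p_greater <- function(x_mat, bg) {
  # x_mat: objects x trials; bg: background counts vector
  n1 <- rowSums(!is.na(x_mat))
  m1 <- rowMeans(x_mat, na.rm = TRUE)
  v1 <- apply(x_mat, 1, stats::var, na.rm = TRUE)
  n2 <- length(bg)
  m2 <- mean(bg)
  v2 <- stats::var(bg)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, nrow(x_mat))
  ok <- se2 > 0 & n1 >= 2
  tt <- (m1[ok] - m2) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1[ok])^2 / (n1[ok] - 1) + (v2 / n2)^2 / (n2 - 1))
  p[ok] <- stats::pt(tt, df, lower.tail = FALSE)
  p
}

#' Screen neurons for responsiveness
#'
#' A neuron is retained if its mean response is significantly higher than
#' its background rate for at least one object (one-sided Welch two-sample
#' t-test, `p < alpha`; default `alpha = 0.005`). Object tests in which both
#' samples have zero variance are undefined and skipped (reported via
#' `message`).
#'
#' @param ds a `ResponseDataset`.
#' @param alpha per-test significance level.
#' @return the subset `ResponseDataset` of responsive neurons, with the
#'   per-neuron minimum p-values in attribute `"min_p"`.
#' @export
screen_responsive <- function(ds, alpha = 0.005) {
  stopifnot(inherits(ds, "ResponseDataset"), alpha > 0, alpha <= 1)
  n_neu <- dim(ds$counts)[1]
  minp <- rep(NA_real_, n_neu)
  n_skipped <- 0L
  for (i in seq_len(n_neu)) {
    x_mat <- matrix(ds$counts[i, , ], dim(ds$counts)[2], dim(ds$counts)[3])
    p <- .welch_p_greater(x_mat, ds$background[i, ])
    n_skipped <- n_skipped + sum(is.na(p))
    minp[i] <- if (all(is.na(p))) Inf else min(p, na.rm = TRUE)
  }
  if (n_skipped > 0) {
    message(sprintf("%d zero-variance (neuron, object) tests skipped",
                    n_skipped))
  }
  keep <- which(minp < alpha)
  out <- ds
  out$counts <- ds$counts[keep, , , drop = FALSE]
  out$background <- ds$background[keep, , drop = FALSE]
  out$neuron_ids <- ds$neuron_ids[keep]
  if (!is.null(ds$rates)) out$rates <- ds$rates[keep, , drop = FALSE]
  attr(out, "min_p") <- minp
  out
}

#' Write/read a trial-level response table
#'
#' Delimited text with columns `neuron_id`, `object_id`, `trial`, `count`,
#' `is_background` (background rows have `object_id = NA`).
#'
#' @param ds a `ResponseDataset`.
#' @param path file path.
#' @return `write_response_table` the path; `read_response_table` a
#'   `ResponseDataset`.
#' @export
write_response_table <- function(ds, path) {
  stopifnot(inherits(ds, "ResponseDataset"))
  dm <- dim(ds$counts)
  resp <- data.frame(
    neuron_id = rep(ds$neuron_ids, times = dm[2] * dm[3]),
    object_id = rep(rep(ds$object_ids, each = dm[1]), times = dm[3]),
    trial = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
    count = as.vector(ds$counts),
    is_background = FALSE)
  resp <- resp[!is.na(resp$count), ]
  bgd <- data.frame(
    neuron_id = rep(ds$neuron_ids, times = ncol(ds$background)),
    object_id = NA_character_,
    trial = rep(seq_len(ncol(ds$background)), each = dm[1]),
    count = as.vector(ds$background),
    is_background = TRUE)
  utils::write.table(rbind(resp, bgd), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  resp <- tab[!tab$is_background, ]
  bgd <- tab[tab$is_background, ]
  neurons <- sort(unique(tab$neuron_id))
  objects <- unique(resp$object_id)
  n_trial <- max(resp$trial)
  counts <- array(NA_real_, c(length(neurons), length(objects), n_trial))
  counts[cbind(match(resp$neuron_id, neurons),
               match(resp$object_id, objects), resp$trial)] <- resp$count
  background <- matrix(NA_real_, length(neurons), max(bgd$trial))
  background[cbind(match(bgd$neuron_id, neurons), bgd$trial)] <- bgd$count
  structure(list(counts = counts, background = background,
                 window = c(start_ms = 100, end_ms = 200),
                 neuron_ids = neurons, object_ids = objects),
            class = "ResponseDataset")
}
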