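# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' Stage toggling must not shift downstream randomness, so each stochastic
#' stage draws its own seed from the master seed and its own name rather than
#' from the global RNG stream.
#'
#' @param seed integer master seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # simple polynomial rolling hash over the stage name, folded with the seed
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# run code under a local RNG state, restoring the caller's stream;
# the seed is forced first so that a stochastic seed expression (e.g. one
# drawn from the caller's stream) is not rolled back by the restore
with_seed <- function(seed, code) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Pearson correlation without the error branches of stats::cor for the
# degenerate zero-variance case: returns NA silently.
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}
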