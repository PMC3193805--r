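`%||%` <- function(x, y) if (is.null(x)) y else x

#' Standard error of the mean
#' @param x numeric vector; NAs dropped.
#' @return SEM, or 0 for a single value.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(0)
  stats::sd(x) / sqrt(length(x))
}

#' Derive a child seed from a master seed and a tag
#'
#' Deterministically folds a master seed with any number of integer or
#' character tags into a new 32-bit seed, so that each simulated tumor,
#' session and pipeline stage gets an independent, reproducible stream.
#'
#' @param seed master integer seed.
#' @param ... integer or character tags (e.g. group index, tumor index,
#'   stage name).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.double(abs(as.integer(seed))) %% 2147483647
  for (p in list(...)) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators never perturb the global stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# 1-D Gaussian smoothing with replicate padding; returns a vector of the
# same length.
smooth1d <- function(x, kernel, r) {
  n <- length(x)
  xp <- x[pmin(pmax(seq.int(1L - r, n + r), 1L), n)]
  as.numeric(stats::convolve(xp, rev(kernel), type = "filter"))
}

# Separable Gaussian smoothing of a matrix (fixed-width kernel, replicate
# padding at the edges).
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  m <- apply(m, 2L, smooth1d, kernel = k, r = r)
  t(apply(m, 1L, smooth1d, kernel = k, r = r))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
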