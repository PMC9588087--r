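#' Run code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded operations do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Truncated normal draws by inverse-CDF
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n` inside `[lower, upper]`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  stopifnot(upper > lower, all(sd > 0))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (any(phi - plo <= 0)) stop("empty truncation window")
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

#' Standardize a numeric vector
#'
#' z-scores with the n-1 denominator; errors on zero variance.
#' @param x Numeric vector.
#' @return z-scored vector.
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

#' Gaussian smoothing matrix for evenly spaced bins
#'
#' Builds a column-stochastic smoothing operator: column j holds the kernel
#' centred on bin j, truncated to `window_s` total width and renormalized at
#' the edges so smoothing preserves a constant signal.
#'
#' @param n_bins Number of time bins.
#' @param bin_s Bin width in seconds.
#' @param sigma_s Gaussian sigma in seconds.
#' @param window_s Total kernel window (truncation) in seconds.
#' @return `n_bins x n_bins` matrix `W`; smoothed rows are `X %*% W`.
#' @keywords internal
gaussian_smoother <- function(n_bins, bin_s, sigma_s = 0.05, window_s = 0.1) {
  stopifnot(n_bins >= 1, bin_s > 0, sigma_s > 0, window_s > 0)
  r <- floor((window_s / 2) / bin_s + 1e-9)
  offs <- (-r):r
  k <- stats::dnorm(offs * bin_s, sd = sigma_s)
  W <- matrix(0, n_bins, n_bins)
  for (j in seq_len(n_bins)) {
    i <- j + offs
    ok <- i >= 1 & i <= n_bins
    W[i[ok], j] <- k[ok] / sum(k[ok])
  }
  W
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(p, what = "probability") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s outside [0, 1]", what))
  }
  invisible(p)
}
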