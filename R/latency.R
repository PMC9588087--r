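#' Sample luminance-change latencies
#'
#' Latencies follow `offset + X` where `X ~ Exponential(tau)` truncated to
#' `[0, cutoff]`, drawn by inverse-CDF so the support is exactly
#' `[offset, offset + cutoff]`. This flattens the subject's temporal
#' expectation of the change while bounding trial duration.
#'
#' @param n Number of draws.
#' @param tau_s Exponential time constant (s), > 0.
#' @param cutoff_s Truncation point (s), > 0.
#' @param offset_s Fixed offset added to every draw (s).
#' @return Numeric vector of latencies (s).
#' @export
#' @examples
#' set.seed(1)
#' range(sample_change_latency(1e4, 2.5, 1.4, 0.4)) # within [0.4, 1.8]
sample_change_latency <- function(n, tau_s, cutoff_s, offset_s = 0.4) {
  if (tau_s <= 0 || cutoff_s <= 0) stop("tau_s and cutoff_s must be positive")
  u <- stats::runif(n)
  x <- -tau_s * log(1 - u * (1 - exp(-cutoff_s / tau_s)))
  offset_s + pmin(x, cutoff_s)
}

#' Mean of the truncated-exponential latency law
#'
#' Closed form `offset + tau - cutoff * exp(-cutoff/tau) / (1 - exp(-cutoff/tau))`,
#' used as the analytic oracle for the sampler.
#'
#' @inheritParams sample_change_latency
#' @return Scalar mean latency (s).
#' @export
truncexp_latency_mean <- function(tau_s, cutoff_s, offset_s = 0.4) {
  if (tau_s <= 0 || cutoff_s <= 0) stop("tau_s and cutoff_s must be positive")
  offset_s + tau_s - cutoff_s * exp(-cutoff_s / tau_s) / (1 - exp(-cutoff_s / tau_s))
}

#' CDF of the truncated-exponential latency law
#'
#' @param q Quantiles (s).
#' @inheritParams sample_change_latency
#' @return `P(latency <= q)`.
#' @export
ptruncexp_latency <- function(q, tau_s, cutoff_s, offset_s = 0.4) {
  x <- pmin(pmax(q - offset_s, 0), cutoff_s)
  (1 - exp(-x / tau_s)) / (1 - exp(-cutoff_s / tau_s))
}
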