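#' Bin spike trains into an event-aligned rate tensor
#'
#' Counts spikes in half-open bins `[edge, edge + bin)` relative to an
#' alignment event and divides by the bin width. Trials lacking the
#' alignment event (e.g. no luminance change) are excluded.
#'
#' @param spikes `data.frame(neuron_id, trial_id, spike_time_s)`.
#' @param events Event table from [trial_events()].
#' @param trial_ids Trials to include (in this order).
#' @param neuron_ids Neurons to include (in this order); silent neurons get
#'   all-zero rows.
#' @param align_event Column of `events` to align to (e.g. `"stim_on"`,
#'   `"change_on"`).
#' @param window `c(start, end)` of the aligned window (s).
#' @param bin_s Bin width (s), > 0.
#' @return An `aligned_tensor`: list with `values` (trials x bins x neurons
#'   array, Hz), `centers`, `edges`, `alignment`, `bin_s`, `trial_ids`,
#'   `neuron_ids`.
#' @export
bin_rates <- function(spikes, events, trial_ids, neuron_ids, align_event,
                      window, bin_s = 0.005) {
  if (bin_s <= 0) stop("bin width must be positive")
  if (!align_event %in% names(events)) stop("unknown alignment event")
  at <- events[[align_event]][match(trial_ids, events$trial_id)]
  if (anyNA(at)) {
    keep <- !is.na(at)
    trial_ids <- trial_ids[keep]
    at <- at[keep]
  }
  n_bins <- floor((window[2] - window[1]) / bin_s + 1e-9)
  if (n_bins < 1) stop("window shorter than one bin")
  edges <- window[1] + bin_s * (0:n_bins)
  n_tr <- length(trial_ids)
  n_nu <- length(neuron_ids)

  sp <- spikes[spikes$trial_id %in% trial_ids & spikes$neuron_id %in% neuron_ids, ]
  tr_row <- match(sp$trial_id, trial_ids)
  rel <- sp$spike_time_s - at[tr_row]
  keep <- rel >= window[1] & rel < window[1] + n_bins * bin_s
  b <- floor((rel[keep] - window[1]) / bin_s) + 1L
  nu <- match(sp$neuron_id[keep], neuron_ids)
  lin <- tr_row[keep] + (b - 1L) * n_tr + (nu - 1L) * n_tr * n_bins
  counts <- tabulate(lin, nbins = n_tr * n_bins * n_nu)
  values <- array(counts / bin_s, dim = c(n_tr, n_bins, n_nu))
  structure(list(values = values,
                 centers = edges[-length(edges)] + bin_s / 2,
                 edges = edges, alignment = align_event, bin_s = bin_s,
                 trial_ids = trial_ids, neuron_ids = neuron_ids),
            class = "aligned_tensor")
}

#' z-score and Gaussian-smooth a pair of aligned tensors
#'
#' Each neuron is z-scored jointly across all trials and all time points of
#' both alignment windows, then smoothed along time with a Gaussian kernel
#' (sigma `sigma_s`) truncated to a `window_s`-wide support and renormalized
#' at the edges. Zero-variance neurons are excluded with a warning.
#'
#' @param stim,change `aligned_tensor`s sharing the neuron roster (stimulus-
#'   and change-aligned windows).
#' @param sigma_s Kernel sigma (s).
#' @param window_s Total kernel window (s).
#' @return List `stim`, `change` (normalized tensors), `z_params`
#'   (per-neuron mean/sd), `dropped` (zero-variance neuron ids).
#' @export
zscore_and_smooth <- function(stim, change, sigma_s = 0.05, window_s = 0.1) {
  stopifnot(identical(stim$neuron_ids, change$neuron_ids))
  n_nu <- length(stim$neuron_ids)
  mu <- sd_ <- numeric(n_nu)
  for (n in seq_len(n_nu)) {
    v <- c(stim$values[, , n], change$values[, , n])
    mu[n] <- mean(v)
    sd_[n] <- stats::sd(v)
  }
  keep <- sd_ > 0
  if (any(!keep)) {
    warning(sprintf("excluding %d zero-variance neuron(s): %s", sum(!keep),
                    paste(stim$neuron_ids[!keep], collapse = ", ")))
  }
  Ws <- gaussian_smoother(dim(stim$values)[2], stim$bin_s, sigma_s, window_s)
  Wc <- gaussian_smoother(dim(change$values)[2], change$bin_s, sigma_s, window_s)
  norm_one <- function(tensor, W) {
    ids <- tensor$neuron_ids[keep]
    out <- array(NA_real_, c(dim(tensor$values)[1:2], sum(keep)))
    j <- 0
    for (n in which(keep)) {
      j <- j + 1
      out[, , j] <- ((tensor$values[, , n] - mu[n]) / sd_[n]) %*% W
    }
    tensor$values <- out
    tensor$neuron_ids <- ids
    tensor
  }
  list(stim = norm_one(stim, Ws), change = norm_one(change, Wc),
       z_params = data.frame(neuron_id = stim$neuron_ids, mean = mu, sd = sd_,
                             kept = keep),
       dropped = stim$neuron_ids[!keep])
}

#' Average an aligned tensor into sliding windows
#'
#' Windows of `width_s` stepped by `step_s`, fully inside the tensor's
#' range (partial windows are dropped). Width and step must be integer
#' multiples of the raw bin.
#'
#' @param tensor An `aligned_tensor`.
#' @param width_s Window width (s).
#' @param step_s Step between window starts (s).
#' @return An `aligned_tensor` of window-averaged rates with window-center
#'   `centers`.
#' @export
window_average <- function(tensor, width_s = 0.025, step_s = 0.010) {
  k <- width_s / tensor$bin_s
  s <- step_s / tensor$bin_s
  if (abs(k - round(k)) > 1e-6 || abs(s - round(s)) > 1e-6) {
    stop("window width and step must be multiples of the raw bin")
  }
  k <- round(k); s <- round(s)
  n_bins <- dim(tensor$values)[2]
  starts <- seq(1L, n_bins - k + 1L, by = s)
  d <- dim(tensor$values)
  out <- array(NA_real_, c(d[1], length(starts), d[3]))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + k - 1L)
    acc <- tensor$values[, idx[1], ]
    for (j in idx[-1]) acc <- acc + tensor$values[, j, ]
    out[, w, ] <- acc / k
  }
  tensor$values <- out
  tensor$centers <- tensor$edges[starts] + width_s / 2
  tensor$edges <- NULL
  tensor$window_s <- width_s
  tensor$step_s <- step_s
  tensor
}
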