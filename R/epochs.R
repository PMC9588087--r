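#' Default analysis epochs
#'
#' Epochs are defined relative to trial events (half-open windows):
#' cue-stimulus (0-0.2 s after stimulus onset), early stimulus (0.2-0.6 s),
#' late stimulus (0.4-0 s before the luminance change; only trials whose
#' change latency is at least 0.4 s contribute), the variable-length
#' stimulus period (stimulus onset to luminance change), the post-cue
#' period (frame cue offset to luminance change), and a 200-ms pre-cue
#' baseline.
#'
#' @return Named list of epoch definitions
#'   `list(start_event, start_offset, end_event, end_offset)`.
#' @export
default_epochs <- function() {
  list(
    cue_stimulus = list("stim_on", 0, "stim_on", 0.2),
    early_stimulus = list("stim_on", 0.2, "stim_on", 0.6),
    late_stimulus = list("change_on", -0.4, "change_on", 0),
    stimulus_period = list("stim_on", 0, "change_on", 0),
    postcue_period = list("cue_off", 0, "change_on", 0),
    baseline_precue = list("cue_on", -0.2, "cue_on", 0))
}

#' Mean firing rates in named epochs
#'
#' Spike count in the half-open per-trial window divided by the window
#' length. Windows that are empty, undefined (missing event) or that start
#' before stimulus onset for change-anchored epochs yield `NA`.
#'
#' @param spikes Spike table (`neuron_id`, `trial_id`, `spike_time_s`).
#' @param events Event table from [trial_events()].
#' @param trial_ids,neuron_ids Rosters (and ordering) to use.
#' @param epochs Epoch definitions, see [default_epochs()].
#' @return Named list of trials x neurons rate matrices (Hz).
#' @export
epoch_rates <- function(spikes, events, trial_ids, neuron_ids,
                        epochs = default_epochs()) {
  ev <- events[match(trial_ids, events$trial_id), ]
  n_tr <- length(trial_ids)
  n_nu <- length(neuron_ids)
  sp <- spikes[spikes$trial_id %in% trial_ids &
                 spikes$neuron_id %in% neuron_ids, ]
  tr_row <- match(sp$trial_id, trial_ids)
  nu_col <- match(sp$neuron_id, neuron_ids)
  out <- list()
  for (nm in names(epochs)) {
    ep <- epochs[[nm]]
    t0 <- ev[[ep[[1]]]] + ep[[2]]
    t1 <- ev[[ep[[3]]]] + ep[[4]]
    dur <- t1 - t0
    valid <- !is.na(dur) & dur > 1e-12
    # change-anchored windows must not reach before stimulus onset
    if (ep[[1]] == "change_on" && ep[[2]] < 0) {
      valid <- valid & !is.na(t0) & t0 >= ev$stim_on - 1e-9
    }
    keep <- !is.na(tr_row) & valid[tr_row] &
      sp$spike_time_s >= t0[tr_row] & sp$spike_time_s < t1[tr_row]
    lin <- tr_row[keep] + (nu_col[keep] - 1L) * n_tr
    counts <- tabulate(lin, nbins = n_tr * n_nu)
    R <- matrix(counts, n_tr, n_nu) / dur
    R[!valid, ] <- NA_real_
    dimnames(R) <- list(NULL, neuron_ids)
    out[[nm]] <- R
  }
  out
}
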