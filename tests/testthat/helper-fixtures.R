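# Shared small fixtures, built once per test run.

fixture_env <- new.env()

with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

small_session <- function(profile = "dlpfc_like", n_neurons = 12,
                          n_trials = 250, paradigm = "D", seed = 101) {
  key <- paste(profile, n_neurons, n_trials, paradigm, seed, sep = "_")
  if (is.null(fixture_env[[key]])) {
    cfg <- task_config(paradigm)
    tr <- generate_trial_schedule(cfg, n_trials, seed = seed)
    tr <- simulate_behavior(tr, cfg, seed = seed + 1)
    fixture_env[[key]] <- generate_population(profile, n_neurons, tr, cfg,
                                              seed = seed + 2)
  }
  fixture_env[[key]]
}

# deterministic spike table: `counts[trial, neuron]` spikes placed evenly
# inside [t0, t1] of each trial
deterministic_spikes <- function(counts, t0, t1, neuron_ids = NULL) {
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(ncol(counts)))
  rows <- list()
  for (n in seq_len(ncol(counts))) {
    for (tr in seq_len(nrow(counts))) {
      k <- counts[tr, n]
      if (k > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          neuron_id = neuron_ids[n], area = "OFC", trial_id = tr,
          spike_time_s = t0 + (seq_len(k) - 0.5) * (t1 - t0) / k)
      }
    }
  }
  do.call(rbind, rows)
}
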