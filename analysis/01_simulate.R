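#!/usr/bin/env Rscript
# Stage 1: simulate the study's raw material.
#
# Builds three synthetic sessions and writes them as plain-text bundles under
# results/sessions/: a valid/invalid-cueing (paradigm D) session recorded with
# a DLPFC-like population (strong cue-side coding that flips sign after
# stimulus onset), the same paradigm with an OFC-like population (salient-
# value-dominated coding), and a target/distractor (paradigm G) session used
# for behavioural scoring.

library(attnvalue)

seed <- 20260928L
out_root <- file.path("results", "sessions")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

specs <- list(
  list(name = "D_dlpfc", paradigm = "D", profile = "dlpfc_like",
       n_trials = 500, n_neurons = 40),
  list(name = "D_ofc", paradigm = "D", profile = "ofc_like",
       n_trials = 500, n_neurons = 40),
  list(name = "G_dlpfc", paradigm = "G", profile = "dlpfc_like",
       n_trials = 500, n_neurons = 20))

for (i in seq_along(specs)) {
  sp <- specs[[i]]
  cfg <- task_config(sp$paradigm)
  tr <- generate_trial_schedule(cfg, sp$n_trials, seed = seed + 10 * i)
  tr <- simulate_behavior(tr, cfg, seed = seed + 10 * i + 1)
  sess <- generate_population(sp$profile, sp$n_neurons, tr, cfg,
                              seed = seed + 10 * i + 2)
  dir <- file.path(out_root, sp$name)
  write_session_bundle(sess, dir)
  write_manifest(file.path(dir, "manifest.json"), seed = seed + 10 * i,
                 params = sp[-1],
                 files = file.path(dir, c("trials.csv", "events.csv",
                                          "spikes.csv")))
  cat(sprintf("%s: %d trials (%.1f%% hits), %d neurons, %d spikes\n",
              sp$name, nrow(tr), 100 * mean(tr$outcome == "hit"),
              sp$n_neurons, nrow(sess$spikes)))
}
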