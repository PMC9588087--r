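#!/usr/bin/env Rscript
# Stage 4: single-neuron value and attention coding.
#
# Reads the OFC-like and DLPFC-like session bundles from stage 1 and runs the
# encoding analyses: the per-variable selectivity screen and tuning
# classification, CPD time courses for both regression models (cue + SV + NSV
# and cue + CV + UCV), epoch-level CPDs with the salient-vs-non-salient and
# cued-vs-un-cued paired tests, the dCPD = CPD(cue) - CPD(SV) area contrast,
# grouped population responses, and the additive two-way ANOVA comparing
# same-reward-pair trials with SV-grouped trials.
# Writes results/selectivity.csv, results/cpd_timecourse.csv,
# results/cpd_epoch.csv, results/grouped_response.csv, results/anova.csv.

library(attnvalue)

for (b in c("D_ofc", "D_dlpfc")) {
  if (!dir.exists(file.path("results", "sessions", b))) {
    stop("run analysis/01_simulate.R first")
  }
}
ofc <- read_session_bundle(file.path("results", "sessions", "D_ofc"),
                           min_trials = 50)
dlpfc <- read_session_bundle(file.path("results", "sessions", "D_dlpfc"),
                             min_trials = 50)

## selectivity screen (OFC-like population)
er <- epoch_rates(ofc$spikes, ofc$events, ofc$trials$trial_id,
                  ofc$neurons$neuron_id)
sel <- selectivity_screen(er, ofc$trials)
write.csv(sel$table, "results/selectivity.csv", row.names = FALSE)
cat(sprintf("Value-selective neurons: %d/%d (%d positive, %d negative, %d contradictory)\n",
            sum(sel$tuning$value_selective), nrow(sel$tuning),
            sum(sel$tuning$tuning_class == "positive"),
            sum(sel$tuning$tuning_class == "negative"),
            sum(sel$tuning$tuning_class == "contradictory")))

## CPD time courses, both model specifications
tc <- list()
for (spec in c("sv_nsv", "cv_ucv")) {
  cp <- cpd_timecourse(ofc, spec, min_trials = 50)
  pop <- cp$pop
  pop$spec <- spec
  tc[[spec]] <- pop
  post <- cp$bins$alignment == "stim_on" & cp$bins$center > 0
  cat(sprintf("[%s] post-stimulus mean CPD: %s\n", spec,
              paste(sprintf("%s %.4f", dimnames(cp$cpd)[[3]],
                            apply(cp$cpd[, post, ], 3, mean)),
                    collapse = ", ")))
}
write.csv(do.call(rbind, tc), "results/cpd_timecourse.csv", row.names = FALSE)

## epoch CPDs and the area contrast on the post-cue window
ep <- list()
for (area in c("ofc", "dlpfc")) {
  sess <- if (area == "ofc") ofc else dlpfc
  s <- epoch_cpd_summary(sess, "sv_nsv", "postcue_period", min_trials = 50)
  s$neurons$area <- toupper(area)
  ep[[area]] <- s$neurons
  cat(sprintf("%s: mean dCPD(cue - SV) = %+.4f (one-sample t p = %.2g); SV vs NSV paired p = %.2g\n",
              toupper(area), s$delta_t$mean, s$delta_t$p, s$paired_t$p))
}
write.csv(do.call(rbind, ep), "results/cpd_epoch.csv", row.names = FALSE)

## grouped population responses (positively tuned OFC-like neurons)
pos <- sel$tuning$neuron_id[sel$tuning$tuning_class == "positive"]
gr_same <- grouped_population_response(ofc, trial_grouping(ofc$trials, "same_pair"),
                                       neuron_ids = pos)
gr_sv <- grouped_population_response(ofc, trial_grouping(ofc$trials, "sv"),
                                     neuron_ids = pos)
traces <- rbind(cbind(grouping = "same_pair", gr_same$traces),
                cbind(grouping = "sv", gr_sv$traces))
write.csv(traces, "results/grouped_response.csv", row.names = FALSE)

## two-way ANOVA: same-reward pairs vs SV grouping
longify <- function(M, grouping) {
  data.frame(response = as.vector(M), grouping = grouping,
             value = rep(colnames(M), each = nrow(M)),
             neuron = rep(rownames(M), ncol(M)))
}
tab <- rbind(longify(gr_same$per_neuron_epoch, "same_pair"),
             longify(gr_sv$per_neuron_epoch, "sv"))
tab <- tab[is.finite(tab$response), ]
aov_out <- two_way_anova(tab, response = "response", factor_a = "grouping",
                         factor_b = "value")
write.csv(aov_out, "results/anova.csv", row.names = FALSE)
cat("Two-way ANOVA (grouping + value), positively tuned neurons:\n")
print(aov_out, digits = 4)

write_manifest("results/cpd_manifest.json", seed = NA,
               params = list(specs = c("sv_nsv", "cv_ucv"),
                             window = "postcue_period", min_trials = 50),
               files = c("results/selectivity.csv",
                         "results/cpd_timecourse.csv",
                         "results/cpd_epoch.csv", "results/anova.csv"))
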