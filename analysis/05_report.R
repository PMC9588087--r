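#!/usr/bin/env Rscript
# Stage 5: aggregate the stage outputs into one JSON summary.
# Exits non-zero if an upstream stage has not produced its files.

library(attnvalue)

need <- c(behavior = "results/behavior_summary.csv",
          comparisons = "results/comparisons.csv",
          decoding = "results/decoding_posterior.csv",
          crosstemporal = "results/decoding_crosstemporal.csv",
          cpd = "results/cpd_timecourse.csv",
          cpd_epoch = "results/cpd_epoch.csv",
          anova = "results/anova.csv")
missing <- need[!file.exists(need)]
if (length(missing)) {
  message("stage missing: ", paste(names(missing), collapse = ", "))
  quit(status = 1)
}

beh <- read.csv(need["behavior"])
dec <- read.csv(need["decoding"])
cpd <- read.csv(need["cpd"])
epo <- read.csv(need["cpd_epoch"])
late <- dec$alignment == "stim_on" & dec$center > 0.3
post <- cpd$alignment == "stim_on" & cpd$center > 0
sv_rows <- cpd$spec == "sv_nsv" & cpd$regressor == "SV" & post
nsv_rows <- cpd$spec == "sv_nsv" & cpd$regressor == "NSV" & post

summary <- list(
  behavior = list(
    valid_hit_rate = beh$rate_mean[beh$trial_type == "valid" &
                                     beh$change_at_salient][1],
    conditions = nrow(beh)),
  decoding = list(
    late_stimulus_posterior = mean(dec$mean_posterior[late]),
    shuffle_posterior = mean(dec$mean_shuffle),
    significant_bins = sum(dec$sig_above)),
  cpd = list(
    sv_mean = mean(cpd$mean[sv_rows]),
    nsv_mean = mean(cpd$mean[nsv_rows]),
    ofc_mean_dcpd = mean(epo$dcpd[epo$area == "OFC"]),
    dlpfc_mean_dcpd = mean(epo$dcpd[epo$area == "DLPFC"])))

jsonlite::write_json(summary, "results/report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/report.json\n")
str(summary)
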