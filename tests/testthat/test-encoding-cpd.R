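test_that("epoch rates use per-trial windows with eligibility rules", {
  ev <- data.frame(trial_id = 1:3,
                   fix_on = 0, sacc_target_on = 0.5, cue_on = 1.0,
                   stim_on = 1.2, cue_off = 1.4,
                   change_on = 1.2 + c(0.8, 0.3, 0.5),
                   distractor_change_on = NA_real_, response = NA_real_,
                   trial_end = 3)
  # 5 spikes in the 0.2-s cue-stimulus epoch of trial 1
  sp <- data.frame(neuron_id = "n1", trial_id = 1,
                   spike_time_s = seq(1.21, 1.39, length.out = 5))
  r <- epoch_rates(sp, ev, 1:3, "n1")
  expect_equal(unname(r$cue_stimulus[1, 1]), 25)
  # late-stimulus epoch requires latency >= 0.4 s
  expect_true(is.na(r$late_stimulus[2, 1]))
  expect_false(is.na(r$late_stimulus[1, 1]))
  # variable-length stimulus period: 5 spikes over 0.8 s
  expect_equal(unname(r$stimulus_period[1, 1]), 5 / 0.8)
  # constant-rate generator: epoch means agree across epochs
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 300, seed = 90), cfg,
                          seed = 91)
  evs <- trial_events(tr, cfg)
  spc <- simulate_neuron(neuron_tuning("c", "OFC", 12), tr, evs, cfg,
                         seed = 92)
  rc <- epoch_rates(spc, evs, tr$trial_id, "c")
  m <- sapply(rc[c("cue_stimulus", "early_stimulus", "stimulus_period")],
              function(M) mean(M, na.rm = TRUE))
  expect_lt(diff(range(m)), 1)
})

test_that("selectivity screen recovers tuning and the contradictory rule", {
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 400, seed = 95), cfg,
                          seed = 96)
  n_tr <- nrow(tr)
  # noiseless linear rates: beta1 exact, positive class
  rates_pos <- matrix(2 + 0.5 * ifelse(is.na(tr$SV), 0, tr$SV), n_tr, 1)
  # contradictory: positive SV slope, negative NSV slope
  rates_con <- matrix(2 + 2 * ifelse(is.na(tr$SV), 0, tr$SV) -
                        3 * ifelse(is.na(tr$NSV), 0, tr$NSV), n_tr, 1)
  set.seed(97)
  rates_null <- matrix(rnorm(n_tr, 10), n_tr, 1)
  R <- cbind(rates_pos, rates_con, rates_null)
  colnames(R) <- c("pos", "con", "null")
  rates <- list(cue_stimulus = R, early_stimulus = R, late_stimulus = R)
  sel <- selectivity_screen(rates, tr)
  sv_row <- sel$table[sel$table$neuron_id == "pos" &
                        sel$table$variable == "SV" &
                        sel$table$epoch == "cue_stimulus", ]
  expect_equal(sv_row$beta1, 0.5, tolerance = 1e-9)
  tun <- sel$tuning
  expect_equal(tun$tuning_class[tun$neuron_id == "pos"], "positive")
  expect_equal(tun$tuning_class[tun$neuron_id == "con"], "contradictory")
  expect_equal(tun$tuning_class[tun$neuron_id == "null"], "none")
})

test_that("CPD equals the squared partial correlation (oracle)", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    colnames(X) <- c("a", "b", "c")
    X <- apply(X, 2, function(v) (v - mean(v)) / sd(v))
    y <- rnorm(n) + X %*% runif(3, -1, 1)
    f <- fit_cpd(y, X)
    expect_true(all(f$cpd >= 0 & f$cpd < 1))
    for (i in 1:3) {
      others <- cbind(1, X[, -i])
      ry <- residuals(lm.fit(others, y))
      rx <- residuals(lm.fit(others, X[, i]))
      expect_equal(unname(f$cpd[i]), cor(ry, rx)^2, tolerance = 1e-10)
    }
  }
  # construction limits
  set.seed(15)
  x1 <- rnorm(100); x2 <- rnorm(100); x3 <- rnorm(100)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  f1 <- fit_cpd(x1, X)                     # response identically x1
  expect_gt(f1$cpd["x1"], 0.999)
  expect_lt(max(f1$cpd[c("x2", "x3")]), 0.05)
  # an irrelevant regressor leaves the SSE unchanged up to fit noise
  expect_lt(abs(f1$sse_reduced["x2"] - f1$sse_full), 1e-20)
  expect_error(fit_cpd(rnorm(5), matrix(rnorm(15), 5, 3)), "at least 10")
  expect_error(fit_cpd(rnorm(20), cbind(rep(1, 20), rnorm(20))), "constant")
})

test_that("CPD time course recovers salient-value dominance", {
  sess <- small_session("ofc_like", 30, 300, seed = 501)
  cp <- cpd_timecourse(sess, "sv_nsv", min_trials = 50)
  post <- cp$bins$alignment == "stim_on" & cp$bins$center > 0.1
  sv <- rowMeans(cp$cpd[, post, 2])
  nsv <- rowMeans(cp$cpd[, post, 3])
  expect_gt(mean(sv), mean(nsv))
  expect_lt(t.test(sv - nsv)$p.value, 1e-3)
  # NSV stays at baseline level
  expect_lt(mean(nsv) - mean(cp$baseline), 0.003)
  # cued/un-cued symmetry under salience-only coding
  cp2 <- cpd_timecourse(sess, "cv_ucv", min_trials = 50)
  cv <- mean(cp2$cpd[, post, 2]); ucv <- mean(cp2$cpd[, post, 3])
  expect_lt(abs(cv - ucv), 0.5 * mean(sv))
  # pure-noise population: nothing significant beyond the FDR level
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 250, seed = 511), cfg,
                          seed = 512)
  ev <- trial_events(tr, cfg)
  sp <- do.call(rbind, lapply(1:15, function(i) {
    simulate_neuron(neuron_tuning(paste0("z", i), "OFC", 10), tr, ev, cfg,
                    seed = 520 + i)
  }))
  sess0 <- list(config = cfg, trials = tr, events = ev, spikes = sp)
  cp0 <- cpd_timecourse(sess0, "sv_nsv", min_trials = 50)
  expect_lte(mean(cp0$pop$sig), 0.02)
})

test_that("epoch CPD summaries separate area-like coding profiles", {
  sess_ofc <- small_session("ofc_like", 25, 300, seed = 601)
  s_ofc <- epoch_cpd_summary(sess_ofc, "sv_nsv", "postcue_period",
                             min_trials = 50)
  expect_lt(s_ofc$delta_t$mean, 0)         # SV dominates over cue coding
  # matched cue and value coding: no systematic difference
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 300, seed = 611), cfg,
                          seed = 612)
  sess_bal <- generate_population("dlpfc_like", 25, tr, cfg, seed = 613,
                                  params = list(p_value_tuned = 1,
                                                value_coef_meanlog = log(3),
                                                cue_coef_meanlog = log(3),
                                                cue_coef_sdlog = 0.1,
                                                value_coef_sdlog = 0.1))
  s_bal <- epoch_cpd_summary(sess_bal, "sv_nsv", "postcue_period",
                             min_trials = 50)
  expect_lt(abs(s_bal$delta_t$mean), abs(s_ofc$delta_t$mean))
  # degenerate population: identical neurons flagged
  sp1 <- sess_ofc$spikes[sess_ofc$spikes$neuron_id ==
                           sess_ofc$neurons$neuron_id[1], ]
  sp2 <- sp1; sp2$neuron_id <- "copy"
  twin <- list(config = sess_ofc$config, trials = sess_ofc$trials,
               events = sess_ofc$events, spikes = rbind(sp1, sp2))
  s_twin <- epoch_cpd_summary(twin, "sv_nsv", "stimulus_period",
                              min_trials = 50)
  expect_true(s_twin$paired_t$degenerate)
})

test_that("grouped responses reconstruct value tuning by grouping", {
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 400, seed = 701), cfg,
                          seed = 702)
  g_same <- trial_grouping(tr, "same_pair")
  used <- !is.na(g_same)
  expect_true(all(tr$left_value[used] == tr$right_value[used]))
  expect_equal(nlevels(g_same), 5)
  # noiseless linear generator: SV-grouped equals same-pair at equal value
  ev <- trial_events(tr, cfg)
  counts <- matrix(0, nrow(tr), 1)
  sv_all <- ifelse(is.na(tr$SV), tr$V_sin, tr$SV)
  counts[, 1] <- (sv_all + 1) * 2
  sp <- deterministic_spikes(counts, t0 = 1.2, t1 = 1.6)
  sess <- list(config = cfg, trials = tr, events = ev, spikes = sp)
  gr_same <- grouped_population_response(sess, g_same, epoch = "cue_stimulus")
  gr_sv <- grouped_population_response(sess, trial_grouping(tr, "sv"),
                                       epoch = "cue_stimulus")
  # trials with SV = v (pairs or not) give the identical deterministic rate
  expect_equal(gr_same$epoch_means$mean, gr_sv$epoch_means$mean,
               tolerance = 1e-9)
  # SV-positive population: group means monotone in SV
  sess2 <- small_session("ofc_like", 20, 300, seed = 711)
  gt <- sess2$ground_truth
  pos <- gt$neuron_id[gt$sv > 0]
  gr <- grouped_population_response(sess2, trial_grouping(sess2$trials, "sv"),
                                    neuron_ids = pos)
  m <- gr$epoch_means$mean[order(as.numeric(as.character(gr$epoch_means$group)))]
  expect_true(all(diff(m) > 0))
  # grouping by CV vs UCV overlaps under salience-only coding
  gcv <- grouped_population_response(sess2, trial_grouping(sess2$trials, "cv"),
                                     neuron_ids = pos)
  gucv <- grouped_population_response(sess2, trial_grouping(sess2$trials, "ucv"),
                                      neuron_ids = pos)
  spread_sv <- diff(range(m))
  gap_cvucv <- max(abs(gcv$epoch_means$mean - gucv$epoch_means$mean))
  expect_lt(gap_cvucv, 0.35 * spread_sv)
})

test_that("additive two-way ANOVA matches hand-computed sums of squares", {
  set.seed(16)
  d <- expand.grid(group = c("same", "sv"), value = c(0, 1, 2, 4, 8),
                   rep = 1:12)
  d$response <- 5 + 0.6 * d$value + rnorm(nrow(d))
  out <- two_way_anova(d)
  # hand oracle on the balanced table
  y <- d$response
  ybar <- mean(y)
  gm <- tapply(y, d$group, mean); vm <- tapply(y, d$value, mean)
  n_g <- table(d$group); n_v <- table(d$value)
  ss_g <- sum(n_g * (gm - ybar)^2)
  ss_v <- sum(n_v * (vm - ybar)^2)
  fit <- lm(response ~ factor(group) + factor(value), d)
  ss_res <- sum(residuals(fit)^2)
  f_g <- (ss_g / 1) / (ss_res / fit$df.residual)
  f_v <- (ss_v / 4) / (ss_res / fit$df.residual)
  expect_equal(out$f[out$term == "group"], f_g, tolerance = 1e-10)
  expect_equal(out$f[out$term == "value"], f_v, tolerance = 1e-10)
  expect_lt(out$p[out$term == "value"], 1e-10)
  # duplicated factor: identical group means give F = 0
  d0 <- d; d0$response <- 5 + 0.6 * d0$value
  out0 <- suppressWarnings(two_way_anova(d0))  # exact fit warns in drop1
  expect_lt(out0$f[out0$term == "group"], 1e-20)
})
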