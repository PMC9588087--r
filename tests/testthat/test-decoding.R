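test_that("spike binning uses half-open bins and recovers rates", {
  ev <- data.frame(trial_id = 1:3, stim_on = c(1, 1, 1), trial_end = 3)
  sp <- data.frame(neuron_id = "n1", trial_id = c(1, 1, 2),
                   spike_time_s = c(1.0, 1.1, 0.95))
  tz <- bin_rates(sp, ev, 1:3, "n1", "stim_on", c(-0.1, 0.2), 0.1)
  # spike exactly at a left edge counts in that bin
  expect_equal(tz$values[1, , 1], c(0, 10, 10))
  expect_equal(tz$values[2, , 1], c(10, 0, 0))
  expect_equal(tz$values[3, , 1], c(0, 0, 0))   # empty train, all-zero row
  expect_error(bin_rates(sp, ev, 1:3, "n1", "stim_on", c(-0.1, 0.2), -1),
               "positive")
  # Poisson generator oracle: constant 20 hz
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 200, seed = 71), cfg,
                          seed = 72)
  evs <- trial_events(tr, cfg)
  sp2 <- simulate_neuron(neuron_tuning("c20", "OFC", 20), tr, evs, cfg,
                         seed = 73)
  tz2 <- bin_rates(sp2, evs, tr$trial_id, "c20", "stim_on", c(-0.4, 0.6), 0.01)
  expect_lt(abs(mean(tz2$values) - 20), 1.0)   # ~3 SE of the Poisson mean
})

test_that("z-scoring normalizes each neuron over both windows jointly", {
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 150, seed = 81), cfg,
                          seed = 82)
  ev <- trial_events(tr, cfg)
  sp <- rbind(simulate_neuron(neuron_tuning("a", "DLPFC", 15,
                                            coef = list(cue_pre = 3)),
                              tr, ev, cfg, seed = 83),
              simulate_neuron(neuron_tuning("b", "DLPFC", 5), tr, ev, cfg,
                              seed = 84))
  hits <- tr$trial_id[tr$outcome == "hit"]
  stim <- bin_rates(sp, ev, hits, c("a", "b"), "stim_on", c(-0.4, 0.6), 0.005)
  chg <- bin_rates(sp, ev, hits, c("a", "b"), "change_on", c(-0.4, 0.4), 0.005)
  # identity smoother isolates the z-scoring contract
  zs <- zscore_and_smooth(stim, chg, sigma_s = 0.05, window_s = 0.005)
  for (n in 1:2) {
    v <- c(zs$stim$values[, , n], zs$change$values[, , n])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  # constant-rate (zero-variance) neuron is excluded with a warning
  sp3 <- rbind(sp, data.frame(neuron_id = "flat", area = "DLPFC",
                              trial_id = hits, spike_time_s = 0.5))
  stim3 <- bin_rates(sp3, ev, hits, c("a", "b", "flat"), "stim_on",
                     c(0.49, 0.51), 0.01)
  chg3 <- stim3
  expect_warning(z3 <- zscore_and_smooth(stim3, chg3, window_s = 0.01),
                 "zero-variance")
  expect_identical(z3$dropped, "flat")

  # white noise: smoothing shrinks variance by the kernel sum-of-squares
  W <- attnvalue:::gaussian_smoother(200, 0.005, 0.05, 0.1)
  X <- matrix(rnorm(500 * 200), 500, 200)
  sm <- X %*% W
  mid <- 60:140
  shrink <- mean(apply(sm[, mid], 2, var))
  expect_equal(shrink, mean(colSums(W[, mid]^2)), tolerance = 0.05)
})

test_that("pseudo-population assembly balances classes and enforces inclusion", {
  sess <- small_session("dlpfc_like", 8, 250, seed = 201)
  inp <- prepare_decoding(sess)
  ens <- with_seed_test(1, build_pseudo_population(inp, n_per_class = 40))
  expect_equal(dim(ens$X)[1], 80)
  expect_equal(table(ens$labels)[["left"]], 40)
  # below-threshold neurons cannot be sampled
  expect_error(build_pseudo_population(inp, n_per_class = 40,
                                       min_trials = 10000), "fewer than")
  # per-neuron sampling without replacement
  expect_true(all(apply(ens$sampled[1:40, ], 2,
                        function(s) !any(duplicated(s)))))
})

test_that("PCA reduction retains the cumulative-variance component count", {
  set.seed(9)
  sess <- small_session("dlpfc_like", 8, 250, seed = 201)
  inp <- prepare_decoding(sess)
  ens <- build_pseudo_population(inp, n_per_class = 40)
  full <- pca_reduce(ens, "per_bin", var_threshold = 1.0)
  expect_true(all(full$dims == min(dim(ens$X)[1], dim(ens$X)[3])))
  expect_error(pca_reduce(ens, "per_bin", var_threshold = 0), "var_threshold")
  # rank-1 data keeps exactly one component
  r1 <- ens
  r1$X <- array(outer(rnorm(80), rep(1, dim(ens$X)[2])) %o% rnorm(8),
                dim(ens$X))
  expect_true(all(pca_reduce(r1, "per_bin", 0.7)$dims == 1))
  # eigenvalue oracle on a random matrix
  A <- matrix(rnorm(200 * 50), 200, 50)
  d <- svd(sweep(A, 2, colMeans(A)), nu = 0)$d
  ev <- eigen(cov(A), only.values = TRUE)$values
  q_oracle <- which(cumsum(ev) / sum(ev) >= 0.7)[1]
  expect_identical(attnvalue:::n_components(d, 0.7), q_oracle)
  # joint mode: one subspace shared across bins
  j <- pca_reduce(ens, "joint", 0.7)
  expect_equal(dim(j$scores)[1:2], dim(ens$X)[1:2])
  expect_equal(dim(j$scores)[3], j$dims)
})

test_that("LDA posteriors match the closed form and brute-force densities", {
  # 1-D, empirical class means +-1, pooled variance exactly 1
  s <- 1 / sqrt(2)
  x <- matrix(c(1 - s, 1 + s, -1 - s, -1 + s), ncol = 1)
  y <- c("A", "A", "B", "B")
  fit <- lda_fit(x, y)
  expect_equal(unname(lda_posterior(fit, 0)[1, "A"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(lda_posterior(fit, 1)[1, "A"]), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # identical class means: posterior 0.5 everywhere
  x2 <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_equal(unname(lda_posterior(lda_fit(x2, y), 5)[1, ]), c(0.5, 0.5))
  # brute-force Gaussian density ratio on 5-D instances
  set.seed(12)
  for (rep in 1:5) {
    n <- 40; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    yy <- rep(c("A", "B"), each = n / 2)
    X[yy == "A", 1] <- X[yy == "A", 1] + runif(1, 0.5, 2)
    f <- lda_fit(X, yy)
    S <- f$cov
    Sinv <- solve(S)
    logd <- function(x, m) -0.5 * drop(t(x - m) %*% Sinv %*% (x - m))
    Xt <- matrix(rnorm(20 * p), 20, p)
    post_ref <- apply(Xt, 1, function(xr) {
      la <- logd(xr, f$means[1, ]); lb <- logd(xr, f$means[2, ])
      exp(la) / (exp(la) + exp(lb))
    })
    post <- lda_posterior(f, Xt)[, 1]
    expect_equal(unname(post), unname(post_ref), tolerance = 1e-10)
    # cross-check against the reference implementation in MASS
    skip_if_not_installed("MASS")
    m <- MASS::lda(X, grouping = yy, prior = c(0.5, 0.5))
    pm <- predict(m, Xt)$posterior[, "A"]
    expect_equal(unname(post), unname(pm), tolerance = 1e-6)
  }
  expect_error(lda_fit(matrix(rnorm(6), 6, 1), rep("A", 6)), "two classes")
})

test_that("exact vectorized LOOCV equals naive refitting", {
  set.seed(13)
  for (p in c(1, 3, 6)) {
    x <- matrix(rnorm(50 * p), 50, p)
    y <- rep(c("left", "right"), 25)
    x[y == "right", 1] <- x[y == "right", 1] + 0.8
    fast <- lda_loocv(x, y)$posterior_true
    naive <- vapply(1:50, function(m) {
      f <- lda_fit(x[-m, , drop = FALSE], y[-m])
      lda_posterior(f, x[m, ])[1, y[m]]
    }, numeric(1))
    expect_equal(fast, naive, tolerance = 1e-10)
  }
})

test_that("diagonal decoding finds cue structure and is seed-deterministic", {
  sess <- small_session("dlpfc_like", 12, 250, seed = 101)
  inp <- prepare_decoding(sess)
  dec <- decode_diagonal(inp, n_per_class = 40, n_cv = 3, seed = 5)
  dec2 <- decode_diagonal(inp, n_per_class = 40, n_cv = 3, seed = 5)
  expect_identical(dec$posterior, dec2$posterior)
  # posteriors are probabilities and class-complementary by construction
  expect_true(all(dec$posterior >= 0 & dec$posterior <= 1))
  late <- inp$bins$alignment == "stim_on" & inp$bins$center > 0.3
  pre <- inp$bins$alignment == "stim_on" & inp$bins$center < -0.25
  expect_gt(mean(dec$mean[late]), 0.8)
  expect_lt(abs(mean(dec$mean[pre]) - 0.5), 0.05)
  # label shuffling collapses performance to chance
  shuf <- decode_diagonal(inp, n_per_class = 40, n_cv = 3, seed = 6,
                          shuffle = TRUE)
  expect_lt(abs(mean(shuf$mean) - 0.5), 0.03)
  # strict per-fold PCA reference path agrees at the bins that matter
  sub <- inp
  keep_bins <- which(late)[1:3]
  sub$values <- inp$values[, keep_bins, , drop = FALSE]
  sub$bins <- inp$bins[keep_bins, ]
  strict <- decode_diagonal(sub, n_per_class = 30, n_cv = 2, seed = 7,
                            strict_folds = TRUE)
  default <- decode_diagonal(sub, n_per_class = 30, n_cv = 2, seed = 7)
  expect_lt(max(abs(strict$mean - default$mean)), 0.1)
})

test_that("decoding accuracy grows with signal strength and population size", {
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 220, seed = 301), cfg,
                          seed = 302)
  acc <- sapply(c(0.5, 2, 6), function(gain) {
    sess <- generate_population("dlpfc_like", 8, tr, cfg, seed = 303,
                                params = list(cue_coef_meanlog = log(gain),
                                              cue_coef_sdlog = 0.1))
    inp <- prepare_decoding(sess)
    late <- inp$bins$alignment == "stim_on" & inp$bins$center > 0.3
    dec <- decode_diagonal(inp, n_per_class = 40, n_cv = 2, seed = 304)
    mean(dec$mean[late])
  })
  expect_true(all(diff(acc) > -0.02))     # non-decreasing within MC error
  expect_gt(acc[3], acc[1])
})

test_that("cross-temporal decoding exposes the attention-side flip", {
  sess <- small_session("dlpfc_like", 12, 250, seed = 101)
  inp <- prepare_decoding(sess)
  ct <- decode_cross_temporal(inp, n_per_class = 40, n_cv = 3, seed = 8)
  post <- inp$bins$alignment == "stim_on" & inp$bins$center > 0.3
  # pre-stimulus-trained decoder goes below chance after the shift
  expect_lt(mean(ct$pretrain_mean[post]), 0.4)
  # within-period blocks of the train x test matrix stay above chance
  late_idx <- which(post)
  expect_gt(mean(ct$matrix[late_idx, late_idx]), 0.7)
  # stationary coding: no flip, matrix uniformly above chance post-stimulus
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 220, seed = 311), cfg,
                          seed = 312)
  ev <- trial_events(tr, cfg)
  sp <- do.call(rbind, lapply(1:10, function(i) {
    simulate_neuron(neuron_tuning(paste0("s", i), "DLPFC", 10,
                                  coef = list(cue_post = sample(c(-4, 4), 1)),
                                  flip_latency_s = -1.0),
                    tr, ev, cfg, seed = 320 + i)
  }))
  sess2 <- list(config = cfg, trials = tr, events = ev, spikes = sp)
  inp2 <- prepare_decoding(sess2)
  ct2 <- decode_cross_temporal(inp2, n_per_class = 40, n_cv = 2, seed = 9)
  idx <- which(inp2$bins$alignment == "stim_on" & inp2$bins$center > 0)
  expect_gt(min(ct2$matrix[idx, idx]), 0.5)
})

test_that("shuffle significance applies BH-FDR with directional masks", {
  set.seed(30)
  M <- 60; T_ <- 10; R <- 3
  bins <- data.frame(center = seq_len(T_), alignment = "stim_on")
  true <- array(0.5 + rnorm(M * T_ * R, 0, 0.05), c(M, T_, R))
  shuf <- array(0.5 + rnorm(M * T_ * R, 0, 0.05), c(M, T_, R))
  true[, 1, ] <- true[, 1, ] + 0.3   # above-null bin
  true[, 2, ] <- true[, 2, ] - 0.3   # below-null bin
  sig <- shuffle_significance(true, shuf, bins, alpha = 0.01)
  expect_true(sig$sig_above[1] && !sig$sig_below[1])
  expect_true(sig$sig_below[2] && !sig$sig_above[2])
  expect_lte(sum(sig$sig_above[-(1:2)] | sig$sig_below[-(1:2)]), 1)
  # zero difference everywhere: nothing significant
  sig0 <- shuffle_significance(true, true, bins)
  expect_false(any(sig0$sig_above | sig0$sig_below))
  # BH step-up rule by hand
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), "BH") < 0.05,
               c(TRUE, TRUE, FALSE))
})

test_that("RT-split decoding flags degenerate splits and favors fast trials", {
  sess <- small_session("dlpfc_like", 10, 250, seed = 401)
  inp <- prepare_decoding(sess)
  const <- inp
  const$rts <- rep(0.25, length(inp$rts))
  expect_true(rt_split_decoding(const, n_per_class = 20)$degenerate)
  # generator with cue coding inversely related to RT
  cfg <- task_config("D")
  tr <- simulate_behavior(generate_trial_schedule(cfg, 300, seed = 411), cfg,
                          seed = 412)
  sess2 <- generate_population("dlpfc_like", 10, tr, cfg, seed = 413,
                               params = list(cue_rt_scaling = 0.9))
  inp2 <- prepare_decoding(sess2)
  rs <- rt_split_decoding(inp2, n_per_class = 40, n_cv = 3, seed = 414)
  expect_false(rs$degenerate)
  pre <- inp2$bins$alignment == "change_on" & inp2$bins$center < 0
  expect_gt(mean(rs$comparison$mean_fast[pre]),
            mean(rs$comparison$mean_slow[pre]))
})
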