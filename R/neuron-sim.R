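#' Response kernel: saturating rise with optional offset decay
#'
#' Zero before `on_s`; rises as `1 - exp(-(t - on)/tau_rise)` until `off_s`;
#' decays exponentially with `tau_decay_s` afterwards. With `off_s = Inf`
#' the component is sustained.
#'
#' @param t Time grid (s).
#' @param on_s,off_s Component on/off times (s).
#' @param tau_rise_s,tau_decay_s Rise and decay time constants (s).
#' @return Kernel values in `[0, 1]`.
#' @keywords internal
response_kernel <- function(t, on_s, off_s = Inf,
                            tau_rise_s = 0.03, tau_decay_s = 0.05) {
  k <- numeric(length(t))
  up <- t >= on_s & t < off_s
  k[up] <- 1 - exp(-(t[up] - on_s) / tau_rise_s)
  if (is.finite(off_s)) {
    peak <- 1 - exp(-(off_s - on_s) / tau_rise_s)
    dn <- t >= off_s
    k[dn] <- peak * exp(-(t[dn] - off_s) / tau_decay_s)
  }
  k
}

#' Define a synthetic neuron's tuning
#'
#' Coefficients are in Hz per regressor unit: `cue_pre` and `cue_post`
#' multiply the signed frame side (-1/+1) before and after the attention
#' shift (they may differ in sign, reproducing the shift geometry);
#' `sv`/`nsv`/`cv`/`ucv` multiply z-scored value levels; `frame` is a
#' side-independent transient at cue onset. Spiking is an inhomogeneous
#' Poisson process on the rectified summed rate.
#'
#' @param neuron_id Identifier.
#' @param area `"OFC"` or `"DLPFC"` label (metadata).
#' @param baseline_hz Baseline rate, >= 0.
#' @param coef Named list of coefficients (Hz per unit); missing entries are 0.
#' @param flip_latency_s Time after stimulus onset at which the cue-side
#'   coding flips from the pre to the post component (s).
#' @param tau_rise_s,tau_decay_s Kernel time constants (s).
#' @return Object of class `neuron_tuning`.
#' @export
neuron_tuning <- function(neuron_id, area = c("OFC", "DLPFC"),
                          baseline_hz = 10,
                          coef = list(),
                          flip_latency_s = 0.15,
                          tau_rise_s = 0.03, tau_decay_s = 0.05,
                          cue_rt_scaling = 0) {
  area <- match.arg(area)
  stopifnot(baseline_hz >= 0)
  full <- list(cue_pre = 0, cue_post = 0, sv = 0, nsv = 0, cv = 0, ucv = 0,
               frame = 0)
  bad <- setdiff(names(coef), names(full))
  if (length(bad)) stop("unknown tuning coefficients: ", paste(bad, collapse = ", "))
  full[names(coef)] <- coef
  structure(list(neuron_id = neuron_id, area = area,
                 baseline_hz = baseline_hz, coef = full,
                 flip_latency_s = flip_latency_s,
                 tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 cue_rt_scaling = cue_rt_scaling),
            class = "neuron_tuning")
}

#' Per-trial regressor values feeding the rate model
#' @keywords internal
tuning_covariates <- function(trials) {
  zs <- function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)  # single-stim trials sit at the mean
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  list(cue_pre = trials$att_cue_loc,
       cue_post = trials$att_cue_loc,
       sv = zs(trials$SV), nsv = zs(trials$NSV),
       cv = zs(trials$CV), ucv = zs(trials$UCV),
       frame = rep(1, nrow(trials)))
}

#' Firing-rate matrix of a synthetic neuron
#'
#' Evaluates `rectify(baseline + sum_c coef_c * kernel_c(t) * x_c(trial))`
#' on an evenly spaced time grid; rates are zero after each trial's end.
#'
#' @param tuning A [neuron_tuning()].
#' @param trials Trial table (with derived regressors).
#' @param events Event table from [trial_events()].
#' @param config The [task_config()].
#' @param bin_s Grid resolution (s), > 0.
#' @return List with `rate` (trials x bins matrix, Hz), `t` (bin left edges,
#'   s) and `bin_s`.
#' @export
neuron_rate <- function(tuning, trials, events, config, bin_s = 0.005) {
  if (bin_s <= 0) stop("bin width must be positive")
  tm <- config$timing
  t_end <- max(events$trial_end)
  t <- seq(0, t_end, by = bin_s)
  t <- t[-length(t)]                      # left edges of the bins
  x <- tuning_covariates(trials)
  # optional RT dependence: cue-coding gain larger on fast-response trials
  if ((tuning$cue_rt_scaling %||% 0) != 0 && !is.null(trials$rt_s)) {
    rt <- trials$rt_s
    g <- rep(1, nrow(trials))
    ok <- !is.na(rt)
    if (any(ok) && stats::sd(rt[ok]) > 0) {
      g[ok] <- pmax(0, 1 - tuning$cue_rt_scaling *
                      (rt[ok] - mean(rt[ok])) / stats::sd(rt[ok]))
    }
    x$cue_pre <- x$cue_pre * g
    x$cue_post <- x$cue_post * g
  }
  flip_t <- tm$stim_on + tuning$flip_latency_s
  kern <- list(
    cue_pre = response_kernel(t, tm$cue_on, flip_t,
                              tuning$tau_rise_s, tuning$tau_decay_s),
    cue_post = response_kernel(t, flip_t, Inf, tuning$tau_rise_s),
    sv = response_kernel(t, tm$stim_on + 0.08, Inf, tuning$tau_rise_s),
    nsv = response_kernel(t, tm$stim_on + 0.08, Inf, tuning$tau_rise_s),
    cv = response_kernel(t, tm$stim_on + 0.08, Inf, tuning$tau_rise_s),
    ucv = response_kernel(t, tm$stim_on + 0.08, Inf, tuning$tau_rise_s),
    frame = response_kernel(t, tm$cue_on, tm$cue_on + 0.06, 0.01, 0.04))
  rate <- matrix(tuning$baseline_hz, nrow(trials), length(t))
  for (cm in names(kern)) {
    b <- tuning$coef[[cm]]
    if (b != 0) rate <- rate + b * outer(x[[cm]], kern[[cm]])
  }
  rate[rate < 0] <- 0
  rate[outer(events$trial_end, t + bin_s, `<`)] <- 0   # beyond trial end
  list(rate = rate, t = t, bin_s = bin_s)
}

#' Simulate a neuron's spike trains
#'
#' Inhomogeneous Poisson spiking: counts per grid bin are
#' `Poisson(rate * bin)`, with spike times placed uniformly within bins.
#'
#' @inheritParams neuron_rate
#' @param seed Optional integer seed.
#' @return `data.frame(neuron_id, area, trial_id, spike_time_s)` sorted by
#'   trial then time.
#' @export
simulate_neuron <- function(tuning, trials, events, config, bin_s = 0.005,
                            seed = NULL) {
  rm_ <- neuron_rate(tuning, trials, events, config, bin_s)
  with_seed(seed, {
    counts <- stats::rpois(length(rm_$rate), rm_$rate * bin_s)
    dim(counts) <- dim(rm_$rate)
    idx <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[counts > 0]
    trial <- rep(trials$trial_id[idx[, 1]], reps)
    left <- rep(rm_$t[idx[, 2]], reps)
    times <- left + stats::runif(length(trial)) * bin_s
    o <- order(trial, times)
    data.frame(neuron_id = tuning$neuron_id, area = tuning$area,
               trial_id = trial[o], spike_time_s = times[o],
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic population and assemble a session
#'
#' Draws per-neuron tunings from an area profile and simulates spiking for
#' every neuron on a shared trial schedule.
#'
#' `"ofc_like"` neurons carry value signals dominated by the salient value
#' (SV): a configurable fraction are value-tuned, with mixed coefficient
#' signs (~58% positive), negligible sustained cue coding, and a brief
#' frame transient. `"dlpfc_like"` neurons carry strong cue-side signals
#' whose sign flips `flip_latency_s` after stimulus onset (the attention
#' shift from the frame to the opposite, cued side), plus moderate SV
#' coding.
#'
#' @param profile `"ofc_like"` or `"dlpfc_like"`.
#' @param n_neurons Number of neurons (> 0).
#' @param trials Trial table (with outcomes, see [simulate_behavior()]).
#' @param config The [task_config()].
#' @param seed Integer seed; the session is deterministic given the seed.
#' @param params Optional overrides: `p_value_tuned`, `p_positive`,
#'   `value_coef_meanlog`, `value_coef_sdlog`, `cue_coef_meanlog`,
#'   `cue_coef_sdlog`, `baseline_range_hz`, `frame_coef_hz`,
#'   `flip_latency_s`, `cue_rt_scaling`.
#' @return A `synthetic_session`: list with `config`, `trials`, `events`,
#'   `spikes` (one data.frame for all neurons), `neurons` (id/area table)
#'   and `ground_truth` (the tuning table).
#' @export
generate_population <- function(profile = c("ofc_like", "dlpfc_like"),
                                n_neurons, trials, config, seed = NULL,
                                params = list()) {
  profile <- match.arg(profile)
  if (n_neurons <= 0) stop("n_neurons must be positive")
  defaults <- if (profile == "ofc_like") {
    list(p_value_tuned = 0.55, p_positive = 0.58,
         value_coef_meanlog = log(3), value_coef_sdlog = 0.35,
         cue_coef_meanlog = -Inf, cue_coef_sdlog = 0,
         baseline_range_hz = c(5, 15), frame_coef_hz = 2.5,
         flip_latency_s = 0.15, cue_rt_scaling = 0)
  } else {
    list(p_value_tuned = 0.45, p_positive = 0.55,
         value_coef_meanlog = log(1.5), value_coef_sdlog = 0.35,
         cue_coef_meanlog = log(4), cue_coef_sdlog = 0.3,
         baseline_range_hz = c(5, 15), frame_coef_hz = 1,
         flip_latency_s = 0.15, cue_rt_scaling = 0)
  }
  defaults[names(params)] <- params
  p <- defaults
  events <- trial_events(trials, config)
  with_seed(seed, {
    tunings <- vector("list", n_neurons)
    for (i in seq_len(n_neurons)) {
      value_tuned <- stats::runif(1) < p$p_value_tuned
      sgn <- if (stats::runif(1) < p$p_positive) 1 else -1
      sv <- if (value_tuned) sgn * stats::rlnorm(1, p$value_coef_meanlog,
                                                 p$value_coef_sdlog) else 0
      cue <- if (is.finite(p$cue_coef_meanlog)) {
        sample(c(-1, 1), 1) * stats::rlnorm(1, p$cue_coef_meanlog,
                                            p$cue_coef_sdlog)
      } else 0
      tunings[[i]] <- neuron_tuning(
        neuron_id = sprintf("%s_%03d", toupper(sub("_like", "", profile)), i),
        area = if (profile == "ofc_like") "OFC" else "DLPFC",
        baseline_hz = stats::runif(1, p$baseline_range_hz[1],
                                   p$baseline_range_hz[2]),
        coef = list(sv = sv,
                    cue_pre = cue,
                    cue_post = -cue,      # sign flip: attention shifts sides
                    frame = p$frame_coef_hz * stats::runif(1, 0.5, 1.5)),
        flip_latency_s = p$flip_latency_s,
        cue_rt_scaling = p$cue_rt_scaling)
    }
    spikes <- do.call(rbind, lapply(tunings, simulate_neuron,
                                    trials = trials, events = events,
                                    config = config))
    gt <- do.call(rbind, lapply(tunings, function(tu) {
      data.frame(neuron_id = tu$neuron_id, area = tu$area,
                 baseline_hz = tu$baseline_hz,
                 as.data.frame(tu$coef),
                 flip_latency_s = tu$flip_latency_s,
                 stringsAsFactors = FALSE)
    }))
    structure(list(config = config, trials = trials, events = events,
                   spikes = spikes,
                   neurons = gt[, c("neuron_id", "area")],
                   ground_truth = gt),
              class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session: %d trials, %d neurons, %d spikes (paradigm %s)>\n",
              nrow(x$trials), nrow(x$neurons), nrow(x$spikes),
              x$config$paradigm))
  invisible(x)
}
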