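#' Regression design for the CPD models
#'
#' Two model specifications: `"sv_nsv"` regresses rate on attention-cue
#' location, salient value and non-salient value; `"cv_ucv"` on cue
#' location, cued value and un-cued value. Cue location is coded -1/+1 and
#' every predictor is z-scored on the analyzed trial subset.
#'
#' @param trials Trial table rows entering the fit.
#' @param spec `"sv_nsv"` or `"cv_ucv"`.
#' @return Matrix (trials x 3) of z-scored predictors with an attribute
#'   `regressors` naming the columns.
#' @export
cpd_design <- function(trials, spec = c("sv_nsv", "cv_ucv")) {
  spec <- match.arg(spec)
  cols <- if (spec == "sv_nsv") c("att_cue_loc", "SV", "NSV")
          else c("att_cue_loc", "CV", "UCV")
  X <- sapply(cols, function(cn) zscore(trials[[cn]]))
  colnames(X) <- cols
  X
}

#' Nested least squares and coefficients of partial determination
#'
#' Fits the full ordinary-least-squares model (intercept + all regressors)
#' and each leave-one-regressor-out reduced model, and computes
#' `CPD_i = (SSE_-i - SSE_all) / SSE_-i` per regressor. `0 <= CPD < 1`
#' is guaranteed by model nesting (degenerate 0/0 reported as 0).
#'
#' @param y Response vector (>= 10 trials).
#' @param X z-scored predictor matrix (trials x k, no intercept column).
#' @param condition_tol Reciprocal-condition threshold below which the
#'   design is flagged collinear.
#' @return List: `coef`, `se`, `t`, `p` (full-model coefficients incl.
#'   intercept), `sse_full`, `sse_reduced` (named), `cpd` (named),
#'   `collinear` flag.
#' @export
fit_cpd <- function(y, X, condition_tol = 1e-10) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 10) stop("need at least 10 trials")
  if (nrow(X) != n) stop("design/response mismatch")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant predictor in design")
  Xf <- cbind(`(Intercept)` = 1, X)
  collinear <- rcond(crossprod(Xf)) < condition_tol
  if (collinear) warning("design is near-collinear; CPDs may be unstable")
  fit <- stats::lm.fit(Xf, y)
  sse_full <- sum(fit$residuals^2)
  k <- ncol(X)
  cf <- fit$coefficients
  XtXinv <- solve(crossprod(Xf))
  sig2 <- sse_full / (n - k - 1)
  se <- sqrt(diag(XtXinv) * sig2)
  tval <- cf / se
  p <- 2 * stats::pt(-abs(tval), df = n - k - 1)
  sse_red <- cpd <- stats::setNames(numeric(k), colnames(X))
  for (i in seq_len(k)) {
    r <- stats::lm.fit(Xf[, -(i + 1), drop = FALSE], y)
    sse_red[i] <- sum(r$residuals^2)
    cpd[i] <- if (sse_red[i] > 0) (sse_red[i] - sse_full) / sse_red[i] else 0
  }
  cpd <- pmin(pmax(cpd, 0), 1 - 1e-15)
  list(coef = cf, se = se, t = tval, p = p, sse_full = sse_full,
       sse_reduced = sse_red, cpd = cpd, collinear = collinear)
}

#' Orthonormal bases for the full and reduced CPD models
#' @keywords internal
cpd_bases <- function(X) {
  Xf <- cbind(1, X)
  k <- ncol(X)
  Q_all <- qr.Q(qr(Xf))
  Q_red <- lapply(seq_len(k), function(i) qr.Q(qr(Xf[, -(i + 1), drop = FALSE])))
  list(Q_all = Q_all, Q_red = Q_red, k = k, names = colnames(X))
}

#' SSE of many responses against a fixed orthonormal basis
#' @keywords internal
sse_against <- function(Q, Y) {
  pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 0)
}

#' CPD time courses across a population
#'
#' Fits the chosen regression model to every neuron's firing rate in
#' consecutive 25-ms windows aligned to the stimulus onset and to the
#' luminance change, computes per-bin CPDs, a per-neuron baseline (the CPD
#' from the 200-ms pre-cue window averaged across the three regressors),
#' and population tests: per-bin two-tailed paired t-tests of each
#' regressor's CPD against baseline, and of the two value regressors
#' against each other, both under Benjamini-Hochberg FDR across bins.
#'
#' Only correct double-stimulus trials with a luminance change enter;
#' neurons below the inclusion rules (fewer than `min_trials` eligible
#' trials or mean rate below `min_rate_hz`) are dropped.
#'
#' @param session Session list (`trials`, `events`, `spikes`).
#' @param spec `"sv_nsv"` or `"cv_ucv"`.
#' @param bin_s Analysis bin (s).
#' @param stim_window,change_window Aligned windows (s).
#' @param p_thresh Significance level applied to FDR-adjusted p-values.
#' @param min_trials,min_rate_hz Neuron inclusion rules.
#' @return A `cpd_result`: `cpd` (neurons x bins x 3 array), `bins`,
#'   `baseline` (per neuron), `pop` (per-bin population mean/SEM and
#'   FDR-adjusted p-values), `spec`, `neuron_ids`, `n_trials`.
#' @export
cpd_timecourse <- function(session, spec = c("sv_nsv", "cv_ucv"),
                           bin_s = 0.025,
                           stim_window = c(-0.4, 0.6),
                           change_window = c(-0.4, 0.4),
                           p_thresh = 0.005,
                           min_trials = 100, min_rate_hz = 1) {
  spec <- match.arg(spec)
  trials <- session$trials
  use <- trials$outcome == "hit" & !trials$is_single_stimulus &
    !is.na(trials$change_latency_s)
  tr <- trials[use, ]
  if (nrow(tr) < 20) stop("too few eligible trials")
  neuron_ids <- unique(session$spikes$neuron_id)

  stim <- bin_rates(session$spikes, session$events, tr$trial_id, neuron_ids,
                    "stim_on", stim_window, bin_s)
  change <- bin_rates(session$spikes, session$events, tr$trial_id, neuron_ids,
                      "change_on", change_window, bin_s)
  base <- bin_rates(session$spikes, session$events, tr$trial_id, neuron_ids,
                    "cue_on", c(-0.2, 0), 0.2)

  # inclusion: eligible-trial count and overall mean rate
  mean_rate <- apply(stim$values, 3, mean)
  keep <- rep(nrow(tr) >= min_trials, length(neuron_ids)) & mean_rate >= min_rate_hz
  neuron_ids <- neuron_ids[keep]
  if (!length(neuron_ids)) stop("no neuron passes the inclusion rules")

  X <- cpd_design(tr, spec)
  bases <- cpd_bases(X)
  bins <- data.frame(
    center = c(stim$centers, change$centers),
    alignment = rep(c("stim_on", "change_on"),
                    c(length(stim$centers), length(change$centers))),
    stringsAsFactors = FALSE)
  T_ <- nrow(bins)
  N <- length(neuron_ids)
  cpd <- array(NA_real_, c(N, T_, 3),
               dimnames = list(neuron_ids, NULL, bases$names))
  vals <- function(tensor, t) matrix(tensor$values[, t, keep], ncol = N)
  Ts <- length(stim$centers)
  for (t in seq_len(T_)) {
    Y <- if (t <= Ts) vals(stim, t) else vals(change, t - Ts)
    sse_all <- sse_against(bases$Q_all, Y)
    for (i in seq_len(3)) {
      sse_r <- sse_against(bases$Q_red[[i]], Y)
      cpd[, t, i] <- ifelse(sse_r > 0, (sse_r - sse_all) / sse_r, 0)
    }
  }
  # baseline: one 200-ms pre-cue window, CPD averaged across regressors
  Yb <- matrix(base$values[, 1, keep], ncol = N)
  sse_all_b <- sse_against(bases$Q_all, Yb)
  cpd_b <- sapply(seq_len(3), function(i) {
    sse_r <- sse_against(bases$Q_red[[i]], Yb)
    ifelse(sse_r > 0, (sse_r - sse_all_b) / sse_r, 0)
  })
  baseline <- rowMeans(cpd_b)

  pop <- data.frame(bins[rep(seq_len(T_), 3), ],
                    regressor = rep(bases$names, each = T_),
                    mean = NA_real_, sem = NA_real_, p = NA_real_,
                    row.names = NULL)
  for (i in seq_len(3)) {
    idx <- (i - 1) * T_ + seq_len(T_)
    pop$mean[idx] <- colMeans(matrix(cpd[, , i], nrow = N))
    pop$sem[idx] <- apply(matrix(cpd[, , i], nrow = N), 2, stats::sd) / sqrt(N)
    pop$p[idx] <- vapply(seq_len(T_), function(t) {
      paired_t_p(cpd[, t, i], baseline)
    }, numeric(1))
  }
  pop$p_fdr <- stats::p.adjust(pop$p, method = "BH")
  pop$sig <- pop$p_fdr < p_thresh
  # value-regressor contrast (SV vs NSV, or CV vs UCV)
  pv <- vapply(seq_len(T_), function(t) paired_t_p(cpd[, t, 2], cpd[, t, 3]),
               numeric(1))
  contrast <- data.frame(bins, p = pv,
                         p_fdr = stats::p.adjust(pv, method = "BH"))
  contrast$sig <- contrast$p_fdr < p_thresh

  structure(list(cpd = cpd, bins = bins, baseline = baseline, pop = pop,
                 contrast = contrast, spec = spec, neuron_ids = neuron_ids,
                 n_trials = nrow(tr)),
            class = "cpd_result")
}

paired_t_p <- function(a, b) {
  d <- a - b
  if (length(d) < 2 || stats::sd(d) == 0) return(1)
  stats::t.test(d)$p.value
}

#' Epoch-level CPDs and area comparisons
#'
#' Computes per-neuron CPDs from the mean firing rate in a per-trial
#' window (the variable-length stimulus period, or the post-cue period for
#' the top-down attention comparison), per-neuron coefficient significance
#' (regression t-test at `p_coef`, uncorrected as in the figure
#' conventions), a population paired t-test between the two value
#' regressors' CPDs, and the per-neuron difference
#' `dCPD = CPD(cue location) - CPD(value2)` with a one-sample t-test.
#'
#' @param session Session list.
#' @param spec `"sv_nsv"` or `"cv_ucv"`.
#' @param window `"stimulus_period"` or `"postcue_period"`.
#' @param p_coef Per-neuron coefficient significance threshold.
#' @param min_trials,min_rate_hz Neuron inclusion rules.
#' @return List: `neurons` (per-neuron CPDs, coefficient p-values,
#'   significance flags, dCPD), `paired_t` (value2 vs value3),
#'   `delta_t` (one-sample test on dCPD), `spec`, `window`.
#' @export
epoch_cpd_summary <- function(session, spec = c("sv_nsv", "cv_ucv"),
                              window = c("stimulus_period", "postcue_period"),
                              p_coef = 0.05,
                              min_trials = 100, min_rate_hz = 1) {
  spec <- match.arg(spec)
  window <- match.arg(window)
  trials <- session$trials
  use <- trials$outcome == "hit" & !trials$is_single_stimulus &
    !is.na(trials$change_latency_s)
  tr <- trials[use, ]
  neuron_ids <- unique(session$spikes$neuron_id)
  R <- epoch_rates(session$spikes, session$events, tr$trial_id, neuron_ids)[[window]]
  ok_tr <- !is.na(R[, 1])
  R <- R[ok_tr, , drop = FALSE]
  tr <- tr[ok_tr, ]
  mean_rate <- colMeans(R)
  keep <- nrow(tr) >= min_trials & mean_rate >= min_rate_hz
  neuron_ids <- neuron_ids[keep]
  R <- R[, keep, drop = FALSE]
  if (length(neuron_ids) < 2) stop("fewer than 2 neurons for population tests")

  X <- cpd_design(tr, spec)
  rows <- lapply(seq_along(neuron_ids), function(j) {
    f <- fit_cpd(R[, j], X)
    data.frame(neuron_id = neuron_ids[j],
               t(f$cpd),
               cue_p = f$p[2], value2_p = f$p[3], value3_p = f$p[4],
               dcpd = unname(f$cpd[1] - f$cpd[2]),
               stringsAsFactors = FALSE)
  })
  neurons <- do.call(rbind, rows)
  names(neurons)[2:4] <- colnames(X)
  neurons$cue_sig <- neurons$cue_p < p_coef
  neurons$value2_sig <- neurons$value2_p < p_coef
  neurons$value3_sig <- neurons$value3_p < p_coef

  v2 <- neurons[[colnames(X)[2]]]
  v3 <- neurons[[colnames(X)[3]]]
  d23 <- v2 - v3
  paired_t <- if (stats::sd(d23) == 0) {
    list(t = NA_real_, p = 1, degenerate = TRUE)
  } else {
    ts <- stats::t.test(d23)
    list(t = unname(ts$statistic), p = ts$p.value, degenerate = FALSE)
  }
  delta_t <- if (stats::sd(neurons$dcpd) == 0) {
    list(mean = mean(neurons$dcpd), t = NA_real_, p = 1, degenerate = TRUE)
  } else {
    ts <- stats::t.test(neurons$dcpd)
    list(mean = mean(neurons$dcpd), t = unname(ts$statistic), p = ts$p.value,
         degenerate = FALSE)
  }
  list(neurons = neurons, paired_t = paired_t, delta_t = delta_t,
       spec = spec, window = window)
}
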