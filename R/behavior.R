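#' Score trials from response and change times
#'
#' Recomputes outcome labels from the recorded event times, applying the
#' detection rules: a saccade within the response window after the target's
#' luminance change is a hit, otherwise a miss; in the
#' target/distractor paradigm a response within the window after the
#' distractor's change is a false alarm (and ends the trial), and a
#' distractor-only trial with fixation held to the end is a correct
#' rejection. Responses before any change are scored `"break"` and excluded
#' from rate denominators downstream.
#'
#' @param trials Trial table.
#' @param events Event table with `response`, `change_on`,
#'   `distractor_change_on` (s from trial start).
#' @param config The [task_config()].
#' @return Character vector of outcome labels, one per trial.
#' @export
score_trials <- function(trials, events, config) {
  rw <- config$response_window
  n <- nrow(trials)
  out <- character(n)
  for (i in seq_len(n)) {
    resp <- events$response[i]
    chg <- events$change_on[i]
    dis <- events$distractor_change_on[i]
    first_chg <- suppressWarnings(min(chg, dis, na.rm = TRUE))
    if (!is.na(resp) && is.finite(first_chg) && resp < first_chg + rw[1]) {
      out[i] <- "break"                  # premature response
    } else if (!is.na(dis) && !is.na(resp) &&
               resp >= dis + rw[1] && resp <= dis + rw[2] &&
               !(!is.na(chg) && resp >= chg + rw[1] && resp <= chg + rw[2])) {
      # a response in the distractor's window is a false alarm unless it
      # also lies in the target's own window (then the target is scored)
      out[i] <- "false_alarm"
    } else if (!is.na(chg)) {
      hit <- !is.na(resp) && resp >= chg + rw[1] && resp <= chg + rw[2]
      out[i] <- if (hit) "hit" else "miss"
    } else {
      # distractor-only trial, no response in the distractor window
      out[i] <- if (is.na(resp)) "correct_rejection" else "miss"
    }
  }
  out
}

#' Per-session behavioural performance
#'
#' Counts and rates per condition cell (`trial_type` crossed with whether the
#' change occurred at the salient stimulus) and the mean reaction time of
#' responded trials (hits and false alarms). The hit rate denominator is
#' hit + miss; the correct-rejection rate denominator is CR + false alarms
#' among distractor-only trials.
#'
#' @param trials Scored trial table (with `outcome`, `rt_s`,
#'   `change_at_salient`).
#' @param session Optional session label.
#' @return `data.frame` with one row per condition: counts, `rate`
#'   (hit rate, or CR rate for distractor-only), `rt_mean_s`, `n_rt`.
#' @export
session_performance <- function(trials, session = NA) {
  tr <- trials[trials$outcome != "break", , drop = FALSE]
  cells <- unique(data.frame(trial_type = tr$trial_type,
                             change_at_salient = tr$change_at_salient,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$trial_type, !cells$change_at_salient), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- tr[tr$trial_type == cells$trial_type[i] &
                tr$change_at_salient == cells$change_at_salient[i], ]
    n_hit <- sum(sub$outcome == "hit")
    n_miss <- sum(sub$outcome == "miss")
    n_fa <- sum(sub$outcome == "false_alarm")
    n_cr <- sum(sub$outcome == "correct_rejection")
    rate <- if (cells$trial_type[i] == "distractor_only") {
      if (n_cr + n_fa > 0) n_cr / (n_cr + n_fa) else NA_real_
    } else if (n_hit + n_miss > 0) n_hit / (n_hit + n_miss) else NA_real_
    rts <- sub$rt_s[sub$outcome %in% c("hit", "false_alarm")]
    data.frame(session = session,
               trial_type = cells$trial_type[i],
               change_at_salient = cells$change_at_salient[i],
               n_hit = n_hit, n_miss = n_miss, n_false_alarm = n_fa,
               n_correct_rejection = n_cr, rate = rate,
               rt_mean_s = if (length(rts)) mean(rts) else NA_real_,
               n_rt = length(rts), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Across-session condition means and SEM
#'
#' Averages each condition's rate and RT within-session first, then reports
#' the across-session mean and standard error (`sd / sqrt(n)`, n-1
#' denominator). Sessions with an empty condition cell are excluded pairwise.
#'
#' @param perfs List of [session_performance()] tables (>= 2 sessions).
#' @return `data.frame`: condition, `rate_mean`, `rate_sem`, `rt_mean_s`,
#'   `rt_sem_s`, `n_sessions`.
#' @export
summarize_sessions <- function(perfs) {
  if (length(perfs) < 2) stop("need at least 2 sessions")
  all <- do.call(rbind, perfs)
  key <- interaction(all$trial_type, all$change_at_salient, drop = TRUE)
  res <- lapply(levels(key), function(k) {
    sub <- all[key == k, ]
    r <- sub$rate[!is.na(sub$rate)]
    rt <- sub$rt_mean_s[!is.na(sub$rt_mean_s)]
    data.frame(trial_type = sub$trial_type[1],
               change_at_salient = sub$change_at_salient[1],
               rate_mean = mean(r), rate_sem = stats::sd(r) / sqrt(length(r)),
               rt_mean_s = if (length(rt)) mean(rt) else NA_real_,
               rt_sem_s = if (length(rt) > 1) stats::sd(rt) / sqrt(length(rt)) else NA_real_,
               n_sessions = length(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's rule). For n <= `exact_max`
#' the two-tailed p is computed by exact enumeration over all 2^n sign
#' assignments of the (tie-averaged) ranks; above that, a normal
#' approximation with tie correction is used. If every difference is zero
#' the result is flagged degenerate with p = 1.
#'
#' @param a,b Equal-length paired per-session metrics.
#' @param exact_max Largest n for exact enumeration (default 15).
#' @return List: `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n` (non-zero pairs), `direction` (sign of median
#'   difference), `method`, `degenerate`.
#' @export
paired_wilcoxon <- function(a, b, exact_max = 15) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n = 0, direction = 0,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null distribution of V over all 2^n sign assignments, via
    # convolution on doubled (integer) midranks
    r2 <- as.integer(round(2 * r))
    cnt <- 1
    for (ri in r2) {
      new <- c(cnt, numeric(ri))
      new[(ri + 1):length(new)] <- new[(ri + 1):length(new)] + cnt
      cnt <- new
    }
    v2 <- 0:(length(cnt) - 1L)
    mu2 <- n * (n + 1) / 2               # 2 * n(n+1)/4
    p <- sum(cnt[abs(v2 - mu2) >= abs(2 * v - mu2) - 1e-9]) / 2^n
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = min(p, 1), n = n,
       direction = sign(stats::median(d)), method = method,
       degenerate = FALSE)
}
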