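#' Default behavioural parameter table
#'
#' Per-condition response probabilities and reaction-time parameters used by
#' [simulate_behavior()]. Cells are `(trial_type, change at salient vs
#' non-salient stimulus)`. Hit probabilities and RT means default to values
#' typical of well-trained subjects on this task (valid ~94%, invalid ~90%,
#' target ~92-94%, distractor correct-rejection ~81%; RTs 220-300 ms); the RT
#' standard deviation is a generator choice (40 ms) since only means are
#' constrained. For distractor changes `p_respond` is the false-alarm
#' probability.
#'
#' @param paradigm `"D"` or `"G"`.
#' @return `data.frame` with columns `trial_type`, `change_salient`,
#'   `p_respond`, `rt_mean_s`, `rt_sd_s`.
#' @export
default_behav_params <- function(paradigm = c("D", "G")) {
  paradigm <- match.arg(paradigm)
  if (paradigm == "D") {
    data.frame(
      trial_type = c("valid", "valid", "invalid", "invalid"),
      change_salient = c(TRUE, FALSE, TRUE, FALSE),
      p_respond = c(0.948, 0.939, 0.903, 0.903),
      rt_mean_s = c(0.2236, 0.2254, 0.2363, 0.2320),
      rt_sd_s = 0.04,
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      trial_type = c("target", "target",
                     "distractor_target", "distractor_target",
                     "distractor", "distractor"),
      change_salient = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
      # "distractor" rows give the false-alarm probability on the
      # distractor's change (1 - correct-rejection rate)
      p_respond = c(0.940, 0.912, 0.900, 0.900, 0.186, 0.186),
      rt_mean_s = c(0.2738, 0.2822, 0.2712, 0.2712, 0.2944, 0.2978),
      rt_sd_s = 0.04,
      stringsAsFactors = FALSE)
  }
}

lookup_cell <- function(params, trial_type, salient) {
  i <- which(params$trial_type == trial_type & params$change_salient == salient)
  if (length(i) != 1L) stop(sprintf("no behavioural cell for (%s, salient=%s)",
                                    trial_type, salient))
  params[i, ]
}

#' Simulate behavioural outcomes for a trial schedule
#'
#' Draws per-trial outcomes (`hit`, `miss`, `false_alarm`,
#' `correct_rejection`) Bernoulli per condition cell, and reaction times from
#' a normal truncated to the legal response window. Distractor+target trials
#' resolve the distractor response first: a false alarm ends the trial and no
#' target response is scored. For correct (rewarded) trials one of the two
#' stimuli is selected at random and its level recorded as
#' `delivered_reward_level`.
#'
#' @param trials Trial table from [generate_trial_schedule()].
#' @param config The matching [task_config()].
#' @param params Behavioural parameter table (see [default_behav_params()]).
#' @param seed Optional integer seed.
#' @return `trials` with `outcome`, `rt_s` (defined only for responses),
#'   `change_at_salient`, and `delivered_reward_level` columns.
#' @export
simulate_behavior <- function(trials, config,
                              params = default_behav_params(config$paradigm),
                              seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  assert_prob(params$p_respond, "response probability")
  rw <- config$response_window
  if (any(params$rt_mean_s < rw[1] | params$rt_mean_s > rw[2])) {
    stop("rt_mean_s outside the legal response window")
  }
  with_seed(seed, {
    n <- nrow(trials)
    outcome <- character(n)
    rt <- rep(NA_real_, n)
    # salience of the changed stimulus; ties (LV == RV) count as salient
    chg_val <- ifelse(trials$change_side == "left",
                      trials$left_value, trials$right_value)
    oth_val <- ifelse(trials$change_side == "left",
                      trials$right_value, trials$left_value)
    salient <- trials$is_single_stimulus | (chg_val >= oth_val)
    # distractor-only trials: the changed stimulus is the distractor
    if (config$paradigm == "G") {
      d_only <- trials$trial_type == "distractor_only"
      dv <- ifelse(trials$cue_side == "left", trials$left_value,
                   trials$right_value)
      ov <- ifelse(trials$cue_side == "left", trials$right_value,
                   trials$left_value)
      salient[d_only] <- (dv >= ov)[d_only]
    }

    draw_rt <- function(cell) rtruncnorm(1, cell$rt_mean_s, cell$rt_sd_s,
                                         rw[1], rw[2])
    for (i in seq_len(n)) {
      tt <- trials$trial_type[i]
      if (config$paradigm == "D" || tt == "target") {
        cell <- lookup_cell(params, tt, salient[i])
        if (stats::runif(1) < cell$p_respond) {
          outcome[i] <- "hit"; rt[i] <- draw_rt(cell)
        } else outcome[i] <- "miss"
      } else if (tt == "distractor_only") {
        cell <- lookup_cell(params, "distractor", salient[i])
        if (stats::runif(1) < cell$p_respond) {
          outcome[i] <- "false_alarm"; rt[i] <- draw_rt(cell)
        } else outcome[i] <- "correct_rejection"
      } else { # distractor_target: distractor response resolved first
        dcell <- lookup_cell(params, "distractor", salient[i])
        if (stats::runif(1) < dcell$p_respond) {
          outcome[i] <- "false_alarm"; rt[i] <- draw_rt(dcell)
        } else {
          tcell <- lookup_cell(params, "distractor_target", salient[i])
          if (stats::runif(1) < tcell$p_respond) {
            outcome[i] <- "hit"; rt[i] <- draw_rt(tcell)
          } else outcome[i] <- "miss"
        }
      }
    }
    # a false alarm ends the trial before the target change is displayed
    fa_dt <- outcome == "false_alarm" & trials$trial_type == "distractor_target"
    trials$change_latency_s[fa_dt] <- NA_real_
    correct <- outcome == "hit" | outcome == "correct_rejection"
    pick_left <- stats::runif(n) < 0.5
    lv <- trials$left_value; rv <- trials$right_value
    lv[is.na(lv)] <- rv[is.na(lv)]; rv[is.na(rv)] <- lv[is.na(rv)]
    delivered <- ifelse(pick_left, lv, rv)
    trials$outcome <- outcome
    trials$rt_s <- rt
    trials$change_at_salient <- salient
    trials$delivered_reward_level <- ifelse(correct, delivered, NA_real_)
    trials
  })
}
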