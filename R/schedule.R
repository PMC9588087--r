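#' Generate a trial schedule
#'
#' Draws a randomized trial table for either paradigm: counterbalanced frame
#' (cue) sides, stimulus values sampled uniformly over the 5 x 5 level grid,
#' trial types per the paradigm's fractions, a configurable fraction of
#' single-stimulus trials, and truncated-exponential change latencies.
#'
#' The frame appears on the side opposite the cued location, so `cue_side`
#' records the frame side and `cued_side` its opposite. In
#' distractor+target trials the target latency is drawn conditional on
#' exceeding the distractor latency (the distractor changes first).
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials (> 0).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A `data.frame` with one row per trial: `trial_id`,
#'   `is_single_stimulus`, `cue_side` (frame side), `cued_side`,
#'   `trial_type`, `left_value`, `right_value`, `change_side`,
#'   `change_latency_s`, `distractor_latency_s` and the derived value
#'   regressors from [derive_regressors()].
#' @export
generate_trial_schedule <- function(config, n_trials, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (n_trials <= 0) stop("n_trials must be positive")
  with_seed(seed, {
    n <- as.integer(n_trials)
    sides <- rep(c("left", "right"), length.out = n)
    cue_side <- sample(sides)             # frame side, counterbalanced
    cued_side <- ifelse(cue_side == "left", "right", "left")
    is_single <- stats::runif(n) < config$p_single

    lv <- sample(config$value_levels, n, replace = TRUE)
    rv <- sample(config$value_levels, n, replace = TRUE)

    if (config$paradigm == "D") {
      trial_type <- ifelse(stats::runif(n) < config$p_valid, "valid", "invalid")
      trial_type[is_single] <- "valid"    # single-stimulus cue always valid
      change_side <- ifelse(trial_type == "valid", cued_side, cue_side)
      lat <- config$latency$target
      change_latency <- sample_change_latency(n, lat$tau_s, lat$cutoff_s, lat$offset_s)
      distractor_latency <- rep(NA_real_, n)
    } else {
      u <- stats::runif(n)
      trial_type <- ifelse(u < config$p_target, "target",
                    ifelse(u < config$p_target + config$p_distractor_only,
                           "distractor_only", "distractor_target"))
      trial_type[is_single] <- "target"
      lt <- config$latency$target
      ld <- config$latency$distractor
      change_latency <- sample_change_latency(n, lt$tau_s, lt$cutoff_s, lt$offset_s)
      distractor_latency <- rep(NA_real_, n)
      dis <- trial_type %in% c("distractor_only", "distractor_target")
      distractor_latency[dis] <-
        sample_change_latency(sum(dis), ld$tau_s, ld$cutoff_s, ld$offset_s)
      # the target change, when present, follows the distractor change
      dt <- which(trial_type == "distractor_target")
      for (i in dt) {
        while (change_latency[i] <= distractor_latency[i]) {
          change_latency[i] <-
            sample_change_latency(1, lt$tau_s, lt$cutoff_s, lt$offset_s)
        }
      }
      change_latency[trial_type == "distractor_only"] <- NA_real_
      change_side <- ifelse(trial_type == "distractor_only",
                            cue_side, cued_side)
    }

    # single-stimulus trials: one stimulus at the cued location
    lv[is_single & cued_side == "right"] <- NA_real_
    rv[is_single & cued_side == "left"] <- NA_real_

    trials <- data.frame(trial_id = seq_len(n),
                         is_single_stimulus = is_single,
                         cue_side = cue_side,
                         cued_side = cued_side,
                         trial_type = trial_type,
                         left_value = lv,
                         right_value = rv,
                         change_side = change_side,
                         change_latency_s = change_latency,
                         distractor_latency_s = distractor_latency,
                         stringsAsFactors = FALSE)
    derive_regressors(trials)
  })
}

#' Derive value regressors from a trial table
#'
#' Pure functions of the stored design fields, double-stimulus trials only
#' (NA elsewhere): cued value `CV` (value at the side opposite the frame),
#' un-cued value `UCV`, salient value `SV = max(LV, RV)`, non-salient value
#' `NSV = min(LV, RV)`, total value `TV`, the differences `LV - RV`,
#' `CV - UCV`, `SV - NSV`, the signed attention-cue location `att_cue_loc`
#' (-1 left frame, +1 right frame), and `V_sin` for single-stimulus trials.
#'
#' @param trials Trial table with `left_value`, `right_value`, `cue_side`,
#'   `cued_side`, `is_single_stimulus`.
#' @return `trials` with regressor columns appended/overwritten.
#' @export
derive_regressors <- function(trials) {
  lv <- trials$left_value
  rv <- trials$right_value
  dbl <- !trials$is_single_stimulus
  cued_left <- trials$cued_side == "left"

  cv <- ifelse(cued_left, lv, rv)
  ucv <- ifelse(cued_left, rv, lv)
  trials$CV <- ifelse(dbl, cv, NA_real_)
  trials$UCV <- ifelse(dbl, ucv, NA_real_)
  trials$SV <- ifelse(dbl, pmax(lv, rv), NA_real_)
  trials$NSV <- ifelse(dbl, pmin(lv, rv), NA_real_)
  trials$TV <- ifelse(dbl, lv + rv, NA_real_)
  trials$LV_minus_RV <- ifelse(dbl, lv - rv, NA_real_)
  trials$CV_minus_UCV <- ifelse(dbl, cv - ucv, NA_real_)
  trials$SV_minus_NSV <- ifelse(dbl, trials$SV - trials$NSV, NA_real_)
  trials$att_cue_loc <- ifelse(trials$cue_side == "right", 1, -1)
  trials$V_sin <- ifelse(dbl, NA_real_, ifelse(cued_left, lv, rv))
  # side of the higher-valued (salient) stimulus; ties count as salient on
  # both sides and are assigned to the changed side downstream
  trials$salient_side <- ifelse(dbl,
                                ifelse(lv >= rv, "left", "right"),
                                trials$cued_side)
  trials
}

#' Per-trial event times
#'
#' Expands a trial schedule into absolute event times (s from trial start)
#' using the configuration's timing constants. `change_on` is stimulus onset
#' plus the drawn latency; `trial_end` is 0.6 s after the last scheduled
#' change (or after the distractor change in distractor-only trials).
#'
#' @param trials Trial table from [generate_trial_schedule()].
#' @param config The [task_config()] used to generate it.
#' @return Wide `data.frame`: `trial_id`, `fix_on`, `sacc_target_on`,
#'   `cue_on`, `stim_on`, `cue_off`, `change_on`, `distractor_change_on`,
#'   `trial_end` (s). `response` is added by [simulate_behavior()].
#' @export
trial_events <- function(trials, config) {
  tm <- config$timing
  n <- nrow(trials)
  change_on <- tm$stim_on + trials$change_latency_s
  dis_on <- tm$stim_on + trials$distractor_latency_s
  last <- pmax(change_on, dis_on, na.rm = TRUE)
  last[is.na(last)] <- tm$stim_on + 0.4
  response <- rep(NA_real_, n)
  if (!is.null(trials$rt_s)) {
    # false alarms time-lock to the distractor's change
    anchor <- ifelse(!is.na(trials$outcome) & trials$outcome == "false_alarm" &
                       !is.na(dis_on), dis_on, change_on)
    response <- anchor + trials$rt_s
  }
  data.frame(trial_id = trials$trial_id,
             fix_on = rep(tm$fix_on, n),
             sacc_target_on = rep(tm$sacc_target_on, n),
             cue_on = rep(tm$cue_on, n),
             stim_on = rep(tm$stim_on, n),
             cue_off = rep(tm$cue_off, n),
             change_on = change_on,
             distractor_change_on = dis_on,
             response = response,
             trial_end = last + 0.6)
}
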