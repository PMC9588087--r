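#' Task configuration for the reward-salience cueing paradigms
#'
#' Encodes the two detection-task variants. In paradigm `"D"` a frame cue is
#' valid on a fraction `p_valid` of trials (the luminance change occurs on the
#' side opposite the frame, i.e. the cued side). In paradigm `"G"` the subject
#' must respond only to changes at the cued location (`target` trials) and
#' ignore changes at the un-cued location; distractor-only and
#' distractor+target trials each make up half of the remaining trials.
#'
#' Change latencies (measured from stimulus onset) follow a truncated
#' exponential plus a fixed offset; see [sample_change_latency()].
#'
#' @param paradigm `"D"` (valid/invalid cueing) or `"G"`
#'   (target/distractor cueing).
#' @param value_levels Ordered reward levels used as regressor codes. The
#'   lowest stimulus (one small drop) codes as 0.
#' @param reward_volumes_ml Juice volume (ml) for each level.
#' @param p_valid Fraction of valid-cue trials (paradigm D).
#' @param p_target,p_distractor_only,p_distractor_target Trial-type fractions
#'   (paradigm G); must sum to 1.
#' @param p_single Fraction of single-stimulus trials (defaults: 0.071 for D,
#'   0.101 for G).
#' @param latency Named list of latency parameter triplets
#'   `list(tau_s=, cutoff_s=, offset_s=)` for `target` and (G) `distractor`
#'   changes.
#' @param timing Event times (s, from trial start): fixation onset, saccade
#'   target onset (+0.5 s), cue onset (+0.5 s), stimulus onset (+0.2 s), cue
#'   offset (0.2 s after stimulus onset).
#' @param response_window Legal response interval after a luminance change, s.
#' @return An object of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config("D")
#' cfg$latency$target$tau_s
task_config <- function(paradigm = c("D", "G"),
                        value_levels = c(0, 1, 2, 4, 8),
                        reward_volumes_ml = c(0.033, 0.10, 0.16, 0.29, 0.55),
                        p_valid = 0.90,
                        p_target = 0.80,
                        p_distractor_only = 0.10,
                        p_distractor_target = 0.10,
                        p_single = NULL,
                        latency = NULL,
                        timing = list(fix_on = 0, sacc_target_on = 0.5,
                                      cue_on = 1.0, stim_on = 1.2,
                                      cue_off = 1.4),
                        response_window = c(0.1, 0.4)) {
  paradigm <- match.arg(paradigm)
  if (is.null(p_single)) p_single <- if (paradigm == "D") 0.071 else 0.101
  if (is.null(latency)) {
    latency <- if (paradigm == "D") {
      list(target = list(tau_s = 2.5, cutoff_s = 1.4, offset_s = 0.4))
    } else {
      list(target = list(tau_s = 2.5, cutoff_s = 1.9, offset_s = 0.4),
           distractor = list(tau_s = 1.25, cutoff_s = 1.9, offset_s = 0.4))
    }
  }

  if (any(diff(value_levels) <= 0)) stop("value_levels must be strictly increasing")
  if (value_levels[1] != 0) stop("lowest value level must code as 0")
  stopifnot(length(reward_volumes_ml) == length(value_levels))
  assert_prob(c(p_valid, p_single), "trial-type fraction")
  if (paradigm == "G") {
    fr <- c(p_target, p_distractor_only, p_distractor_target)
    assert_prob(fr, "trial-type fraction")
    if (abs(sum(fr) - 1) > 1e-9) stop("paradigm G trial-type fractions must sum to 1")
  }
  for (l in latency) {
    if (l$tau_s <= 0 || l$cutoff_s <= 0 || l$offset_s < 0) {
      stop("latency parameters must be positive (tau, cutoff) and offset >= 0")
    }
  }
  tm <- unlist(timing)
  if (any(diff(tm[c("fix_on", "sacc_target_on", "cue_on", "stim_on", "cue_off")]) <= 0)) {
    stop("event timing must be strictly increasing")
  }
  if (response_window[2] <= response_window[1] || response_window[1] < 0) {
    stop("response window must be a positive-length interval")
  }

  structure(list(paradigm = paradigm,
                 value_levels = value_levels,
                 reward_volumes_ml = stats::setNames(reward_volumes_ml,
                                                     value_levels),
                 p_valid = p_valid,
                 p_target = p_target,
                 p_distractor_only = p_distractor_only,
                 p_distractor_target = p_distractor_target,
                 p_single = p_single,
                 latency = latency,
                 timing = timing,
                 response_window = response_window),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config paradigm=%s, levels={%s}>\n", x$paradigm,
              paste(x$value_levels, collapse = ",")))
  invisible(x)
}
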