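#' Write a session bundle
#'
#' Serializes a session to the plain-text bundle layout: `trials.csv`,
#' `events.csv` (long: trial_id, event, time_s), `spikes.csv` (sorted by
#' neuron, trial, time), `session.json` (paradigm, config echo, format
#' version) and, for synthetic sessions, `ground_truth.json`. Times are in
#' seconds relative to trial start; nulls are written as `NA`.
#'
#' @param session A `synthetic_session` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  ev <- session$events
  long <- stats::reshape(ev, direction = "long",
                         varying = setdiff(names(ev), "trial_id"),
                         v.names = "time_s", timevar = "event",
                         times = setdiff(names(ev), "trial_id"),
                         idvar = "trial_id")
  long <- long[!is.na(long$time_s), c("trial_id", "event", "time_s")]
  long <- long[order(long$trial_id, long$time_s), ]
  utils::write.csv(long, file.path(dir, "events.csv"), row.names = FALSE)
  sp <- session$spikes[order(session$spikes$neuron_id,
                             session$spikes$trial_id,
                             session$spikes$spike_time_s), ]
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  cfg <- session$config
  meta <- list(format_version = "1.0",
               paradigm = cfg$paradigm,
               value_levels = cfg$value_levels,
               p_valid = cfg$p_valid,
               p_single = cfg$p_single,
               timing = cfg$timing,
               response_window = cfg$response_window)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(session$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read and validate a session bundle
#'
#' Loads the bundle written by [write_session_bundle()], validates
#' referential integrity (every spike and event references an existing
#' trial, non-negative times, spikes sorted within neuron/trial), and
#' flags neurons failing the inclusion rules (at least `min_trials`
#' valid-cue/target trials and a mean rate of at least `min_rate_hz`)
#' without dropping them.
#'
#' @param dir Bundle directory.
#' @param min_trials,min_rate_hz Inclusion rules used for flagging.
#' @return List: `trials`, `events` (wide), `spikes`, `config` (metadata
#'   echo), `neurons` (with `included` flag and exclusion reason),
#'   `ground_truth` (if present).
#' @export
read_session_bundle <- function(dir, min_trials = 100, min_rate_hz = 1) {
  need <- c("trials.csv", "events.csv", "spikes.csv", "session.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) stop("missing bundle files: ",
                            paste(missing, collapse = ", "))
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  long <- utils::read.csv(file.path(dir, "events.csv"),
                          stringsAsFactors = FALSE)
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"),
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)

  for (col in c("trial_id", "event", "time_s")) {
    if (!col %in% names(long)) stop("events.csv missing column: ", col)
  }
  for (col in c("neuron_id", "trial_id", "spike_time_s")) {
    if (!col %in% names(spikes)) stop("spikes.csv missing column: ", col)
  }
  bad <- which(!spikes$trial_id %in% trials$trial_id)
  if (length(bad)) stop(sprintf("spikes.csv row %d references unknown trial %s",
                                bad[1], spikes$trial_id[bad[1]]))
  bad <- which(!long$trial_id %in% trials$trial_id)
  if (length(bad)) stop(sprintf("events.csv row %d references unknown trial %s",
                                bad[1], long$trial_id[bad[1]]))
  if (any(spikes$spike_time_s < 0) || any(long$time_s < 0)) {
    stop("negative event or spike times")
  }
  o <- order(spikes$neuron_id, spikes$trial_id, spikes$spike_time_s)
  if (is.unsorted(o)) spikes <- spikes[o, ]

  events <- stats::reshape(long, direction = "wide", idvar = "trial_id",
                           timevar = "event", v.names = "time_s")
  names(events) <- sub("^time_s\\.", "", names(events))
  events <- events[order(events$trial_id), ]
  for (col in c("distractor_change_on", "response")) {
    if (!col %in% names(events)) events[[col]] <- NA_real_
  }

  # inclusion flags: valid-cue (target) trial count and mean response rate
  vt <- trials$trial_id[trials$trial_type %in% c("valid", "target")]
  dur <- events$trial_end[match(spikes$trial_id, events$trial_id)]
  ids <- unique(spikes$neuron_id)
  n_valid <- vapply(ids, function(id) {
    length(unique(spikes$trial_id[spikes$neuron_id == id &
                                    spikes$trial_id %in% vt]))
  }, numeric(1))
  total_dur <- sum(events$trial_end)
  rate <- vapply(ids, function(id) {
    sum(spikes$neuron_id == id) / total_dur
  }, numeric(1))
  area <- if ("area" %in% names(spikes)) {
    spikes$area[match(ids, spikes$neuron_id)]
  } else NA_character_
  neurons <- data.frame(neuron_id = ids, area = area,
                        n_valid_trials = n_valid, mean_rate_hz = rate,
                        included = n_valid >= min_trials & rate >= min_rate_hz,
                        reason = ifelse(n_valid < min_trials, "too_few_trials",
                                 ifelse(rate < min_rate_hz, "low_rate", "")),
                        row.names = NULL, stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path,
                                                      simplifyVector = TRUE)
        else NULL
  list(trials = trials, events = events, spikes = spikes, config = meta,
       neurons = neurons, ground_truth = gt)
}

#' Write a run manifest
#'
#' Records the package version, seed, parameters and MD5 hashes of the
#' input and output files so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param seed Seed used.
#' @param params Named list of run parameters.
#' @param files Character vector of files to hash.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, params = list(), files = character()) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "attnvalue",
    version = as.character(utils::packageVersion("attnvalue")),
    seed = seed,
    params = params,
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
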