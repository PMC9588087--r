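#' Trial grouping factors for population-response plots
#'
#' Standard groupings used to visualize value coding: `"same_pair"` keeps
#' only trials where the two stimuli carry the same reward (group label is
#' that value, 5 groups); `"sv"`, `"nsv"`, `"cv"`, `"ucv"` group all
#' double-stimulus trials by the corresponding value regressor;
#' `"salient8_attention"` keeps trials whose salient stimulus is worth 8
#' drops and contrasts attention toward vs away from it (label
#' `toward_<NSV>` / `away_<NSV>` by the other stimulus's value).
#'
#' @param trials Trial table with derived regressors.
#' @param type Grouping name.
#' @return Factor of group labels, `NA` for excluded trials.
#' @export
trial_grouping <- function(trials, type = c("same_pair", "sv", "nsv", "cv",
                                            "ucv", "salient8_attention")) {
  type <- match.arg(type)
  dbl <- !trials$is_single_stimulus
  g <- rep(NA_character_, nrow(trials))
  if (type == "same_pair") {
    sel <- dbl & trials$left_value == trials$right_value
    g[sel] <- as.character(trials$left_value[sel])
  } else if (type %in% c("sv", "nsv", "cv", "ucv")) {
    v <- trials[[toupper(type)]]
    g[dbl] <- as.character(v[dbl])
  } else {
    sel <- dbl & trials$SV == 8
    toward <- trials$cued_side == trials$salient_side
    g[sel] <- paste0(ifelse(toward[sel], "toward_", "away_"),
                     trials$NSV[sel])
  }
  factor(g)
}

#' Grouped population response traces and epoch means
#'
#' For each neuron, averages its rate over the trials of each group, then
#' reports the across-neuron mean and SEM per group: time courses on both
#' alignments (consecutive 25-ms bins) and epoch means. Neurons with an
#' empty group are omitted from that group.
#'
#' @param session Session list.
#' @param grouping Factor over rows of `session$trials`
#'   (see [trial_grouping()]), `NA` excluded.
#' @param neuron_ids Neurons to include (e.g. a tuning-class subpopulation);
#'   default all.
#' @param epoch Epoch for the scalar means (default `"stimulus_period"`).
#' @param bin_s Trace resolution (s).
#' @param stim_window,change_window Aligned trace windows (s).
#' @return List: `traces` (alignment, center, group, mean, sem, n_neurons),
#'   `epoch_means` (group, mean, sem, n_neurons), `per_neuron_epoch`
#'   (neuron x group matrix of epoch means).
#' @export
grouped_population_response <- function(session, grouping,
                                        neuron_ids = NULL,
                                        epoch = "stimulus_period",
                                        bin_s = 0.025,
                                        stim_window = c(-0.4, 0.6),
                                        change_window = c(-0.4, 0.4)) {
  trials <- session$trials
  stopifnot(length(grouping) == nrow(trials))
  correct <- trials$outcome %in% c("hit", "correct_rejection")
  use <- correct & !is.na(grouping)
  tr <- trials[use, ]
  grp <- droplevels(grouping[use])
  if (is.null(neuron_ids)) neuron_ids <- unique(session$spikes$neuron_id)

  er <- epoch_rates(session$spikes, session$events, tr$trial_id,
                    neuron_ids)[[epoch]]
  has_change <- !is.na(tr$change_latency_s)
  stim <- bin_rates(session$spikes, session$events, tr$trial_id, neuron_ids,
                    "stim_on", stim_window, bin_s)
  change <- bin_rates(session$spikes, session$events,
                      tr$trial_id[has_change], neuron_ids,
                      "change_on", change_window, bin_s)

  lev <- levels(grp)
  per_neuron <- matrix(NA_real_, length(neuron_ids), length(lev),
                       dimnames = list(neuron_ids, lev))
  traces <- list()
  for (gi in seq_along(lev)) {
    rows <- which(grp == lev[gi])
    rows_chg <- match(intersect(tr$trial_id[rows],
                                change$trial_ids), change$trial_ids)
    for (tensor_info in list(list(stim, rows, "stim_on"),
                             list(change, rows_chg, "change_on"))) {
      tensor <- tensor_info[[1]]; rws <- tensor_info[[2]]
      if (!length(rws)) next
      pn <- apply(tensor$values[rws, , , drop = FALSE], c(2, 3), mean)
      traces[[length(traces) + 1]] <- data.frame(
        alignment = tensor_info[[3]], center = tensor$centers,
        group = lev[gi],
        mean = rowMeans(pn), sem = apply(pn, 1, stats::sd) / sqrt(ncol(pn)),
        n_neurons = ncol(pn), stringsAsFactors = FALSE)
    }
    e <- er[rows, , drop = FALSE]
    per_neuron[, gi] <- colMeans(e, na.rm = TRUE)
  }
  ok <- !is.nan(per_neuron)
  em <- data.frame(group = lev,
                   mean = colMeans(per_neuron, na.rm = TRUE),
                   sem = apply(per_neuron, 2, function(v)
                     stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
                   n_neurons = colSums(ok), row.names = NULL)
  list(traces = do.call(rbind, traces), epoch_means = em,
       per_neuron_epoch = per_neuron)
}

#' Additive two-way ANOVA on grouped epoch responses
#'
#' Main-effect F statistics for an additive two-factor model (no
#' interaction), using type-II sums of squares: each factor's SS is the
#' SSE drop from adding it to the model already containing the other
#' factor, tested against the full additive model's residual mean square.
#'
#' @param df Data with a numeric response and two factor columns.
#' @param response,factor_a,factor_b Column names.
#' @return `data.frame(term, df, sum_sq, f, p)` plus a `residual` row.
#' @export
two_way_anova <- function(df, response = "response", factor_a = "group",
                          factor_b = "value") {
  d <- data.frame(y = df[[response]],
                  a = factor(df[[factor_a]]), b = factor(df[[factor_b]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(d$a) < 2 || nlevels(d$b) < 2) stop("both factors need >= 2 levels")
  full <- stats::lm(y ~ a + b, data = d)
  dr <- stats::drop1(full, test = "F")          # type-II SS for additive model
  res_df <- full$df.residual
  res_ss <- sum(stats::residuals(full)^2)
  out <- data.frame(term = c(factor_a, factor_b, "residual"),
                    df = c(dr$Df[-1], res_df),
                    sum_sq = c(dr$`Sum of Sq`[-1], res_ss),
                    f = c(dr$`F value`[-1], NA),
                    p = c(dr$`Pr(>F)`[-1], NA),
                    row.names = NULL)
  out
}
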