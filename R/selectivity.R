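#' Task variables screened for single-neuron selectivity
#' @keywords internal
value_variables <- function() {
  c("LV", "RV", "LV_minus_RV", "CV", "UCV", "CV_minus_UCV",
    "SV", "NSV", "SV_minus_NSV", "TV")
}

#' Single-neuron selectivity screen
#'
#' One simple linear regression (rate on variable) per neuron, per task
#' variable, per epoch, with a two-sided t-test on the slope. Double-
#' stimulus correct trials enter the value-variable regressions; single-
#' stimulus correct trials enter the `V_sin` regression. A neuron is
#' selective to a variable at `p < p_thresh` (default 0.005); a neuron is
#' value-selective if selective to any value variable in any epoch.
#'
#' @param rates Named list of trials x neurons epoch-rate matrices
#'   ([epoch_rates()]), rows matching `trials`.
#' @param trials Trial table with derived regressors and outcomes.
#' @param epochs Epoch names to screen (default the three task epochs).
#' @param p_thresh Selectivity threshold on the slope p-value.
#' @return A `selectivity_result`: list with `table` (neuron x variable x
#'   epoch long data.frame: `beta0`, `beta1`, `t`, `p`, `selective`) and
#'   `tuning` (per neuron: class `positive`, `negative`, `contradictory`,
#'   or `none`, plus `value_selective`).
#' @export
selectivity_screen <- function(rates, trials,
                               epochs = c("cue_stimulus", "early_stimulus",
                                          "late_stimulus"),
                               p_thresh = 0.005) {
  correct <- trials$outcome %in% c("hit", "correct_rejection")
  dbl <- correct & !trials$is_single_stimulus
  sgl <- correct & trials$is_single_stimulus
  vars <- value_variables()
  res <- list()
  for (ep in epochs) {
    R <- rates[[ep]]
    if (is.null(R)) stop("missing epoch rates: ", ep)
    for (v in c(vars, "att_cue_loc", "V_sin")) {
      rows <- if (v == "V_sin") sgl else dbl
      x <- trials[[v]]
      use <- rows & !is.na(x) & !is.na(R[, 1])
      if (sum(use) < 5 || stats::sd(x[use]) == 0) next
      fit <- slope_tests(x[use], R[use, , drop = FALSE])
      res[[length(res) + 1]] <- data.frame(
        neuron_id = colnames(R), variable = v, epoch = ep,
        beta0 = fit$b0, beta1 = fit$b1, t = fit$t, p = fit$p,
        selective = fit$p < p_thresh, row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, res)
  tuning <- classify_tuning(tab, vars)
  structure(list(table = tab, tuning = tuning, p_thresh = p_thresh),
            class = "selectivity_result")
}

#' Vectorized simple-regression slope t-tests (one x, many y columns)
#' @keywords internal
slope_tests <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ybar <- colMeans(Y)
  b1 <- drop(crossprod(xc, Y)) / sxx
  b0 <- ybar - b1 * mean(x)
  Yc <- sweep(Y, 2, ybar)
  sse <- pmax(colSums(Yc^2) - b1^2 * sxx, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  tval <- ifelse(se > 0, b1 / se, 0)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(b0 = b0, b1 = b1, t = tval, p = p)
}

#' Classify value tuning from a selectivity table
#'
#' Positive (negative) tuning requires sign-consistent significant slopes
#' across value variables and epochs; significant slopes of opposite signs
#' mark the neuron contradictory, and it is excluded from tuned groups.
#'
#' @param tab Long selectivity table.
#' @param vars Value-variable names.
#' @return Per-neuron data.frame with `tuning_class` and `value_selective`.
#' @keywords internal
classify_tuning <- function(tab, vars = value_variables()) {
  vt <- tab[tab$variable %in% vars, ]
  ids <- unique(tab$neuron_id)
  cls <- vapply(ids, function(id) {
    sub <- vt[vt$neuron_id == id & vt$selective, ]
    if (!nrow(sub)) return("none")
    pos <- any(sub$beta1 > 0)
    neg <- any(sub$beta1 < 0)
    if (pos && neg) "contradictory" else if (pos) "positive" else "negative"
  }, character(1))
  data.frame(neuron_id = ids, tuning_class = cls,
             value_selective = cls != "none", row.names = NULL,
             stringsAsFactors = FALSE)
}
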