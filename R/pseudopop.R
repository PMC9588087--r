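#' Prepare a session for pseudo-population decoding
#'
#' Selects eligible trials (correct, double-stimulus, cue-valid/target
#' trials with a luminance change), bins both alignment windows at the raw
#' resolution, z-scores each neuron across all trials and time points of
#' both windows, smooths, window-averages into the decoding windows, and
#' concatenates the two alignments along time.
#'
#' @param session A `synthetic_session` or the list returned by
#'   [read_session_bundle()].
#' @param stim_window,change_window Alignment windows (s) around stimulus
#'   onset and luminance change.
#' @param raw_bin_s Raw bin width before smoothing (s).
#' @param decode_bin_s,step_s Sliding decode window and step (s).
#' @param sigma_s,smooth_window_s Gaussian smoothing parameters (s).
#' @param min_trials Minimum trials per cue side for a neuron to enter.
#' @return A `decode_input`: list with `values` (trials x bins x neurons),
#'   `bins` (data.frame `center`, `alignment`), `labels` (cue side),
#'   `rts`, `trial_ids`, `neuron_ids`.
#' @export
prepare_decoding <- function(session,
                             stim_window = c(-0.4, 0.6),
                             change_window = c(-0.4, 0.4),
                             raw_bin_s = 0.005,
                             decode_bin_s = 0.025, step_s = 0.010,
                             sigma_s = 0.05, smooth_window_s = 0.1,
                             min_trials = 100) {
  trials <- session$trials
  ok <- trials$outcome == "hit" & !trials$is_single_stimulus &
    trials$trial_type %in% c("valid", "target", "distractor_target")
  tr <- trials[ok, ]
  neuron_ids <- unique(session$spikes$neuron_id)

  per_class <- table(tr$cue_side)
  if (length(per_class) < 2) stop("need trials from both cue sides")

  stim <- bin_rates(session$spikes, session$events, tr$trial_id, neuron_ids,
                    "stim_on", stim_window, raw_bin_s)
  change <- bin_rates(session$spikes, session$events, tr$trial_id, neuron_ids,
                      "change_on", change_window, raw_bin_s)
  tr <- tr[match(stim$trial_ids, tr$trial_id), ]
  zs <- zscore_and_smooth(stim, change, sigma_s, smooth_window_s)
  ws <- window_average(zs$stim, decode_bin_s, step_s)
  wc <- window_average(zs$change, decode_bin_s, step_s)
  values <- array(NA_real_, c(dim(ws$values)[1],
                              dim(ws$values)[2] + dim(wc$values)[2],
                              dim(ws$values)[3]))
  values[, seq_len(dim(ws$values)[2]), ] <- ws$values
  values[, dim(ws$values)[2] + seq_len(dim(wc$values)[2]), ] <- wc$values
  bins <- data.frame(
    center = c(ws$centers, wc$centers),
    alignment = rep(c("stim_on", "change_on"),
                    c(length(ws$centers), length(wc$centers))),
    stringsAsFactors = FALSE)
  structure(list(values = values, bins = bins,
                 labels = tr$cue_side, rts = tr$rt_s,
                 trial_ids = tr$trial_id, neuron_ids = ws$neuron_ids,
                 min_trials = min_trials),
            class = "decode_input")
}

#' Assemble a balanced pseudo-population ensemble
#'
#' For each neuron independently, samples `n_per_class` trials without
#' replacement from each cue-side condition; pseudo-trial m pairs the m-th
#' sampled trial of every neuron within a class. Neurons with fewer than
#' `min_trials` trials in either condition are excluded (error if none
#' remain).
#'
#' @param input A `decode_input` from [prepare_decoding()].
#' @param n_per_class Trials sampled per class per neuron.
#' @param min_trials Inclusion threshold per class (defaults to
#'   `n_per_class`).
#' @param trial_subset Optional logical/index vector restricting the trials
#'   each neuron may sample from (e.g. an RT split half).
#' @return A `pseudo_ensemble`: list with `X` (M x bins x neurons),
#'   `labels` (length M), `bins`, `sampled` (trial-row matrix M x neurons).
#' @export
build_pseudo_population <- function(input, n_per_class = 100,
                                    min_trials = n_per_class,
                                    trial_subset = NULL) {
  labels <- input$labels
  rows <- seq_along(labels)
  if (!is.null(trial_subset)) rows <- rows[trial_subset[rows]]
  left <- rows[labels[rows] == "left"]
  right <- rows[labels[rows] == "right"]
  if (length(left) < min_trials || length(right) < min_trials) {
    stop(sprintf("fewer than %d trials in a cue condition (%d left, %d right)",
                 min_trials, length(left), length(right)))
  }
  if (length(left) < n_per_class || length(right) < n_per_class) {
    stop("n_per_class exceeds available trials")
  }
  n_nu <- length(input$neuron_ids)
  M <- 2L * n_per_class
  X <- array(NA_real_, c(M, nrow(input$bins), n_nu))
  sampled <- matrix(NA_integer_, M, n_nu)
  for (n in seq_len(n_nu)) {
    li <- sample(left, n_per_class)
    ri <- sample(right, n_per_class)
    X[seq_len(n_per_class), , n] <- input$values[li, , n]
    X[n_per_class + seq_len(n_per_class), , n] <- input$values[ri, , n]
    sampled[, n] <- c(li, ri)
  }
  structure(list(X = X,
                 labels = rep(c("left", "right"), each = n_per_class),
                 bins = input$bins, sampled = sampled,
                 neuron_ids = input$neuron_ids),
            class = "pseudo_ensemble")
}

#' Principal-component reduction of a pseudo-ensemble
#'
#' `mode = "per_bin"` runs an independent PCA on the neuron dimension at
#' each time bin; `mode = "joint"` runs one PCA on the `MT x N` unfolding so
#' every bin shares the same subspace. In both modes the retained dimension
#' is the smallest count whose cumulative explained variance reaches
#' `var_threshold`.
#'
#' @param ensemble A `pseudo_ensemble`.
#' @param mode `"per_bin"` or `"joint"`.
#' @param var_threshold Cumulative variance threshold in (0, 1].
#' @return The ensemble with `scores` added: for `per_bin` a list of M x P_t
#'   score matrices; for `joint` an M x T x Q array plus `loadings`,
#'   `center`.
#' @export
pca_reduce <- function(ensemble, mode = c("per_bin", "joint"),
                       var_threshold = 0.70) {
  mode <- match.arg(mode)
  if (var_threshold <= 0 || var_threshold > 1) {
    stop("var_threshold must be in (0, 1]")
  }
  X <- ensemble$X
  M <- dim(X)[1]; T_ <- dim(X)[2]; N <- dim(X)[3]
  if (mode == "per_bin") {
    scores <- vector("list", T_)
    dims <- integer(T_)
    for (t in seq_len(T_)) {
      A <- X[, t, , drop = TRUE]
      dim(A) <- c(M, N)
      A <- sweep(A, 2, colMeans(A))
      sv <- svd(A, nu = min(M, N), nv = 0)
      p <- n_components(sv$d, var_threshold)
      scores[[t]] <- sv$u[, seq_len(p), drop = FALSE] *
        rep(sv$d[seq_len(p)], each = M)
      dims[t] <- p
    }
    ensemble$scores <- scores
    ensemble$dims <- dims
  } else {
    A <- matrix(aperm(X, c(1, 2, 3)), nrow = M * T_, ncol = N)
    ctr <- colMeans(A)
    A <- sweep(A, 2, ctr)
    sv <- svd(A, nu = 0)
    q <- n_components(sv$d, var_threshold)
    V <- sv$v[, seq_len(q), drop = FALSE]
    S <- A %*% V
    ensemble$scores <- array(S, c(M, T_, q))
    ensemble$loadings <- V
    ensemble$center <- ctr
    ensemble$dims <- q
  }
  ensemble$mode <- mode
  ensemble$var_threshold <- var_threshold
  ensemble
}

#' Number of components reaching a cumulative-variance threshold
#' @param d Singular values.
#' @param threshold Variance fraction in (0, 1].
#' @keywords internal
n_components <- function(d, threshold) {
  v <- d^2
  v <- v / sum(v)
  p <- which(cumsum(v) >= threshold - 1e-12)[1]
  max(1L, p)
}
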