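#' Diagonal (same-time) pseudo-population decoding
#'
#' At every sliding time window, reduces the ensemble with a per-bin PCA
#' and computes exact leave-one-out LDA posteriors for the true cue-side
#' label. The whole procedure is repeated over `n_cv` independently
#' resampled pseudo-ensembles. z-scoring and PCA are label-blind and fitted
#' on the current ensemble; the LDA itself is strictly leave-one-out (set
#' `strict_folds = TRUE` to refit the PCA on every training fold as well).
#'
#' @param input A `decode_input` from [prepare_decoding()].
#' @param n_per_class Trials per cue side per neuron in each ensemble.
#' @param n_cv Number of independent ensemble resamplings.
#' @param var_threshold PCA cumulative-variance threshold.
#' @param seed Integer seed.
#' @param shuffle Permute labels within each ensemble before decoding
#'   (builds the shuffle null).
#' @param strict_folds Refit PCA per training fold (slow; small inputs).
#' @param trial_subset Optional restriction of the sampled trials.
#' @return A `decoding_result`: `posterior` (M x bins x n_cv array of
#'   true-label posteriors), `mean` (per-bin mean), `sem` (across
#'   pseudo-trials), `bins`, and the run settings.
#' @export
decode_diagonal <- function(input, n_per_class = 100, n_cv = 200,
                            var_threshold = 0.70, seed = NULL,
                            shuffle = FALSE, strict_folds = FALSE,
                            trial_subset = NULL) {
  with_seed(seed, {
    T_ <- nrow(input$bins)
    M <- 2L * n_per_class
    post <- array(NA_real_, c(M, T_, n_cv))
    for (r in seq_len(n_cv)) {
      ens <- build_pseudo_population(input, n_per_class,
                                     min_trials = min(input$min_trials,
                                                      n_per_class),
                                     trial_subset = trial_subset)
      labs <- ens$labels
      if (shuffle) labs <- sample(labs)
      if (strict_folds) {
        for (t in seq_len(T_)) {
          A <- matrix(ens$X[, t, ], nrow = M)
          post[, t, r] <- pca_lda_loocv_strict(A, labs, var_threshold)
        }
      } else {
        ens <- pca_reduce(ens, "per_bin", var_threshold)
        for (t in seq_len(T_)) {
          post[, t, r] <- lda_loocv(ens$scores[[t]], labs)$posterior_true
        }
      }
    }
    per_trial <- apply(post, c(1, 2), mean)   # M x T, averaged over repeats
    structure(list(posterior = post,
                   per_trial = per_trial,
                   mean = colMeans(per_trial),
                   sem = apply(per_trial, 2, stats::sd) / sqrt(M),
                   bins = input$bins,
                   settings = list(n_per_class = n_per_class, n_cv = n_cv,
                                   var_threshold = var_threshold,
                                   seed = seed, shuffle = shuffle,
                                   mode = "per_bin")),
              class = "decoding_result")
  })
}

#' Cross-temporal pseudo-population decoding
#'
#' Reduces each resampled ensemble with a single joint PCA (one subspace
#' shared by all time bins), trains an LDA at each time bin, and tests it at
#' every bin; entries with train == test use exact leave-one-out. A separate
#' row is computed for a decoder trained on the mean activity in a
#' pre-stimulus window (default 50-200 ms before stimulus onset), whose
#' below-0.5 entries after stimulus onset indicate that the attention
#' location has flipped to the opposite side.
#'
#' @inheritParams decode_diagonal
#' @param prestim_range Window (s, relative to stimulus onset) for the
#'   pre-stimulus-trained decoder.
#' @return A `cross_temporal_result`: `matrix` (train x test mean
#'   true-label posterior, averaged over resamples), `pretrain_mean`,
#'   `pretrain_posterior` (M x bins x n_cv), `bins`, settings.
#' @export
decode_cross_temporal <- function(input, n_per_class = 100, n_cv = 20,
                                  var_threshold = 0.70, seed = NULL,
                                  prestim_range = c(-0.2, -0.05),
                                  shuffle = FALSE) {
  with_seed(seed, {
    T_ <- nrow(input$bins)
    M <- 2L * n_per_class
    cmat <- matrix(0, T_, T_)
    pre_post <- array(NA_real_, c(M, T_, n_cv))
    pre_bins <- which(input$bins$alignment == "stim_on" &
                        input$bins$center >= prestim_range[1] &
                        input$bins$center <= prestim_range[2])
    if (!length(pre_bins)) stop("empty pre-stimulus training window")
    for (r in seq_len(n_cv)) {
      ens <- build_pseudo_population(input, n_per_class,
                                     min_trials = min(input$min_trials,
                                                      n_per_class))
      labs <- ens$labels
      if (shuffle) labs <- sample(labs)
      ens <- pca_reduce(ens, "joint", var_threshold)
      S <- ens$scores                       # M x T x Q
      Q <- dim(S)[3]
      Sflat <- matrix(S, nrow = M * T_, ncol = Q)
      is1 <- labs == levels(as.factor(labs))[1]
      true_post <- function(fit) {
        # logits for every (trial, test-bin) at once
        D <- matrix(Sflat %*% fit$w, M, T_) + fit$c0
        P1 <- stats::plogis(D)
        P1[!is1, ] <- 1 - P1[!is1, ]
        P1
      }
      diag_loo <- vapply(seq_len(T_), function(t) {
        mean(lda_loocv(matrix(S[, t, ], nrow = M), labs)$posterior_true)
      }, numeric(1))
      for (b in seq_len(T_)) {
        fit <- lda_fit(matrix(S[, b, ], nrow = M), labs)
        row <- colMeans(true_post(fit))
        row[b] <- diag_loo[b]               # honest entry on the diagonal
        cmat[b, ] <- cmat[b, ] + row
      }
      pre_feat <- apply(S[, pre_bins, , drop = FALSE], c(1, 3), mean)
      fit <- lda_fit(matrix(pre_feat, nrow = M), labs)
      pre_post[, , r] <- true_post(fit)
    }
    structure(list(matrix = cmat / n_cv,
                   pretrain_posterior = pre_post,
                   pretrain_mean = apply(pre_post, 2, mean),
                   bins = input$bins,
                   settings = list(n_per_class = n_per_class, n_cv = n_cv,
                                   var_threshold = var_threshold,
                                   seed = seed, shuffle = shuffle,
                                   prestim_range = prestim_range,
                                   mode = "joint")),
              class = "cross_temporal_result")
  })
}

#' Shuffle-null significance of decoding posteriors
#'
#' Per-bin two-tailed paired t-tests of true-label posteriors against the
#' shuffled-label posteriors (paired by pseudo-trial index, repeats
#' averaged), with Benjamini-Hochberg FDR across bins. Above-null and
#' below-null bins are reported as separate masks, since below-chance
#' performance is meaningful (a sign-reversed representation).
#'
#' @param post_true,post_shuffle M x bins x repeats arrays of true-label
#'   posteriors (true and shuffled-label runs).
#' @param bins Bin metadata (`center`, `alignment`).
#' @param alpha FDR level (default 0.01).
#' @return `data.frame`: per bin, mean true/shuffled posterior, `t`, `p`,
#'   `p_fdr`, `sig_above`, `sig_below`.
#' @export
shuffle_significance <- function(post_true, post_shuffle, bins, alpha = 0.01) {
  if (dim(post_shuffle)[3] < 2 && dim(post_true)[3] < 2) {
    stop("need at least 2 repeats to form the null comparison")
  }
  a <- apply(post_true, c(1, 2), mean)
  b <- apply(post_shuffle, c(1, 2), mean)
  T_ <- ncol(a)
  tt <- pp <- numeric(T_)
  for (t in seq_len(T_)) {
    d <- a[, t] - b[, t]
    if (stats::sd(d) == 0) {
      tt[t] <- 0; pp[t] <- 1
    } else {
      ts <- stats::t.test(d)
      tt[t] <- unname(ts$statistic); pp[t] <- ts$p.value
    }
  }
  p_fdr <- stats::p.adjust(pp, method = "BH")
  data.frame(bins,
             mean_true = colMeans(a), mean_shuffle = colMeans(b),
             t = tt, p = pp, p_fdr = p_fdr,
             sig_above = p_fdr < alpha & tt > 0,
             sig_below = p_fdr < alpha & tt < 0)
}

#' Reaction-time median-split decoding
#'
#' Splits each neuron's eligible trials at the median reaction time (the
#' median trial goes to the slow half), decodes each half separately, and
#' compares the halves per bin with two-tailed paired t-tests under BH-FDR.
#'
#' @inheritParams decode_diagonal
#' @param alpha FDR level for the fast/slow comparison.
#' @return List: `fast`, `slow` (decoding_results), `comparison`
#'   (per-bin data.frame), `degenerate` (TRUE when RTs admit no split).
#' @export
rt_split_decoding <- function(input, n_per_class = 50, n_cv = 20,
                              var_threshold = 0.70, seed = NULL,
                              alpha = 0.01) {
  rts <- input$rts
  if (all(is.na(rts)) || stats::sd(rts, na.rm = TRUE) == 0) {
    return(list(fast = NULL, slow = NULL, comparison = NULL,
                degenerate = TRUE))
  }
  med <- stats::median(rts, na.rm = TRUE)
  fast_sel <- !is.na(rts) & rts < med
  slow_sel <- !is.na(rts) & rts >= med
  seeds <- with_seed(seed, sample.int(2^31 - 1, 2))
  fast <- decode_diagonal(input, n_per_class, n_cv, var_threshold,
                          seed = seeds[1], trial_subset = fast_sel)
  slow <- decode_diagonal(input, n_per_class, n_cv, var_threshold,
                          seed = seeds[2], trial_subset = slow_sel)
  a <- fast$per_trial
  b <- slow$per_trial
  T_ <- ncol(a)
  tt <- pp <- numeric(T_)
  for (t in seq_len(T_)) {
    d <- a[, t] - b[, t]
    if (stats::sd(d) == 0) { tt[t] <- 0; pp[t] <- 1 } else {
      ts <- stats::t.test(d)
      tt[t] <- unname(ts$statistic); pp[t] <- ts$p.value
    }
  }
  p_fdr <- stats::p.adjust(pp, method = "BH")
  comparison <- data.frame(input$bins, mean_fast = fast$mean,
                           mean_slow = slow$mean, t = tt, p = pp,
                           p_fdr = p_fdr, sig = p_fdr < alpha)
  list(fast = fast, slow = slow, comparison = comparison, degenerate = FALSE)
}
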