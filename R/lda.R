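#' Fit a two-class linear discriminant model
#'
#' Gaussian classes with pooled covariance; the posterior follows Bayes'
#' rule with the stated prior (default equal priors, 0.5). When the pooled
#' covariance is near-singular it is shrunk toward the scaled identity by
#' `shrink * mean(diag(S))`.
#'
#' @param x Feature matrix (trials x components).
#' @param y Class labels (two classes).
#' @param prior Prior probability of the first class level.
#' @param shrink Shrinkage constant applied when near-singular.
#' @return An `lda_model`: `classes`, `means` (2 x P), `w`, `c0` such that
#'   the posterior of class 1 is `plogis(x %*% w + c0 + log(prior/(1-prior)))`.
#' @export
lda_fit <- function(x, y, prior = 0.5, shrink = 1e-6) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required")
  if (nrow(x) < 3) stop("need at least 3 trials")
  if (min(table(y)) < 1) stop("both classes must be present")
  assert_prob(prior, "prior")
  cls <- levels(y)
  m1 <- colMeans(x[y == cls[1], , drop = FALSE])
  m2 <- colMeans(x[y == cls[2], , drop = FALSE])
  S <- pooled_cov(x, y)
  Sinv <- safe_inverse(S, shrink)
  w <- Sinv %*% (m1 - m2)
  c0 <- -0.5 * sum((m1 + m2) * w)
  structure(list(classes = cls, means = rbind(m1, m2), w = drop(w), c0 = c0,
                 prior = prior, cov = S),
            class = "lda_model")
}

pooled_cov <- function(x, y) {
  cls <- levels(y)
  W <- matrix(0, ncol(x), ncol(x))
  for (c in cls) {
    xc <- x[y == c, , drop = FALSE]
    xc <- sweep(xc, 2, colMeans(xc))
    W <- W + crossprod(xc)
  }
  W / (nrow(x) - 2)
}

safe_inverse <- function(S, shrink = 1e-6) {
  out <- tryCatch({
    r <- rcond(S)
    if (!is.finite(r) || r < 1e-10) stop("near-singular")
    solve(S)
  }, error = function(e) NULL)
  if (is.null(out)) {
    S <- S + shrink * mean(diag(S)) * diag(nrow(S))
    out <- solve(S)
  }
  out
}

#' Posterior class probabilities under a fitted LDA model
#'
#' @param model An `lda_model`.
#' @param x New feature matrix (trials x components).
#' @return Matrix (trials x 2) of class posteriors; rows sum to 1.
#' @export
lda_posterior <- function(model, x) {
  x <- matrix(x, ncol = length(model$w))
  d <- drop(x %*% model$w) + model$c0 +
    log(model$prior / (1 - model$prior))
  p1 <- stats::plogis(d)
  out <- cbind(p1, 1 - p1)
  colnames(out) <- model$classes
  out
}

#' Exact leave-one-out LDA posteriors (vectorized)
#'
#' For each trial, refits the two-class LDA on the remaining trials and
#' returns the posterior probability assigned to the held-out trial's true
#' class. The refit is exact but computed in closed form via rank-one
#' downdates of the pooled scatter (Sherman-Morrison), so the cost is a few
#' matrix products rather than M refits. Verified against naive refitting.
#'
#' @param x Feature matrix (M x P).
#' @param y Class labels (two classes).
#' @param prior Prior of the first class level.
#' @param shrink Shrinkage constant for a near-singular scatter.
#' @return List: `posterior_true` (length M), `posterior_class1`,
#'   `classes`.
#' @export
lda_loocv <- function(x, y, prior = 0.5, shrink = 1e-6) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required")
  cls <- levels(y)
  M <- nrow(x)
  n1 <- sum(y == cls[1]); n2 <- sum(y == cls[2])
  if (min(n1, n2) < 2) stop("need at least 2 trials per class")
  m1 <- colMeans(x[y == cls[1], , drop = FALSE])
  m2 <- colMeans(x[y == cls[2], , drop = FALSE])
  W <- pooled_cov(x, y) * (M - 2)          # pooled within-class scatter
  tr <- mean(diag(W))
  if (!is.finite(rcond(W)) || rcond(W) < 1e-10) {
    W <- W + shrink * tr * diag(nrow(W))
  }
  Winv <- solve(W)

  is1 <- y == cls[1]
  nc <- ifelse(is1, n1, n2)
  s <- ifelse(is1, 1, -1)
  kn <- 1 / (nc - 1)
  alpha <- nc / (nc - 1)
  b <- m1 - m2
  mid <- (m1 + m2) / 2
  U <- matrix(0, M, ncol(x))
  U[is1, ] <- sweep(x[is1, , drop = FALSE], 2, m1)
  U[!is1, ] <- sweep(x[!is1, , drop = FALSE], 2, m2)
  Z <- sweep(x, 2, mid)

  wb <- Winv %*% b
  zb <- drop(Z %*% wb)
  ub <- drop(U %*% wb)
  UW <- U %*% Winv
  q <- rowSums(UW * U)
  zu <- rowSums((Z %*% Winv) * U)

  mWa <- zb + 0.5 * kn * ub - s * kn * (zu + 0.5 * kn * q)
  uWa <- ub - s * kn * q
  mWu <- zu + 0.5 * kn * q
  denom <- 1 - alpha * q
  delta <- (M - 3) * (mWa + alpha * uWa * mWu / denom)
  logit <- delta + log(prior / (1 - prior))
  p1 <- stats::plogis(logit)
  list(posterior_true = ifelse(is1, p1, 1 - p1),
       posterior_class1 = p1, classes = cls)
}

#' Strict per-fold PCA + LDA leave-one-out (reference path)
#'
#' Refits the PCA subspace and the LDA on every training fold and projects
#' the held-out trial; exact but O(M) SVDs, intended for small instances
#' and as the leakage-free reference for the default path.
#'
#' @param A Trials x neurons matrix at one time bin.
#' @param y Class labels.
#' @param var_threshold PCA cumulative-variance threshold.
#' @param prior Prior of the first class level.
#' @return Vector of true-class posteriors, length `nrow(A)`.
#' @export
pca_lda_loocv_strict <- function(A, y, var_threshold = 0.70, prior = 0.5) {
  A <- as.matrix(A)
  y <- as.factor(y)
  M <- nrow(A)
  out <- numeric(M)
  for (m in seq_len(M)) {
    tr <- A[-m, , drop = FALSE]
    ctr <- colMeans(tr)
    trc <- sweep(tr, 2, ctr)
    sv <- svd(trc, nu = 0)
    p <- n_components(sv$d, var_threshold)
    V <- sv$v[, seq_len(p), drop = FALSE]
    fit <- lda_fit(trc %*% V, y[-m], prior = prior)
    post <- lda_posterior(fit, (A[m, ] - ctr) %*% V)
    out[m] <- post[1, as.character(y[m])]
  }
  out
}
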