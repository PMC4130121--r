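#' Fisher-z confidence interval for a correlation
#'
#' `atanh(r) +/- z_(alpha/2) / sqrt(n - 3)`, mapped back with `tanh`.
#'
#' @param r sample correlation, `|r| < 1`.
#' @param n sample size, `n > 3`.
#' @param level confidence level.
#' @return numeric length-2: lower and upper bounds.
#' @examples
#' corr_ci(-0.30, 79)  # c(-0.49, -0.08) to 2 dp
#' @export
corr_ci <- function(r, n, level = 0.95) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) >= 1)
    stop("'r' must be a single correlation with |r| < 1", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 3)
    stop("'n' must exceed 3", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)",
                                     call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z / sqrt(n - 3)
  tanh(atanh(r) + c(-1, 1) * half)
}

#' Pairwise robust correlation matrix
#'
#' Applies [robust_cor()] to every pair of columns: each variable is
#' Box-Cox transformed once (per-variable exponent), then every pair is
#' separately fed to the multivariate-t EM estimator.
#'
#' @param X numeric matrix or data.frame of strictly positive variables.
#' @inheritParams robust_cor
#' @return list with `r` (p x p correlation matrix), `lambda` (named
#'   vector of Box-Cox exponents) and `n`.
#' @export
robust_cor_matrix <- function(X, df = 4, transform = TRUE) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("need at least two variables", call. = FALSE)
  lambda <- rep(NA_real_, p)
  names(lambda) <- colnames(X)
  Xt <- X
  if (transform) {
    for (j in seq_len(p)) {
      lambda[j] <- boxcox_lambda(X[, j])
      Xt[, j] <- boxcox_transform(X[, j], lambda[j])
    }
  }
  R <- diag(p)
  dimnames(R) <- list(colnames(X), colnames(X))
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    # a perfectly collinear pair (e.g. two indices that are exact
    # rescalings of each other) has a singular scatter; record +/-1
    rp <- stats::cor(Xt[, j], Xt[, k])
    if (abs(rp) > 1 - 1e-10) {
      R[j, k] <- R[k, j] <- sign(rp)
      next
    }
    fit <- t_cov_em(Xt[, c(j, k)], df = df)
    R[j, k] <- R[k, j] <- fit$correlation[1, 2]
  }
  list(r = R, lambda = lambda, n = nrow(X))
}
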