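#' Box-Cox power transformation
#'
#' `boxcox_transform()` applies the power transform
#' `(x^lambda - 1) / lambda` (natural log when `|lambda| < 1e-8`);
#' `boxcox_lambda()` selects the exponent by maximising the profile
#' log-likelihood of the normal model, including the Jacobian term
#' `(lambda - 1) * sum(log x)`, over a fixed grid.
#'
#' @param x strictly positive numeric vector.
#' @param lambda power exponent.
#' @param grid candidate exponents; default `seq(-3, 3, by = 0.01)`.
#' @return `boxcox_transform()`: the transformed vector.
#'   `boxcox_lambda()`: the grid argmax of the profile log-likelihood.
#' @examples
#' boxcox_transform(3, 2)        # (9 - 1)/2 = 4
#' boxcox_transform(exp(1), 0)   # 1
#' @name boxcox
NULL

#' @rdname boxcox
#' @export
boxcox_transform <- function(x, lambda) {
  .check_positive(x, "x")
  if (length(lambda) != 1L || !is.finite(lambda))
    stop("'lambda' must be a finite scalar", call. = FALSE)
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcox
#' @export
boxcox_lambda <- function(x, grid = seq(-3, 3, by = 0.01)) {
  .check_positive(x, "x")
  n <- length(x)
  if (n < 5) stop("need at least 5 observations to select lambda",
                  call. = FALSE)
  if (stats::var(x) == 0)
    stop("'x' is constant; Box-Cox lambda is undefined", call. = FALSE)
  slx <- sum(log(x))
  ll <- vapply(grid, function(lam) {
    y <- boxcox_transform(x, lam)
    s2 <- mean((y - mean(y))^2)
    -n / 2 * log(s2) + (lam - 1) * slx
  }, numeric(1))
  grid[which.max(ll)]
}
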