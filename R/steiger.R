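#' Williams-Steiger test for two dependent correlations
#'
#' Tests whether two correlations sharing one variable differ: `r_jk` and
#' `r_jh`, estimated on the same `n` subjects, with `r_kh` the correlation
#' between the two non-shared variables. This is the Williams-modified t
#' (the form recommended for a single shared variable), referred against
#' the t distribution with `n - 3` degrees of freedom:
#'
#' `t = (r_jk - r_jh) * sqrt( (n-1)(1 + r_kh) /
#'       ( 2 * |R| * (n-1)/(n-3) + rbar^2 (1 - r_kh)^3 ) )`
#'
#' where `|R| = 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 r_jk r_jh r_kh` is the
#' determinant of the 3x3 correlation matrix and `rbar = (r_jk + r_jh)/2`.
#' The statistic is zero exactly when the two correlations are equal. To
#' compare the *magnitudes* of correlations with opposite signs (a
#' resistance index vs a sensitivity index against the same reference),
#' negate one variable's correlations (`r_jk` and `r_kh`) before calling.
#'
#' @param r_jk,r_jh the two correlations being compared (shared variable
#'   j).
#' @param r_kh correlation between the non-shared variables k and h.
#' @param n sample size, `n > 3`.
#' @return object of class `steiger_test`: list with `t_stat`, `df`,
#'   `p_value` (two-sided), and the inputs.
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n) {
  for (nm in c("r_jk", "r_jh", "r_kh")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) >= 1)
      stop("'", nm, "' must be a single correlation with |r| < 1",
           call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n <= 3)
    stop("'n' must exceed 3", call. = FALSE)
  detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  if (detR < -1e-8)
    stop("inconsistent correlation triple: the implied 3x3 correlation ",
         "matrix has negative determinant (", signif(detR, 3), ")",
         call. = FALSE)
  detR <- max(detR, 0)
  rbar <- (r_jk + r_jh) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_kh)^3
  t_stat <- (r_jk - r_jh) * sqrt((n - 1) * (1 + r_kh) / denom)
  df <- n - 3
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t_stat = t_stat, df = df, p_value = p,
                 r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n),
            class = "steiger_test")
}

#' @export
print.steiger_test <- function(x, ...) {
  cat(sprintf("Williams-Steiger test: r_jk = %.3f vs r_jh = %.3f (r_kh = %.3f, n = %d)\n",
              x$r_jk, x$r_jh, x$r_kh, x$n))
  cat(sprintf("  t = %.3f on %d df, two-sided p = %.4f\n",
              x$t_stat, x$df, x$p_value))
  invisible(x)
}
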