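#' Tertile assignment on the insulin-sensitivity scale
#'
#' Rank-based thirds. With `direction = "decreasing"` (a resistance
#' index: fasting insulin, HOMA-IR, FIRI, or an adiposity surrogate) the
#' values are negated before ranking, so the returned `high` category
#' always means high insulin *sensitivity*. Ties are broken by stable
#' original-order ranking (`ties.method = "first"`); ties spanning a cut
#' point trigger a warning. When n is not divisible by 3, the extra
#' member(s) go to the extreme groups: first `low`, then `high`.
#'
#' @param values numeric vector, no missing values, `n >= 3`.
#' @param direction does the value *increase* or *decrease* with insulin
#'   sensitivity?
#' @return factor with levels `low`, `medium`, `high`.
#' @export
assign_thirds <- function(values, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  oriented <- if (direction == "decreasing") -values else values
  q <- n %/% 3; rem <- n %% 3
  n_low <- q + (rem >= 1)
  n_high <- q + (rem >= 2)
  n_med <- n - n_low - n_high
  rk <- rank(oriented, ties.method = "first")
  srt <- sort(oriented)
  for (cut in c(n_low, n_low + n_med)) {
    if (cut >= 1 && cut < n && srt[cut] == srt[cut + 1]) {
      warning("tied values span a tertile boundary; assignment follows ",
              "stable original-order ranking", call. = FALSE)
      break
    }
  }
  out <- cut(rk, breaks = c(0, n_low, n_low + n_med, n),
             labels = c("low", "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Sex-specific tertiles, pooled
#'
#' Assigns thirds separately within each sex and returns the pooled
#' category vector (in original subject order). This is how the
#' all-subjects cross-classification is formed.
#'
#' @inheritParams assign_thirds
#' @param sex vector of sex codes aligned with `values`.
#' @export
sexwise_thirds <- function(values, sex, direction = c("increasing",
                                                      "decreasing")) {
  direction <- match.arg(direction)
  if (length(sex) != length(values))
    stop("'sex' and 'values' lengths differ", call. = FALSE)
  out <- factor(rep(NA_character_, length(values)),
                levels = c("low", "medium", "high"))
  for (s in unique(sex)) {
    sel <- sex == s
    out[sel] <- assign_thirds(values[sel], direction)
  }
  out
}

#' Cohen's kappa from a square contingency table
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` with the expected agreement
#' `p_e` computed from the row and column marginals.
#'
#' @param table square matrix of non-negative counts with positive total.
#' @return scalar kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(table) {
  tb <- as.matrix(table)
  if (nrow(tb) != ncol(tb)) stop("'table' must be square", call. = FALSE)
  if (any(tb < 0) || sum(tb) <= 0)
    stop("'table' must be non-negative with positive total", call. = FALSE)
  N <- sum(tb)
  po <- sum(diag(tb)) / N
  pe <- sum(rowSums(tb) * colSums(tb)) / N^2
  if (abs(1 - pe) < 1e-12)
    stop("expected agreement is 1 (degenerate margins); kappa undefined",
         call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Cross-classification of surrogate thirds against reference thirds
#'
#' Builds the 3x3 table of reference (clamp) thirds against surrogate
#' thirds, the percent correctly classified within each reference
#' category, the overall fraction correct, and Cohen's kappa.
#'
#' @param ref_cats,test_cats factors with levels `low`/`medium`/`high`
#'   (reference first).
#' @param stratum label stored with the result (`"all"`, `"male"`,
#'   `"female"`, ...).
#' @return object of class `concordance`: `table` (reference in rows),
#'   `pct_correct_by_ref`, `overall_correct`, `kappa`, `kappa_ci`
#'   (`NA` until filled by [bootstrap_kappa_ci()]), `n`, `stratum`.
#' @export
cross_classify <- function(ref_cats, test_cats, stratum = "all") {
  if (length(ref_cats) != length(test_cats))
    stop("'ref_cats' and 'test_cats' lengths differ", call. = FALSE)
  lv <- c("low", "medium", "high")
  ref_cats <- factor(ref_cats, levels = lv)
  test_cats <- factor(test_cats, levels = lv)
  if (anyNA(ref_cats) || anyNA(test_cats))
    stop("categories must be low/medium/high with no missing values",
         call. = FALSE)
  tb <- table(ref = ref_cats, test = test_cats)
  n <- sum(tb)
  pct <- 100 * diag(tb) / rowSums(tb)
  structure(list(table = unclass(tb),
                 pct_correct_by_ref = pct,
                 overall_correct = sum(diag(tb)) / n,
                 kappa = cohen_kappa(tb),
                 kappa_ci = c(NA_real_, NA_real_),
                 n = n, stratum = stratum),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Tertile concordance (", x$stratum, " stratum, n = ", x$n, ")\n",
      sep = "")
  print(x$table)
  cat(sprintf("Correct by reference third: %s\n",
              paste(sprintf("%s %.0f%%", names(x$pct_correct_by_ref),
                            x$pct_correct_by_ref), collapse = ", ")))
  cat(sprintf("Overall correct %d/%d; kappa = %.2f",
              round(x$overall_correct * x$n), x$n, x$kappa))
  if (!anyNA(x$kappa_ci))
    cat(sprintf(" (95%% CI %.2f to %.2f)", x$kappa_ci[1], x$kappa_ci[2]))
  cat("\n")
  invisible(x)
}

#' Bootstrap confidence interval for kappa
#'
#' Resamples subjects with replacement, recomputes tertiles and kappa in
#' every replicate, and returns the percentile interval. When `sex` is
#' supplied, tertiles are recomputed within sex in every replicate (the
#' way the pooled all-subjects classification is formed); resampling
#' itself is unstratified. Replicates with degenerate margins are skipped
#' with a warning and their count reported as an attribute.
#'
#' @param ref_values reference measurements (clamp M; thirds taken
#'   increasing).
#' @param test_values surrogate measurements.
#' @param sex optional sex codes; when given, thirds are sex-specific.
#' @param direction direction of `test_values` (see [assign_thirds()]).
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed optional integer seed for reproducibility.
#' @return numeric length-2 interval with attribute `skipped` (number of
#'   degenerate replicates).
#' @export
bootstrap_kappa_ci <- function(ref_values, test_values, sex = NULL,
                               direction = c("increasing", "decreasing"),
                               B = 1000, level = 0.95, seed = NULL) {
  direction <- match.arg(direction)
  n <- length(ref_values)
  if (length(test_values) != n)
    stop("'ref_values' and 'test_values' lengths differ", call. = FALSE)
  if (n < 6) stop("need at least 6 subjects per stratum", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  thirds <- function(rv, tv, sx) {
    if (is.null(sx)) {
      list(ref = assign_thirds(rv, "increasing"),
           test = assign_thirds(tv, direction))
    } else {
      list(ref = sexwise_thirds(rv, sx, "increasing"),
           test = sexwise_thirds(tv, sx, direction))
    }
  }
  kap <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sx <- if (is.null(sex)) NULL else sex[idx]
    if (!is.null(sx) && any(table(sx) < 3)) { skipped <- skipped + 1L; next }
    th <- suppressWarnings(thirds(ref_values[idx], test_values[idx], sx))
    tb <- table(th$ref, th$test)
    kap[b] <- tryCatch(cohen_kappa(tb), error = function(e) NA_real_)
    if (is.na(kap[b])) skipped <- skipped + 1L
  }
  if (skipped > 0)
    warning(skipped, " bootstrap replicate(s) with degenerate margins ",
            "were skipped", call. = FALSE)
  alpha <- (1 - level) / 2
  ci <- stats::quantile(kap, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  attr(ci, "skipped") <- skipped
  ci
}
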