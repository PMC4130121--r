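# Internal argument checking shared across the package.

# Stop if x is not a finite, strictly positive numeric vector.
# `name` appears in the error so callers can see which field is at fault.
.check_positive <- function(x, name) {
  if (missing(x) || is.null(x) || length(x) == 0L)
    stop("'", name, "' is missing", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'", name, "' must be finite and non-missing", call. = FALSE)
  if (any(x <= 0))
    stop("'", name, "' must be strictly positive", call. = FALSE)
  invisible(x)
}

.check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'", name, "' must be finite and non-missing", call. = FALSE)
  if (any(x < 0))
    stop("'", name, "' must be non-negative", call. = FALSE)
  invisible(x)
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be TRUE or FALSE", call. = FALSE)
  invisible(x)
}

# format "mean ± sd" strings for report tables
.mean_sd <- function(m, s, digits = 2) {
  ifelse(is.na(m), "", paste0(round(m, digits), " ± ", round(s, digits)))
}
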