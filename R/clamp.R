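#' Clamp trace container
#'
#' A `clamp_trace` holds one subject's euglycemic hyperinsulinemic clamp
#' record: blood glucose and exogenous glucose infusion rate sampled on a
#' 5-minute grid, plus plasma insulin at the nominal sampling times
#' (fasting and the 80/90/100-minute steady-state samples). The protocol
#' infuses insulin at a constant 80 mU per m^2 body surface area per
#' minute while 20% glucose is infused at a variable rate to hold blood
#' glucose at the 100 mg/dL target.
#'
#' @param subject_id subject identifier (scalar character).
#' @param time sampling times in minutes, strictly increasing.
#' @param glucose blood glucose at each time, mg/dL, non-negative.
#' @param gir exogenous glucose infusion rate at each time, mg/min,
#'   non-negative.
#' @param insulin plasma insulin at each time, uU/mL; `NA` where not
#'   sampled (typically only 0/80/90/100 min are sampled).
#' @param insulin_infusion_rate insulin infusion rate, mU/m^2/min.
#' @return An object of class `clamp_trace`.
#' @export
clamp_trace <- function(subject_id, time, glucose, gir, insulin = NULL,
                        insulin_infusion_rate = 80) {
  if (length(subject_id) != 1L) stop("'subject_id' must be a scalar")
  n <- length(time)
  if (length(glucose) != n || length(gir) != n)
    stop("'time', 'glucose' and 'gir' must have equal length", call. = FALSE)
  if (is.null(insulin)) insulin <- rep(NA_real_, n)
  if (length(insulin) != n)
    stop("'insulin' must align with 'time'", call. = FALSE)
  if (anyNA(time) || any(diff(time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  .check_nonnegative(glucose, "glucose")
  .check_nonnegative(gir, "gir")
  structure(
    list(subject_id = as.character(subject_id),
         data = data.frame(time = as.numeric(time),
                           glucose = as.numeric(glucose),
                           gir = as.numeric(gir),
                           insulin = as.numeric(insulin)),
         insulin_infusion_rate = insulin_infusion_rate),
    class = "clamp_trace")
}

#' @export
print.clamp_trace <- function(x, ...) {
  cat("Euglycemic clamp trace for subject", x$subject_id, "\n")
  cat("  ", nrow(x$data), "samples over",
      min(x$data$time), "-", max(x$data$time), "min;",
      sum(!is.na(x$data$insulin)), "insulin samples\n")
  cat("  insulin infusion:", x$insulin_infusion_rate, "mU/m2/min\n")
  invisible(x)
}

# nominal sampling times are matched within +/- 0.5 min of the grid
.TIME_TOL <- 0.5

#' Steady-state summary of a clamp trace
#'
#' Averages glucose infusion rate and blood glucose over the steady-state
#' window (80-100 min by default, endpoints inclusive), computes the
#' within-window coefficient of variation of blood glucose, and averages
#' the available steady-state insulin samples (nominal 80/90/100 min). A
#' glucose CV of 5% or more is flagged with a warning but the record is
#' retained.
#'
#' @param trace a [clamp_trace()].
#' @param window numeric length-2, steady-state window in minutes.
#' @return list with `mean_gir` (mg/min), `ss_glucose` (mg/dL),
#'   `cv_glucose` (%), `ss_insulin` (uU/mL, `NA` if never sampled in the
#'   window).
#' @export
steady_state_summary <- function(trace, window = c(80, 100)) {
  stopifnot(inherits(trace, "clamp_trace"))
  if (length(window) != 2L || window[1] >= window[2])
    stop("'window' must be an increasing pair of times", call. = FALSE)
  d <- trace$data
  if (window[1] < min(d$time) - .TIME_TOL ||
      window[2] > max(d$time) + .TIME_TOL)
    stop("steady-state window [", window[1], ", ", window[2],
         "] extends beyond the sampled trace", call. = FALSE)
  inw <- d$time >= window[1] - .TIME_TOL & d$time <= window[2] + .TIME_TOL
  if (sum(inw) < 3L)
    stop("fewer than 3 samples inside the steady-state window", call. = FALSE)
  g <- d$glucose[inw]
  mean_g <- mean(g)
  cv <- 100 * stats::sd(g) / mean_g
  if (cv >= 5)
    warning("within-window blood glucose CV is ", round(cv, 1),
            "% (>= 5%) for subject ", trace$subject_id, call. = FALSE)
  ins <- d$insulin[inw]
  ss_ins <- if (all(is.na(ins))) NA_real_ else mean(ins, na.rm = TRUE)
  list(mean_gir = mean(d$gir[inw]), ss_glucose = mean_g,
       cv_glucose = cv, ss_insulin = ss_ins)
}

#' Glucose-space correction factor
#'
#' Multiplicative correction for between-subject deviation from the clamp
#' glucose target: the group-average steady-state glucose divided by the
#' individual steady-state glucose.
#'
#' @param individual_ss_glucose subject's steady-state glucose, mg/dL.
#' @param group_mean_ss_glucose cohort mean steady-state glucose, mg/dL.
#' @return dimensionless correction factor.
#' @export
glucose_space_correction <- function(individual_ss_glucose,
                                     group_mean_ss_glucose) {
  .check_positive(individual_ss_glucose, "individual_ss_glucose")
  .check_positive(group_mean_ss_glucose, "group_mean_ss_glucose")
  group_mean_ss_glucose / individual_ss_glucose
}

#' Clamp M value for one subject
#'
#' Insulin-mediated glucose uptake from the steady-state glucose infusion
#' rate, corrected for glucose space and normalised per kg fat-free mass
#' (`m_adjusted`) and per kg body weight (`m_unadjusted`). An auxiliary
#' insulin-normalised value `m_over_i = m_adjusted / ss_insulin` is also
#' reported when steady-state insulin was sampled; the headline M values
#' are *not* divided by insulin.
#'
#' @param trace a [clamp_trace()].
#' @param weight body weight, kg.
#' @param fat_free_mass fat-free mass, kg.
#' @param group_mean_ss_glucose cohort mean steady-state glucose, mg/dL;
#'   must be computed over the analysis cohort before calling (see
#'   [m_value_cohort()]).
#' @param window steady-state window, minutes.
#' @return An object of class `m_value`: list with `mean_gir`,
#'   `ss_glucose`, `ss_insulin`, `cv_glucose`, `space_correction`,
#'   `m_unadjusted` (mg/min/kg body weight), `m_adjusted` (mg/min/kg
#'   fat-free mass) and `m_over_i`.
#' @export
m_value <- function(trace, weight, fat_free_mass, group_mean_ss_glucose,
                    window = c(80, 100)) {
  .check_positive(weight, "weight")
  .check_positive(fat_free_mass, "fat_free_mass")
  ss <- steady_state_summary(trace, window)
  corr <- glucose_space_correction(ss$ss_glucose, group_mean_ss_glucose)
  out <- list(subject_id = trace$subject_id,
              mean_gir = ss$mean_gir,
              ss_glucose = ss$ss_glucose,
              ss_insulin = ss$ss_insulin,
              cv_glucose = ss$cv_glucose,
              space_correction = corr,
              m_unadjusted = ss$mean_gir * corr / weight,
              m_adjusted = ss$mean_gir * corr / fat_free_mass,
              m_over_i = if (is.na(ss$ss_insulin)) NA_real_ else
                ss$mean_gir * corr / fat_free_mass / ss$ss_insulin)
  class(out) <- "m_value"
  out
}

#' @export
print.m_value <- function(x, ...) {
  cat("Clamp M value, subject", x$subject_id, "\n")
  cat(sprintf("  steady state: GIR %.1f mg/min, glucose %.1f mg/dL (CV %.1f%%)\n",
              x$mean_gir, x$ss_glucose, x$cv_glucose))
  cat(sprintf("  space correction %.3f\n", x$space_correction))
  cat(sprintf("  M = %.2f mg/min/kg FFM (%.2f mg/min/kg body weight)\n",
              x$m_adjusted, x$m_unadjusted))
  invisible(x)
}

#' Cohort M values
#'
#' Derives per-subject M values for a whole cohort: steady-state summaries
#' are computed for every trace first, the group mean steady-state glucose
#' is taken over those subjects, and the per-subject glucose-space
#' corrections then use that group mean.
#'
#' @param traces list of [clamp_trace()] objects.
#' @param subjects data.frame with columns `subject_id`, `weight_kg`,
#'   `fat_free_mass_kg` covering every trace.
#' @param window steady-state window, minutes.
#' @return data.frame with one row per trace: steady-state summaries,
#'   space correction, `m_unadjusted`, `m_adjusted`, `m_over_i`.
#' @export
m_value_cohort <- function(traces, subjects, window = c(80, 100)) {
  stopifnot(is.list(traces), length(traces) > 0L)
  ids <- vapply(traces, function(tr) tr$subject_id, character(1))
  idx <- match(ids, subjects$subject_id)
  if (anyNA(idx))
    stop("subjects table is missing ids: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  ss <- lapply(traces, steady_state_summary, window = window)
  grp <- mean(vapply(ss, `[[`, numeric(1), "ss_glucose"))
  rows <- lapply(seq_along(traces), function(i) {
    m <- m_value(traces[[i]], weight = subjects$weight_kg[idx[i]],
                 fat_free_mass = subjects$fat_free_mass_kg[idx[i]],
                 group_mean_ss_glucose = grp, window = window)
    data.frame(subject_id = m$subject_id, mean_gir = m$mean_gir,
               ss_glucose = m$ss_glucose, ss_insulin = m$ss_insulin,
               cv_glucose = m$cv_glucose, space_correction = m$space_correction,
               m_unadjusted = m$m_unadjusted, m_adjusted = m$m_adjusted,
               m_over_i = m$m_over_i)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_mean_ss_glucose") <- grp
  out
}
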