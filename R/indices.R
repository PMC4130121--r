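#' Fasting surrogate indices of insulin sensitivity
#'
#' Functions computing the classical fasting indices from fasting plasma
#' glucose and insulin: HOMA-IR and FIRI (insulin *resistance*; higher =
#' more resistant), QUICKI and the glucose/insulin ratio (insulin
#' *sensitivity*; higher = more sensitive).
#'
#' Unit conventions follow the published definitions: HOMA-IR and FIRI take
#' glucose in mmol/L, QUICKI and the glucose/insulin ratio default to
#' glucose in mg/dL (configurable), and insulin is always in uU/mL
#' (numerically equal to mU/L).
#'
#' @param glucose fasting plasma glucose; mmol/L for [homa_ir()] and
#'   [firi()], mg/dL by default for [quicki()] and [gi_ratio()].
#' @param insulin fasting plasma insulin in uU/mL.
#' @return Numeric vector (vectorised over inputs).
#' @examples
#' homa_ir(4.5, 5)        # 1.0
#' firi(4.5, 5)           # 0.9 = 0.9 * homa_ir(4.5, 5)
#' quicki(100, 10)        # 1/3
#' gi_ratio(100, 10)      # 10
#' @name fasting-indices
NULL

#' @rdname fasting-indices
#' @export
homa_ir <- function(glucose, insulin) {
  .check_positive(glucose, "glucose")
  .check_positive(insulin, "insulin")
  glucose * insulin / 22.5
}

#' @rdname fasting-indices
#' @export
firi <- function(glucose, insulin) {
  .check_positive(glucose, "glucose")
  .check_positive(insulin, "insulin")
  glucose * insulin / 25
}

#' @rdname fasting-indices
#' @param log_base base of the logarithm in the QUICKI denominator, 10
#'   (the published convention, default) or `exp(1)`.
#' @param glucose_units units in which `glucose` is supplied.
#' @export
quicki <- function(glucose, insulin, log_base = 10,
                   glucose_units = c("mg/dL", "mmol/L")) {
  .check_positive(glucose, "glucose")
  .check_positive(insulin, "insulin")
  glucose_units <- match.arg(glucose_units)
  if (glucose_units == "mmol/L")
    glucose <- convert_glucose(glucose, "mmol/L", "mg/dL")
  if (!isTRUE(log_base %in% c(10, exp(1))))
    stop("'log_base' must be 10 or exp(1)", call. = FALSE)
  denom <- log(insulin, base = log_base) + log(glucose, base = log_base)
  if (any(abs(denom) < 1e-8))
    stop("QUICKI denominator log(insulin) + log(glucose) is singular",
         call. = FALSE)
  1 / denom
}

#' @rdname fasting-indices
#' @export
gi_ratio <- function(glucose, insulin,
                     glucose_units = c("mg/dL", "mmol/L")) {
  .check_positive(glucose, "glucose")
  .check_positive(insulin, "insulin")
  glucose_units <- match.arg(glucose_units)
  glucose / insulin
}

#' All fasting indices at once
#'
#' Convenience wrapper computing HOMA-IR, FIRI, QUICKI and the fasting
#' glucose/insulin ratio from glucose in mmol/L (converted internally to
#' mg/dL for the indices conventionally defined on that scale).
#'
#' @param glucose_mmol fasting glucose, mmol/L.
#' @param insulin fasting insulin, uU/mL.
#' @inheritParams quicki
#' @return data.frame with columns `homa_ir`, `firi`, `quicki`, `gi_ratio`,
#'   `fasting_insulin`.
#' @export
fasting_indices <- function(glucose_mmol, insulin, log_base = 10) {
  g_mgdl <- convert_glucose(glucose_mmol, "mmol/L", "mg/dL")
  data.frame(
    homa_ir = homa_ir(glucose_mmol, insulin),
    firi = firi(glucose_mmol, insulin),
    quicki = quicki(g_mgdl, insulin, log_base = log_base),
    gi_ratio = gi_ratio(g_mgdl, insulin),
    fasting_insulin = insulin
  )
}

#' LDL cholesterol by the Friedewald formula
#'
#' LDL = TC - HDL - TG/5, all in mg/dL. The formula is invalid for
#' triglycerides above 400 mg/dL and an error is raised there; a negative
#' result is returned with a warning.
#'
#' @param total_chol,hdl,triglycerides serum lipids, mg/dL.
#' @return LDL cholesterol, mg/dL.
#' @examples
#' friedewald_ldl(160, 48, 50)  # 102
#' @export
friedewald_ldl <- function(total_chol, hdl, triglycerides) {
  .check_nonnegative(total_chol, "total_chol")
  .check_nonnegative(hdl, "hdl")
  .check_nonnegative(triglycerides, "triglycerides")
  if (any(triglycerides > 400))
    stop("Friedewald formula is not valid for triglycerides > 400 mg/dL",
         call. = FALSE)
  ldl <- total_chol - hdl - triglycerides / 5
  if (any(ldl < 0))
    warning("Friedewald LDL is negative for some subjects", call. = FALSE)
  ldl
}

# mg/dL per mmol/L for glucose (molar mass 180.16 g/mol => 18.016 mg/dL
# per mmol/L)
.GLUCOSE_MGDL_PER_MMOL <- 18.016

#' Convert glucose between mg/dL and mmol/L
#'
#' @param value glucose concentration(s), non-negative.
#' @param from_units,to_units `"mg/dL"` or `"mmol/L"`.
#' @return `value` expressed in `to_units`.
#' @export
convert_glucose <- function(value, from_units, to_units) {
  .check_nonnegative(value, "value")
  units <- c("mg/dL", "mmol/L")
  if (!from_units %in% units || !to_units %in% units)
    stop("glucose units must be one of 'mg/dL', 'mmol/L'", call. = FALSE)
  if (from_units == to_units) return(value)
  if (from_units == "mmol/L") value * .GLUCOSE_MGDL_PER_MMOL
  else value / .GLUCOSE_MGDL_PER_MMOL
}

#' BMI category
#'
#' Half-open bins: lean `[0, 25)`, overweight `[25, 30)`, obese `[30, Inf)`
#' kg/m^2.
#'
#' @param bmi body mass index, kg/m^2, strictly positive.
#' @return factor with levels `lean`, `overweight`, `obese`.
#' @export
bmi_category <- function(bmi) {
  .check_positive(bmi, "bmi")
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("lean", "overweight", "obese"))
}
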