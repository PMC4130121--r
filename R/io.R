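# CSV dialects: one wide row per subject; clamp records in long format.

.SUBJECT_COLS <- c("subject_id", "sex", "age", "height_cm", "weight_kg",
                   "waist_cm", "hip_cm", "percent_fat",
                   "fat_free_mass_kg", "fasting_glucose_mmol_l",
                   "fasting_insulin_uu_ml", "tc_mg_dl", "hdl_mg_dl",
                   "tg_mg_dl", "sbp", "dbp")

.CLAMP_COLS <- c("subject_id", "time_min", "glucose_mg_dl", "gir_mg_min",
                 "insulin_uu_ml")

#' Read and write the subject CSV
#'
#' One row per subject with the fixed column set
#' `subject_id,sex,age,height_cm,weight_kg,waist_cm,hip_cm,percent_fat,`
#' `fat_free_mass_kg,fasting_glucose_mmol_l,fasting_insulin_uu_ml,`
#' `tc_mg_dl,hdl_mg_dl,tg_mg_dl,sbp,dbp`; sex coded `M`/`F`; missing
#' values as empty cells. The reader derives `bmi` and `whtr` from
#' height, weight and waist and validates basic plausibility (positive
#' anthropometry, non-diabetic fasting glucose below 7 mmol/L).
#'
#' @param path file path.
#' @return `read_subject_csv()`: data.frame of subject records.
#' @export
read_subject_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.SUBJECT_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("subject CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    warning("subject CSV is empty", call. = FALSE)
    out <- df[, .SUBJECT_COLS]
    out$bmi <- numeric(0); out$whtr <- numeric(0)
    return(out)
  }
  bad_sex <- which(!df$sex %in% c("M", "F"))
  if (length(bad_sex) > 0)
    stop("unknown sex code in row(s) ", paste(bad_sex, collapse = ", "),
         " (must be 'M' or 'F')", call. = FALSE)
  num_cols <- setdiff(.SUBJECT_COLS, c("subject_id", "sex"))
  for (cl in num_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad) > 0)
      stop("unparseable value in column '", cl, "', row ", bad[1],
           ": '", raw[bad[1]], "'", call. = FALSE)
    val[!nzchar(raw)] <- NA_real_
    df[[cl]] <- val
  }
  for (cl in c("height_cm", "weight_kg", "waist_cm", "hip_cm",
               "fat_free_mass_kg")) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    if (length(bad) > 0)
      stop("non-positive '", cl, "' in row ", bad[1], call. = FALSE)
  }
  high_g <- which(!is.na(df$fasting_glucose_mmol_l) &
                    df$fasting_glucose_mmol_l >= 7)
  if (length(high_g) > 0)
    warning("fasting glucose >= 7 mmol/L (diabetic range) in row(s) ",
            paste(high_g, collapse = ", "), call. = FALSE)
  df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  df$whtr <- df$waist_cm / df$height_cm
  df
}

#' @rdname read_subject_csv
#' @param subjects data.frame with the subject columns (extra derived
#'   columns are dropped on write).
#' @export
write_subject_csv <- function(subjects, path) {
  missing_cols <- setdiff(.SUBJECT_COLS, names(subjects))
  if (length(missing_cols) > 0)
    stop("subjects table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(subjects[, .SUBJECT_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read and write the clamp CSV
#'
#' Long format with columns
#' `subject_id,time_min,glucose_mg_dl,gir_mg_min,insulin_uu_ml`; insulin
#' populated only at the sampled times (empty elsewhere).
#'
#' @param path file path.
#' @return `read_clamp_csv()`: named list of [clamp_trace()] objects.
#' @export
read_clamp_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.CLAMP_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("clamp CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    warning("clamp CSV is empty", call. = FALSE)
    return(list())
  }
  for (cl in setdiff(.CLAMP_COLS, "subject_id")) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad) > 0)
      stop("unparseable value in column '", cl, "', row ", bad[1],
           ": '", raw[bad[1]], "'", call. = FALSE)
    val[!nzchar(raw)] <- NA_real_
    df[[cl]] <- val
  }
  split_df <- split(df, df$subject_id)
  traces <- lapply(split_df, function(d) {
    d <- d[order(d$time_min), ]
    clamp_trace(d$subject_id[1], d$time_min, d$glucose_mg_dl,
                d$gir_mg_min, d$insulin_uu_ml)
  })
  traces[unique(df$subject_id)]
}

#' @rdname read_clamp_csv
#' @param traces list of [clamp_trace()] objects.
#' @export
write_clamp_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(subject_id = tr$subject_id, time_min = tr$data$time,
               glucose_mg_dl = tr$data$glucose,
               gir_mg_min = tr$data$gir,
               insulin_uu_ml = tr$data$insulin))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
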