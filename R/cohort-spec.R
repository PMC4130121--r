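#' Default group parameters for the synthetic cohort
#'
#' Reads the versioned parameter file shipped with the package: per
#' (sex x BMI-category) means and SDs for age, anthropometry, blood
#' pressure, lipids, fasting glucose/insulin and the clamp M value, plus
#' sex-level height distributions.
#'
#' @param path optional path to an alternative JSON parameter file with
#'   the same layout.
#' @return nested list as stored in the JSON file.
#' @export
default_cohort_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_params.json",
                        package = "clampval", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Specification of a synthetic study cohort
#'
#' Bundles everything the generator needs: cohort size and sex ratio,
#' per-stratum distribution parameters, the latent correlation structure
#' between true insulin sensitivity and the fasting/adiposity measures,
#' and the clamp measurement-noise levels.
#'
#' `latent_structure` gives target correlations, on the Gaussian-copula
#' (log) scale, between latent insulin sensitivity `S_true` and log
#' HOMA-IR, BMI and waist circumference, plus the correlations among those
#' three. The waist-to-height target is reported for reference only: WHtR
#' is waist/height by construction, so its correlation with `S_true` is
#' inherited from waist (attenuated by independent height variation)
#' rather than set directly.
#'
#' @param n_subjects cohort size (>= 2).
#' @param sex_ratio fraction of males.
#' @param group_params parameter list as from [default_cohort_params()].
#' @param latent_structure named list of copula-scale correlations:
#'   `s_homa`, `s_bmi`, `s_waist`, `s_whtr` (reference), `homa_bmi`,
#'   `homa_waist`, `bmi_waist`.
#' @param noise named list: `glucose_cv` (%, within-window blood glucose),
#'   `gir_sd` (relative SD of the glucose infusion rate), `insulin_cv`
#'   (%, steady-state insulin), `ss_glucose_sd` (mg/dL, between-subject SD
#'   of the individual clamp glucose level around the 100 mg/dL target).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 87,
                        sex_ratio = 51 / 87,
                        group_params = default_cohort_params(),
                        latent_structure = list(
                          s_homa = -0.30, s_bmi = -0.38, s_waist = -0.43,
                          s_whtr = -0.38,
                          homa_bmi = 0.45, homa_waist = 0.45,
                          bmi_waist = 0.85),
                        noise = list(glucose_cv = 2, gir_sd = 0.04,
                                     insulin_cv = 5, ss_glucose_sd = 3),
                        seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("'n_subjects' must be at least 2", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("'sex_ratio' must be in [0, 1]", call. = FALSE)
  ls <- latent_structure
  need <- c("s_homa", "s_bmi", "s_waist", "homa_bmi", "homa_waist",
            "bmi_waist")
  if (!all(need %in% names(ls)))
    stop("latent_structure must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  rs <- unlist(ls[need])
  if (any(abs(rs) >= 1))
    stop("latent correlations must lie in (-1, 1)", call. = FALSE)
  R <- .latent_corr_matrix(ls)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("latent_structure implies a non-positive-definite correlation ",
         "matrix (smallest eigenvalue ", signif(min(ev), 3), ")",
         call. = FALSE)
  for (nm in c("glucose_cv", "gir_sd", "insulin_cv", "ss_glucose_sd"))
    .check_nonnegative(noise[[nm]], paste0("noise$", nm))
  structure(list(n_subjects = as.integer(round(n_subjects)),
                 sex_ratio = sex_ratio, group_params = group_params,
                 latent_structure = ls, noise = noise, seed = seed),
            class = "cohort_spec")
}

# 4x4 latent correlation matrix in the order (S_true, logHOMA, BMI, waist)
.latent_corr_matrix <- function(ls) {
  R <- diag(4)
  dimnames(R) <- rep(list(c("s", "homa", "bmi", "waist")), 2)
  R["s", "homa"] <- R["homa", "s"] <- ls$s_homa
  R["s", "bmi"] <- R["bmi", "s"] <- ls$s_bmi
  R["s", "waist"] <- R["waist", "s"] <- ls$s_waist
  R["homa", "bmi"] <- R["bmi", "homa"] <- ls$homa_bmi
  R["homa", "waist"] <- R["waist", "homa"] <- ls$homa_waist
  R["bmi", "waist"] <- R["waist", "bmi"] <- ls$bmi_waist
  R
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  n =", x$n_subjects, sprintf("(%.0f%% male)", 100 * x$sex_ratio), "\n")
  ls <- x$latent_structure
  cat(sprintf("  latent corr(S, .): logHOMA %.2f, BMI %.2f, waist %.2f\n",
              ls$s_homa, ls$s_bmi, ls$s_waist))
  cat(sprintf("  noise: glucose CV %.1f%%, GIR SD %.0f%%, insulin CV %.1f%%\n",
              x$noise$glucose_cv, 100 * x$noise$gir_sd, x$noise$insulin_cv))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
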