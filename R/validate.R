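# End-to-end orchestration of the validation study.

# surrogate measures and the direction in which each increases with
# insulin sensitivity
.SURROGATES <- data.frame(
  name = c("fasting_insulin", "gi_ratio", "homa_ir", "firi", "quicki",
           "age", "bmi", "waist", "whtr"),
  column = c("fasting_insulin_uu_ml", "gi_ratio", "homa_ir", "firi",
             "quicki", "age", "bmi", "waist_cm", "whtr"),
  direction = c("decreasing", "increasing", "decreasing", "decreasing",
                "increasing", "decreasing", "decreasing", "decreasing",
                "decreasing"),
  group = c("fasting", "fasting", "fasting", "fasting", "fasting",
            "clinical", "clinical", "clinical", "clinical"),
  stringsAsFactors = FALSE)

.ANALYSIS_VARS <- c("age", "height_cm", "weight_kg", "waist_cm", "hip_cm",
                    "percent_fat", "fat_free_mass_kg",
                    "fasting_glucose_mmol_l", "fasting_insulin_uu_ml",
                    "tc_mg_dl", "hdl_mg_dl", "tg_mg_dl", "sbp", "dbp")

#' Configuration of a validation run
#'
#' Exactly one data source must be given: a [cohort_spec()] to simulate,
#' or paths to the subject and clamp CSV files.
#'
#' @param cohort_spec a [cohort_spec()], or `NULL` when reading CSVs.
#' @param subjects_csv,clamp_csv input paths, or `NULL` when simulating.
#' @param quicki_log_base log base for QUICKI (10 or `exp(1)`).
#' @param t_df degrees of freedom of the multivariate-t correlation model.
#' @param huber_tuning tuning constant of the robust regressions.
#' @param bootstrap_B bootstrap replicates for the kappa intervals
#'   (>= 100).
#' @param seed integer seed governing the whole run.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort_spec = NULL, subjects_csv = NULL,
                       clamp_csv = NULL, quicki_log_base = 10,
                       t_df = 4, huber_tuning = 1.345,
                       bootstrap_B = 1000, seed = 1) {
  simulate <- !is.null(cohort_spec)
  from_csv <- !is.null(subjects_csv) || !is.null(clamp_csv)
  if (simulate == from_csv)
    stop("give exactly one of 'cohort_spec' or the CSV paths",
         call. = FALSE)
  if (from_csv && (is.null(subjects_csv) || is.null(clamp_csv)))
    stop("both 'subjects_csv' and 'clamp_csv' are required", call. = FALSE)
  if (bootstrap_B < 100) stop("'bootstrap_B' must be at least 100",
                              call. = FALSE)
  structure(list(cohort_spec = cohort_spec, subjects_csv = subjects_csv,
                 clamp_csv = clamp_csv, quicki_log_base = quicki_log_base,
                 t_df = t_df, huber_tuning = huber_tuning,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full index-validation analysis
#'
#' Ingests (or simulates) a cohort with clamp records, derives the
#' fasting indices and clamp M values, and performs the three analysis
#' stages: robust correlations of every surrogate with the clamp M value
#' (overall and by sex, Box-Cox + multivariate-t EM, Fisher-z intervals)
#' with Williams-Steiger comparisons between surrogates; Huber
#' regressions of M on each index with sex and adiposity; and
#' sex-specific tertile concordance with bootstrap kappa intervals.
#' Subjects missing any analysis variable (or a clamp record) are dropped
#' with a logged count; all randomness flows from the configured seed, so
#' identical configurations give identical results.
#'
#' @param config a [run_config()].
#' @return object of class `index_validation` with components `analysis`
#'   (the complete-case analysis frame), `table1`, `correlations`,
#'   `steiger`, `regressions`, `concordance`, `figure_data`, `log`, and
#'   `s_true` for simulated cohorts.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  if (!is.null(config$cohort_spec)) {
    sim <- simulate_study(config$cohort_spec)
    subjects <- sim$subjects
    traces <- sim$traces
    s_true <- sim$s_true
  } else {
    subjects <- read_subject_csv(config$subjects_csv)
    traces <- read_clamp_csv(config$clamp_csv)
    s_true <- NULL
  }
  n_total <- nrow(subjects)

  # complete cases: every analysis variable present plus a clamp record
  has_vars <- stats::complete.cases(subjects[, .ANALYSIS_VARS])
  has_trace <- subjects$subject_id %in%
    vapply(traces, function(tr) tr$subject_id, character(1))
  keep <- has_vars & has_trace
  dropped <- subjects$subject_id[!keep]
  subjects <- subjects[keep, , drop = FALSE]
  if (!is.null(s_true)) s_true <- s_true[keep]
  if (nrow(subjects) < 10)
    stop("fewer than 10 complete cases after filtering", call. = FALSE)
  traces <- traces[match(subjects$subject_id,
                         vapply(traces, function(tr) tr$subject_id,
                                character(1)))]

  # derived quantities
  mv <- m_value_cohort(traces, subjects)
  analysis <- cbind(subjects,
                    fasting_indices(subjects$fasting_glucose_mmol_l,
                                    subjects$fasting_insulin_uu_ml,
                                    log_base = config$quicki_log_base),
                    mv[match(subjects$subject_id, mv$subject_id),
                       c("m_unadjusted", "m_adjusted", "ss_glucose",
                         "ss_insulin", "cv_glucose", "m_over_i")])
  if (!("bmi" %in% names(analysis)))
    analysis$bmi <- analysis$weight_kg / (analysis$height_cm / 100)^2
  if (!("whtr" %in% names(analysis)))
    analysis$whtr <- analysis$waist_cm / analysis$height_cm
  analysis$whr <- analysis$waist_cm / analysis$hip_cm
  tg_ok <- analysis$tg_mg_dl <= 400
  analysis$ldl_mg_dl <- NA_real_
  if (any(tg_ok))
    analysis$ldl_mg_dl[tg_ok] <- friedewald_ldl(
      analysis$tc_mg_dl[tg_ok], analysis$hdl_mg_dl[tg_ok],
      analysis$tg_mg_dl[tg_ok])

  table1 <- make_table1(analysis)
  corr <- .correlation_stage(analysis, config)
  regressions <- .regression_stage(analysis, config)
  concordance <- .concordance_stage(analysis, config)

  log <- list(seed = config$seed, n_total = n_total,
              n_complete = nrow(analysis),
              n_dropped = length(dropped), dropped_ids = dropped,
              t_df = config$t_df, huber_tuning = config$huber_tuning,
              bootstrap_B = config$bootstrap_B,
              r_version = R.version.string,
              package_version =
                as.character(utils::packageVersion("clampval")))

  structure(list(config = config, analysis = analysis, s_true = s_true,
                 table1 = table1, correlations = corr$correlations,
                 correlation_matrices = corr$matrices,
                 steiger = corr$steiger, figure_data = corr$figure_data,
                 regressions = regressions, concordance = concordance,
                 log = log),
            class = "index_validation")
}

# correlations of every surrogate with m_adjusted, per stratum, plus
# Williams-Steiger comparisons between surrogates (signs aligned so that
# every comparison is between sensitivity-oriented correlations)
.correlation_stage <- function(analysis, config) {
  strata <- list(all = rep(TRUE, nrow(analysis)),
                 male = analysis$sex == "M",
                 female = analysis$sex == "F")
  sur <- .SURROGATES
  corr_rows <- list(); steiger_rows <- list(); mats <- list()
  fig_scatter <- list(); fig_lines <- list()
  for (st in names(strata)) {
    sel <- strata[[st]]
    dat <- analysis[sel, , drop = FALSE]
    X <- as.matrix(dat[, c(sur$column, "m_adjusted")])
    colnames(X) <- c(sur$name, "m_adjusted")
    rcm <- robust_cor_matrix(X, df = config$t_df)
    mats[[st]] <- rcm
    n <- rcm$n
    for (i in seq_len(nrow(sur))) {
      r <- rcm$r["m_adjusted", sur$name[i]]
      ci <- corr_ci(r, n)
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        stratum = st, surrogate = sur$name[i], r = r,
        ci_low = ci[1], ci_high = ci[2], n = n,
        lambda = rcm$lambda[sur$name[i]])
    }
    signs <- ifelse(sur$direction == "increasing", 1, -1)
    for (i in seq_len(nrow(sur) - 1)) for (j in (i + 1):nrow(sur)) {
      stg <- tryCatch(
        steiger_test(signs[i] * rcm$r["m_adjusted", sur$name[i]],
                     signs[j] * rcm$r["m_adjusted", sur$name[j]],
                     signs[i] * signs[j] * rcm$r[sur$name[i], sur$name[j]],
                     n),
        error = function(e) NULL)
      if (is.null(stg)) next
      steiger_rows[[length(steiger_rows) + 1L]] <- data.frame(
        stratum = st, surrogate_1 = sur$name[i],
        surrogate_2 = sur$name[j], t_stat = stg$t_stat, df = stg$df,
        p_value = stg$p_value)
    }
    # Box-Cox scatter and straight-line coordinates for redrawing the
    # correlation panels
    my <- boxcox_transform(dat$m_adjusted, rcm$lambda["m_adjusted"])
    for (i in seq_len(nrow(sur))) {
      xv <- boxcox_transform(dat[[sur$column[i]]],
                             rcm$lambda[sur$name[i]])
      if (st == "all")
        fig_scatter[[sur$name[i]]] <- data.frame(
          surrogate = sur$name[i], subject_id = dat$subject_id,
          sex = dat$sex, x_transformed = xv, m_transformed = my)
      cf <- stats::coef(stats::lm(my ~ xv))
      fig_lines[[length(fig_lines) + 1L]] <- data.frame(
        surrogate = sur$name[i], stratum = st,
        intercept = cf[1], slope = cf[2])
    }
  }
  list(correlations = do.call(rbind, corr_rows),
       steiger = do.call(rbind, steiger_rows),
       matrices = mats,
       figure_data = list(scatter = do.call(rbind, fig_scatter),
                          lines = do.call(rbind, fig_lines)))
}

# robust fits: adiposity-only models plus one model per fasting index
# (index + sex + waist), everything on Box-Cox scales
.regression_stage <- function(analysis, config) {
  bc <- function(x) boxcox_transform(x, boxcox_lambda(x))
  y <- bc(analysis$m_adjusted)
  female <- as.numeric(analysis$sex == "F")
  adip <- list(bmi = bc(analysis$bmi), waist = bc(analysis$waist_cm),
               whtr = bc(analysis$whtr))
  models <- list(
    bmi = cbind(`(Intercept)` = 1, sex_female = female, bmi = adip$bmi),
    waist = cbind(`(Intercept)` = 1, sex_female = female,
                  waist = adip$waist),
    whtr = cbind(`(Intercept)` = 1, sex_female = female, whtr = adip$whtr),
    bmi_wc = cbind(`(Intercept)` = 1, sex_female = female,
                   bmi = adip$bmi, waist = adip$waist))
  for (idx in c("fasting_insulin", "homa_ir", "quicki", "firi",
                "gi_ratio")) {
    col <- .SURROGATES$column[.SURROGATES$name == idx]
    X <- cbind(`(Intercept)` = 1, sex_female = female,
               index = bc(analysis[[col]]), waist = adip$waist)
    models[[idx]] <- X
  }
  lapply(models, function(X)
    fit_huber(y, X, tuning = config$huber_tuning))
}

# tertile cross-classification against clamp thirds, with bootstrap
# kappa intervals (thirds are sex-specific; pooled for "all")
.concordance_stage <- function(analysis, config) {
  sur <- .SURROGATES
  out <- list()
  for (i in seq_len(nrow(sur))) {
    xv <- analysis[[sur$column[i]]]
    dir <- sur$direction[i]
    per_stratum <- list()
    # all subjects: sex-specific thirds, pooled
    ref <- sexwise_thirds(analysis$m_adjusted, analysis$sex, "increasing")
    tst <- sexwise_thirds(xv, analysis$sex, dir)
    cc <- cross_classify(ref, tst, stratum = "all")
    cc$kappa_ci <- bootstrap_kappa_ci(analysis$m_adjusted, xv,
                                      sex = analysis$sex, direction = dir,
                                      B = config$bootstrap_B)
    per_stratum$all <- cc
    for (st in c("male", "female")) {
      sel <- analysis$sex == if (st == "male") "M" else "F"
      if (sum(sel) < 6) next
      cc <- cross_classify(assign_thirds(analysis$m_adjusted[sel],
                                         "increasing"),
                           assign_thirds(xv[sel], dir), stratum = st)
      cc$kappa_ci <- bootstrap_kappa_ci(analysis$m_adjusted[sel], xv[sel],
                                        direction = dir,
                                        B = config$bootstrap_B)
      per_stratum[[st]] <- cc
    }
    out[[sur$name[i]]] <- per_stratum
  }
  out
}

#' @export
print.index_validation <- function(x, ...) {
  cat("Index-validation analysis\n")
  cat("  n =", x$log$n_complete, "complete cases of", x$log$n_total,
      "subjects (", x$log$n_dropped, "dropped )\n")
  ov <- x$correlations[x$correlations$stratum == "all", ]
  cat("  Correlations with clamp M (all subjects):\n")
  for (i in seq_len(nrow(ov)))
    cat(sprintf("    %-16s r = %5.2f (%5.2f to %5.2f)\n", ov$surrogate[i],
                ov$r[i], ov$ci_low[i], ov$ci_high[i]))
  r2 <- vapply(x$regressions, function(f) f$r_squared, numeric(1))
  cat(sprintf("  Robust-model R^2 range: %.2f to %.2f\n",
              min(r2), max(r2)))
  kap <- vapply(x$concordance, function(cs) cs$all$kappa, numeric(1))
  cat(sprintf("  Tertile kappa vs clamp (all): %.2f to %.2f\n",
              min(kap), max(kap)))
  invisible(x)
}

#' @export
summary.index_validation <- function(object, ...) {
  print(object)
  cat("\nSteiger comparisons (all subjects, p < 0.05):\n")
  sg <- object$steiger[object$steiger$stratum == "all" &
                         object$steiger$p_value < 0.05, ]
  if (nrow(sg) == 0) cat("  none\n") else
    for (i in seq_len(nrow(sg)))
      cat(sprintf("    %s vs %s: t = %.2f, p = %.4f\n", sg$surrogate_1[i],
                  sg$surrogate_2[i], sg$t_stat[i], sg$p_value[i]))
  invisible(object)
}

#' Write the full report bundle
#'
#' Writes tab-separated reports for each analysis stage, the figure
#' coordinate data, and a JSON run log into a directory.
#'
#' @param x an [run_validation()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_validation_report <- function(x, dir) {
  stopifnot(inherits(x, "index_validation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_table1_tsv(x$table1, file.path(dir, "table1.tsv"))
  tsv(x$correlations, "correlations.tsv")
  tsv(x$steiger, "steiger.tsv")
  reg <- do.call(rbind, lapply(names(x$regressions), function(nm) {
    f <- x$regressions[[nm]]
    data.frame(model = nm, term = names(f$coefficients),
               beta = f$coefficients, se = f$std_errors,
               p = f$p_values, r_squared = f$r_squared,
               row.names = NULL)
  }))
  tsv(reg, "regression.tsv")
  conc <- do.call(rbind, lapply(names(x$concordance), function(nm) {
    do.call(rbind, lapply(x$concordance[[nm]], function(cc)
      data.frame(surrogate = nm, stratum = cc$stratum,
                 pct_low = cc$pct_correct_by_ref["low"],
                 pct_medium = cc$pct_correct_by_ref["medium"],
                 pct_high = cc$pct_correct_by_ref["high"],
                 total_correct = round(cc$overall_correct * cc$n),
                 n = cc$n, kappa = cc$kappa,
                 kappa_ci_low = cc$kappa_ci[1],
                 kappa_ci_high = cc$kappa_ci[2], row.names = NULL)))
  }))
  tsv(conc, "concordance.tsv")
  tsv(x$figure_data$scatter, "figure1_scatter.tsv")
  tsv(x$figure_data$lines, "figure1_lines.tsv")
  jsonlite::write_json(x$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
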