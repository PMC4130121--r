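#' Group comparison tests for the cohort description
#'
#' `kruskal_wallis()` wraps the rank-based Kruskal-Wallis test (tie
#' corrected, chi-square reference with k - 1 df); identical values in
#' all groups return H = 0, p = 1 rather than an error.
#' `linear_trend_test()` tests for a linear trend of a variable over the
#' ordinal BMI-category scores 0/1/2 via the least-squares slope (t test,
#' two-sided). `interaction_test()` tests sex-by-category heterogeneity:
#' by default the 1-df product term sex x score in a linear model with
#' main effects; `two_df = TRUE` instead compares the full categorical
#' interaction model against the additive model by an F test.
#'
#' @param groups list of two or more numeric vectors.
#' @return `kruskal_wallis()`: list with `H` and `p`.
#' @name group-tests
NULL

#' @rdname group-tests
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' @rdname group-tests
#' @param values numeric vector.
#' @param category_scores ordinal scores (0/1/2 for lean/overweight/obese).
#' @export
linear_trend_test <- function(values, category_scores) {
  if (length(values) != length(category_scores))
    stop("'values' and 'category_scores' lengths differ", call. = FALSE)
  if (length(unique(category_scores)) < 2)
    stop("need at least 2 distinct category scores", call. = FALSE)
  if (length(values) < 3) stop("need at least 3 observations",
                               call. = FALSE)
  fit <- stats::lm(values ~ category_scores)
  co <- stats::coef(summary(fit))
  unname(co["category_scores", "Pr(>|t|)"])
}

#' @rdname group-tests
#' @param sex sex codes, at least 2 levels populated.
#' @param category BMI category (factor or scores).
#' @param two_df use the 2-df categorical interaction instead of the
#'   1-df ordinal-score product term?
#' @export
interaction_test <- function(values, sex, category, two_df = FALSE) {
  if (length(unique(sex)) < 2)
    stop("need both sexes to test an interaction", call. = FALSE)
  if (length(unique(category)) < 2)
    stop("need at least 2 BMI categories", call. = FALSE)
  sex <- factor(sex)
  if (two_df) {
    category <- factor(category)
    if (any(table(sex, category) == 0))
      stop("empty sex-by-category cell; interaction inestimable",
           call. = FALSE)
    full <- stats::lm(values ~ sex * category)
    add <- stats::lm(values ~ sex + category)
    an <- stats::anova(add, full)
    return(an[["Pr(>F)"]][2])
  }
  score <- if (is.factor(category) || is.character(category))
    as.numeric(factor(category, levels = c("lean", "overweight",
                                           "obese"))) - 1
  else as.numeric(category)
  fit <- stats::lm(values ~ sex + score + sex:score)
  co <- stats::coef(summary(fit))
  term <- grep(":score$|^score:", rownames(co), value = TRUE)
  if (length(term) != 1 || anyNA(co[term, ]))
    stop("interaction term inestimable (empty cell?)", call. = FALSE)
  unname(co[term, "Pr(>|t|)"])
}

# Table-1 row variables, in display order, with the analysis-frame column
# each summarises. "Plasma insulin" repeats the fasting insulin field
# under the fasting-indices block, as the study layout does.
.TABLE1_ROWS <- list(
  c("Age (years)", "age"),
  c("BMI (kg/m2)", "bmi"),
  c("Percent fat (%)", "percent_fat"),
  c("Waist circumference (cm)", "waist_cm"),
  c("Hip circumference (cm)", "hip_cm"),
  c("Waist-to-hip ratio", "whr"),
  c("Waist-to-height ratio", "whtr"),
  c("Systolic blood pressure (mmHg)", "sbp"),
  c("Diastolic blood pressure (mmHg)", "dbp"),
  c("Total cholesterol (mg/dL)", "tc_mg_dl"),
  c("Triglycerides (mg/dL)", "tg_mg_dl"),
  c("HDL cholesterol (mg/dL)", "hdl_mg_dl"),
  c("LDL cholesterol (mg/dL)", "ldl_mg_dl"),
  c("Fasting glucose (mmol/L)", "fasting_glucose_mmol_l"),
  c("Fasting insulin (uU/mL)", "fasting_insulin_uu_ml"),
  c("M unadjusted (mg/min/kg)", "m_unadjusted"),
  c("M adjusted to lean mass (mg/min/kg)", "m_adjusted"),
  c("Plasma insulin (uU/mL)", "fasting_insulin"),
  c("Glucose/Insulin ratio (mg/dL per uU/mL)", "gi_ratio"),
  c("HOMA-IR", "homa_ir"),
  c("FIRI", "firi"),
  c("QUICKI", "quicki"))

#' Cohort description by sex and BMI category
#'
#' Summarises every study variable as mean and SD within the six
#' sex-by-BMI-category strata and attaches, per sex, the Kruskal-Wallis
#' p across categories and the linear-trend p over ordinal category
#' scores, plus the sex-by-category interaction p (pooled sexes).
#'
#' @param analysis analysis data.frame containing `sex` (`"M"`/`"F"`),
#'   `bmi`, and the summarised variable columns (see [run_validation()]
#'   for how it is assembled).
#' @return data.frame, one row per variable: stratum means/SDs (columns
#'   `<sex>_<category>_mean`/`_sd`), per-sex test p-values and the
#'   interaction p. Stratum sizes are in attribute `stratum_n`. Empty
#'   strata give `NA` summaries and tests.
#' @export
make_table1 <- function(analysis) {
  stopifnot(is.data.frame(analysis), all(c("sex", "bmi") %in%
                                           names(analysis)))
  category <- bmi_category(analysis$bmi)
  sexes <- c(M = "male", F = "female")
  cats <- c("lean", "overweight", "obese")
  rows <- Filter(function(r) r[2] %in% names(analysis), .TABLE1_ROWS)
  out <- lapply(rows, function(rw) {
    v <- analysis[[rw[2]]]
    rec <- list(variable = rw[1])
    for (sx in names(sexes)) {
      for (ct in cats) {
        sel <- analysis$sex == sx & category == ct
        rec[[paste0(sexes[sx], "_", ct, "_mean")]] <-
          if (any(sel)) mean(v[sel]) else NA_real_
        rec[[paste0(sexes[sx], "_", ct, "_sd")]] <-
          if (sum(sel) > 1) stats::sd(v[sel]) else NA_real_
      }
      sel_sex <- analysis$sex == sx
      grps <- split(v[sel_sex], droplevels(category[sel_sex]))
      rec[[paste0("p_kruskal_", sexes[sx])]] <-
        if (length(grps) >= 2) kruskal_wallis(grps)$p else NA_real_
      sc <- as.numeric(category[sel_sex]) - 1
      rec[[paste0("p_linearity_", sexes[sx])]] <-
        if (length(unique(sc)) >= 2) linear_trend_test(v[sel_sex], sc)
        else NA_real_
    }
    rec$p_interaction <- tryCatch(
      interaction_test(v, analysis$sex, category),
      error = function(e) NA_real_)
    as.data.frame(rec, check.names = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "stratum_n") <- table(sex = analysis$sex, category = category)
  res
}

#' Write a Table-1-style TSV
#'
#' Formats [make_table1()] output as mean +/- SD strings with p-value
#' columns and writes it as tab-separated text.
#'
#' @param table1 output of [make_table1()].
#' @param path output file path.
#' @export
write_table1_tsv <- function(table1, path) {
  fm <- data.frame(variable = table1$variable)
  for (sx in c("male", "female")) {
    for (ct in c("lean", "overweight", "obese"))
      fm[[paste0(sx, "_", ct)]] <-
        .mean_sd(table1[[paste0(sx, "_", ct, "_mean")]],
                 table1[[paste0(sx, "_", ct, "_sd")]])
    fm[[paste0("p_kruskal_", sx)]] <-
      signif(table1[[paste0("p_kruskal_", sx)]], 2)
    fm[[paste0("p_linearity_", sx)]] <-
      signif(table1[[paste0("p_linearity_", sx)]], 2)
  }
  fm$p_interaction <- signif(table1$p_interaction, 2)
  utils::write.table(fm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
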