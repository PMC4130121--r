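# Synthetic cohort and clamp-trace generation.
#
# Latent construction: per subject a 4-variate standard normal
# (Z_S, Z_H, Z_B, Z_W) with the configured correlation matrix drives
# latent insulin sensitivity S_true (lognormal, sex-level moments matched
# to the reference M values), log HOMA-IR (normal, sex-level moments
# matched to the reference HOMA summaries), BMI (sex-level mixture over
# BMI categories, each category a moment-matched truncated normal on its
# bin, sampled through the Z_B quantile so BMI is monotone in Z_B), and
# waist (within-stratum normal at the Z_W quantile). Everything else is
# drawn per stratum, independent of the latent block.

# truncated-normal quantile for parent N(mean, sd) restricted to [lo, hi]
.qtnorm <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

# mean and sd of N(mean, sd) truncated to [lo, hi]
.tnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parent (mean, sd) whose [lo, hi]-truncation has the target moments.
# The mean is weighted much more heavily: when the target sd is not
# attainable under truncation (a tight bin, or a one-sided bin with a
# decaying target), the match keeps the mean and concedes spread.
.match_tnorm <- function(target_mean, target_sd, lo, hi) {
  obj <- function(par) {
    mo <- .tnorm_moments(par[1], exp(par[2]), lo, hi)
    100 * (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

# lognormal (meanlog, sdlog) matching a natural-scale mean and sd
.lnorm_params <- function(mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# pooled mean/sd of a variable across a set of reference groups
.sex_pooled <- function(groups, var) {
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, function(g) g[[var]][1], numeric(1))
  s <- vapply(groups, function(g) g[[var]][2], numeric(1))
  mu <- sum(n * m) / sum(n)
  # pooled variance: within + between components
  v <- sum(n * (s^2 + (m - mu)^2)) / sum(n)
  c(mean = mu, sd = sqrt(v))
}

.BMI_BINS <- list(lean = c(13, 25), overweight = c(25, 30),
                  obese = c(30, 80))

# positive normal draw per stratum (simple rejection at a floor)
.rnorm_pos <- function(n, mean, sd, lo = 0.1) {
  pmax(stats::rnorm(n, mean, sd), lo)
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` subject records whose stratum structure (sex x BMI
#' category frequencies, within-stratum anthropometry, lipids and blood
#' pressure) follows the configured group parameters, together with a
#' hidden per-subject latent insulin sensitivity `S_true` (mg/min/kg
#' fat-free mass) correlated with log HOMA-IR, BMI and waist through a
#' Gaussian copula. Fasting insulin is derived from the latent HOMA-IR and
#' the drawn fasting glucose, so corr(Box-Cox HOMA, Box-Cox S_true)
#' approaches the configured `s_homa` target as n grows. Fasting glucose
#' is truncated below the diabetes threshold (7 mmol/L).
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (data.frame of subject records, one row
#'   per subject) and `s_true` (numeric vector, the hidden latent insulin
#'   sensitivity of each subject).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  n_male <- round(n * spec$sex_ratio)
  sexes <- rep(c("male", "female"), c(n_male, n - n_male))
  R <- .latent_corr_matrix(spec$latent_structure)
  # latent S_true and log HOMA marginals are cohort-level (pooled over
  # all six reference strata), so the configured copula correlation is
  # also the cohort-level correlation; sex and BMI-category gradients in
  # insulin emerge through the copula coupling with adiposity
  all_groups <- c(spec$group_params$groups$male,
                  spec$group_params$groups$female)
  m_pool <- .sex_pooled(all_groups, "m_adjusted")
  g_pool <- .sex_pooled(all_groups, "fasting_glucose")
  i_pool <- .sex_pooled(all_groups, "fasting_insulin")
  homa_mean <- g_pool["mean"] * i_pool["mean"] / 22.5
  homa_sd <- homa_mean * sqrt((g_pool["sd"] / g_pool["mean"])^2 +
                                (i_pool["sd"] / i_pool["mean"])^2)
  latent <- list(s = .lnorm_params(m_pool["mean"], m_pool["sd"]),
                 homa = .lnorm_params(homa_mean, homa_sd))
  out <- vector("list", 2L)
  names(out) <- c("male", "female")
  for (sx in c("male", "female")) {
    ns <- sum(sexes == sx)
    if (ns == 0L) next
    out[[sx]] <- .generate_sex_block(ns, sx, spec, R, latent)
  }
  subjects <- do.call(rbind, lapply(out[!vapply(out, is.null, logical(1))],
                                    `[[`, "subjects"))
  s_true <- unlist(lapply(out[!vapply(out, is.null, logical(1))],
                          `[[`, "s_true"), use.names = FALSE)
  subjects$subject_id <- sprintf("S%03d", seq_len(nrow(subjects)))
  rownames(subjects) <- NULL
  list(subjects = subjects, s_true = s_true)
}

.generate_sex_block <- function(ns, sx, spec, R, latent) {
  gp <- spec$group_params$groups[[sx]]
  cats <- c("lean", "overweight", "obese")
  n_cat <- vapply(gp[cats], function(g) as.numeric(g$n), numeric(1))
  p_cat <- n_cat / sum(n_cat)
  cum <- cumsum(p_cat)

  Z <- MASS::mvrnorm(ns, mu = rep(0, 4), Sigma = R)
  if (ns == 1L) Z <- matrix(Z, nrow = 1)

  s_true <- exp(latent$s["meanlog"] + latent$s["sdlog"] * Z[, 1])
  homa <- exp(latent$homa["meanlog"] + latent$homa["sdlog"] * Z[, 2])

  # BMI through the sex-level category mixture, monotone in Z_B
  u_b <- stats::pnorm(Z[, 3])
  cat_idx <- findInterval(u_b, cum) + 1L  # 1..3
  cat_idx[cat_idx > 3L] <- 3L
  category <- cats[cat_idx]
  lo_p <- c(0, cum)[cat_idx]
  u_in <- (u_b - lo_p) / p_cat[cat_idx]  # rescaled within-band quantile
  bmi <- numeric(ns)
  for (k in seq_along(cats)) {
    sel <- cat_idx == k
    if (!any(sel)) next
    bin <- .BMI_BINS[[cats[k]]]
    par <- .match_tnorm(gp[[cats[k]]]$bmi[1], gp[[cats[k]]]$bmi[2],
                        bin[1], bin[2])
    bmi[sel] <- .qtnorm(u_in[sel], par["mean"], par["sd"], bin[1], bin[2])
  }

  # waist within stratum at the Z_W quantile (monotone within stratum;
  # the between-stratum gradient comes from the category assignment)
  u_w <- stats::pnorm(Z[, 4])
  waist <- numeric(ns)
  for (k in seq_along(cats)) {
    sel <- cat_idx == k
    if (!any(sel)) next
    w <- gp[[cats[k]]]$waist
    waist[sel] <- .qtnorm(u_w[sel], w[1], w[2], 40, 200)
  }

  hpars <- spec$group_params$height_cm[[sx]]
  height <- .rnorm_pos(ns, hpars[1], hpars[2], lo = 120)
  weight <- bmi * (height / 100)^2

  draw <- function(var, lo = 0.1, hi = Inf) {
    x <- numeric(ns)
    for (k in seq_along(cats)) {
      sel <- cat_idx == k
      if (!any(sel)) next
      pr <- gp[[cats[k]]][[var]]
      x[sel] <- .qtnorm(stats::runif(sum(sel)), pr[1], pr[2], lo, hi)
    }
    x
  }
  age <- draw("age", lo = 18, hi = 75)
  pfat <- draw("percent_fat", lo = 3, hi = 60)
  hip <- draw("hip", lo = 50, hi = 200)
  sbp <- draw("sbp", lo = 80, hi = 220)
  dbp <- draw("dbp", lo = 45, hi = 130)
  tg <- draw("tg", lo = 20, hi = 399)
  hdl <- draw("hdl", lo = 20, hi = 130)
  tc <- pmax(draw("tc", lo = 80, hi = 400), hdl + tg / 5 + 5)
  glucose <- draw("fasting_glucose", lo = 3.0, hi = 6.95)
  insulin <- homa * 22.5 / glucose

  subjects <- data.frame(
    subject_id = NA_character_,
    sex = ifelse(sx == "male", "M", "F"),
    age = age, height_cm = height, weight_kg = weight,
    bmi = bmi, waist_cm = waist, hip_cm = hip,
    whtr = waist / height, percent_fat = pfat,
    fat_free_mass_kg = weight * (1 - pfat / 100),
    fasting_glucose_mmol_l = glucose,
    fasting_insulin_uu_ml = insulin,
    tc_mg_dl = tc, hdl_mg_dl = hdl, tg_mg_dl = tg,
    sbp = sbp, dbp = dbp,
    stringsAsFactors = FALSE)
  list(subjects = subjects, s_true = as.numeric(s_true))
}

#' Simulate one subject's clamp trace
#'
#' Builds a 0-100 min clamp record on a 5-minute grid. Blood glucose
#' approaches the subject's individual steady-state level (the 100 mg/dL
#' target plus a between-subject offset) linearly over the first 40 min
#' and then stays there up to within-window noise at the configured CV.
#' The glucose infusion rate ramps up over the first 60 min and plateaus
#' at `S_true x fat_free_mass x (achieved glucose / 100)` mg/min --
#' uptake scales with the clamped glucose level by mass action, which is
#' exactly what the glucose-space correction removes -- so the expected
#' within-window mean GIR equals `S_true x FFM` at the 100 mg/dL target,
#' with multiplicative noise. Plasma
#' insulin is sampled at 0/80/90/100 min; the steady-state level is the
#' fasting level plus the infusion-driven increment (per-BSA dosing and
#' BSA-proportional clearance by the Du Bois formula cancel, giving
#' `rate / 0.6` uU/mL) with multiplicative noise.
#'
#' @param subject one-row data.frame of subject fields (as produced by
#'   [generate_cohort()]).
#' @param s_true latent insulin sensitivity, mg/min/kg fat-free mass.
#' @param spec a [cohort_spec()] supplying the noise levels.
#' @param ss_glucose_target the subject's individual steady-state glucose
#'   level, mg/dL; by default drawn as `100 + N(0, noise$ss_glucose_sd)`.
#' @return a [clamp_trace()].
#' @export
generate_clamp_trace <- function(subject, s_true, spec,
                                 ss_glucose_target = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  .check_positive(s_true, "s_true")
  ns <- spec$noise
  if (is.null(ss_glucose_target))
    ss_glucose_target <- 100 + stats::rnorm(1, 0, ns$ss_glucose_sd)
  time <- seq(0, 100, by = 5)
  g0 <- convert_glucose(subject$fasting_glucose_mmol_l, "mmol/L", "mg/dL")
  approach <- pmax(0, 1 - time / 40)
  glucose <- ss_glucose_target + (g0 - ss_glucose_target) * approach
  glucose <- glucose * (1 + stats::rnorm(length(time), 0,
                                         ns$glucose_cv / 100))
  # mass action: uptake scales with the achieved glucose level, which is
  # exactly the between-subject difference the glucose-space correction
  # removes downstream
  plateau <- s_true * subject$fat_free_mass_kg * ss_glucose_target / 100
  gir <- plateau * pmin(1, time / 60) *
    (1 + stats::rnorm(length(time), 0, ns$gir_sd))
  gir <- pmax(gir, 0)
  # Du Bois body surface area; dose and clearance are both per-BSA so the
  # steady-state increment is size-independent
  bsa <- 0.007184 * subject$weight_kg^0.425 * subject$height_cm^0.725
  dose <- spec$group_params$insulin_infusion_rate %||% 80
  increment <- (dose * bsa) / (0.6 * bsa)
  i_ss <- subject$fasting_insulin_uu_ml + increment
  insulin <- rep(NA_real_, length(time))
  at <- function(t) which.min(abs(time - t))
  insulin[at(0)] <- subject$fasting_insulin_uu_ml
  for (t in c(80, 90, 100))
    insulin[at(t)] <- i_ss * (1 + stats::rnorm(1, 0, ns$insulin_cv / 100))
  clamp_trace(subject$subject_id, time, glucose, gir, insulin,
              insulin_infusion_rate = dose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete clamp study
#'
#' Generates a cohort and one clamp trace per subject under a single seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects`, `s_true` and `traces` (list of
#'   [clamp_trace()] objects, in subject order).
#' @export
simulate_study <- function(spec) {
  coh <- generate_cohort(spec)  # sets the seed if spec$seed is given
  traces <- lapply(seq_len(nrow(coh$subjects)), function(i)
    generate_clamp_trace(coh$subjects[i, , drop = FALSE],
                         coh$s_true[i], spec))
  c(coh, list(traces = traces))
}
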