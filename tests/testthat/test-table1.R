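test_that("Kruskal-Wallis wrapper matches a hand rank computation", {
  # identical distributions across groups: H = 0, p = 1 path
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(list(c(5, 5, 5), c(5, 5)))$p, 1)

  # well-separated groups: H from first principles (no ties)
  g <- list(c(1, 2, 3), c(11, 12, 13), c(21, 22, 23))
  kw <- kruskal_wallis(g)
  x <- unlist(g)
  rk <- rank(x)
  grp <- rep(seq_along(g), lengths(g))
  N <- length(x)
  H_hand <- 12 / (N * (N + 1)) *
    sum(tapply(rk, grp, sum)^2 / lengths(g)) - 3 * (N + 1)
  expect_equal(kw$H, H_hand)
  expect_lt(kw$p, 0.05)

  # two groups: H equals the squared standardised rank-sum statistic
  g2 <- list(c(1, 5, 7, 3), c(10, 2, 8, 9, 6))
  kw2 <- kruskal_wallis(g2)
  r1 <- sum(rank(unlist(g2))[1:4])
  n1 <- 4; n2 <- 5; N2 <- 9
  z <- (r1 - n1 * (N2 + 1) / 2) / sqrt(n1 * n2 * (N2 + 1) / 12)
  expect_equal(kw2$H, z^2)
})

test_that("linear trend test recovers the closed-form slope inference", {
  # small exact case against textbook least-squares formulas
  v <- c(1, 2, 4, 3, 5, 9)
  s <- c(0, 0, 1, 1, 2, 2)
  p <- linear_trend_test(v, s)
  fit <- summary(lm(v ~ s))
  expect_equal(p, fit$coefficients["s", "Pr(>|t|)"])
  b <- cov(v, s) / var(s)
  se <- sqrt(sum(residuals(lm(v ~ s))^2 / 4) / sum((s - mean(s))^2))
  expect_equal(p, 2 * pt(-abs(b / se), df = 4))

  # strong monotone trend is detected
  set.seed(401)
  sc <- rep(0:2, each = 30)
  expect_lt(linear_trend_test(5 + 2 * sc + rnorm(90, sd = 0.5), sc), 0.01)
  expect_error(linear_trend_test(1:5, rep(0, 5)), "distinct")
})

test_that("trend test holds its size under permuted category labels", {
  set.seed(402)
  v <- rlnorm(45)
  sc <- rep(0:2, each = 15)
  rejections <- 0L
  n_sim <- 1000
  for (i in seq_len(n_sim))
    if (linear_trend_test(v, sample(sc)) < 0.05)
      rejections <- rejections + 1L
  expect_gte(rejections / n_sim, 0.03)
  expect_lte(rejections / n_sim, 0.07)
})

test_that("interaction test detects crossing effects and is null-calibrated", {
  set.seed(403)
  sex <- rep(c("M", "F"), each = 60)
  cat <- factor(rep(rep(c("lean", "overweight", "obese"), each = 20), 2),
                levels = c("lean", "overweight", "obese"))
  score <- as.numeric(cat) - 1
  # additive model: interaction should rarely fire
  v_add <- 2 + score + 0.5 * (sex == "F") + rnorm(120, sd = 0.3)
  rej <- 0L
  for (i in 1:400) {
    v_sim <- 2 + score + 0.5 * (sex == "F") + rnorm(120, sd = 0.3)
    if (interaction_test(v_sim, sex, cat) < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 400, 0.02)
  expect_lte(rej / 400, 0.09)
  # crossing interaction: slope +1 in men, -1 in women
  v_cross <- 2 + score * ifelse(sex == "M", 1, -1) + rnorm(120, sd = 0.3)
  expect_lt(interaction_test(v_cross, sex, cat), 0.01)
  # 2-df variant agrees qualitatively
  expect_lt(interaction_test(v_cross, sex, cat, two_df = TRUE), 0.01)
  expect_error(interaction_test(v_add, rep("M", 120), cat), "both sexes")
  expect_error(interaction_test(v_add, sex, rep("lean", 120)),
               "categories")
})

test_that("the cohort description has the study layout and identities", {
  sim <- simulate_study(small_spec(n = 87, seed = 12))
  mv <- m_value_cohort(sim$traces, sim$subjects)
  analysis <- cbind(sim$subjects,
                    fasting_indices(sim$subjects$fasting_glucose_mmol_l,
                                    sim$subjects$fasting_insulin_uu_ml),
                    mv[, c("m_unadjusted", "m_adjusted")])
  analysis$whr <- analysis$waist_cm / analysis$hip_cm
  analysis$ldl_mg_dl <- friedewald_ldl(analysis$tc_mg_dl,
                                       analysis$hdl_mg_dl,
                                       analysis$tg_mg_dl)
  tb <- make_table1(analysis)
  expect_equal(nrow(tb), 22L)  # every study variable row
  expect_equal(sum(attr(tb, "stratum_n")), 87)
  # FIRI row = 0.9 x HOMA row, elementwise across all strata
  homa_row <- tb[tb$variable == "HOMA-IR", grepl("_mean$|_sd$", names(tb))]
  firi_row <- tb[tb$variable == "FIRI", grepl("_mean$|_sd$", names(tb))]
  expect_equal(unname(unlist(firi_row)), 0.9 * unname(unlist(homa_row)))
  # p-value columns lie in [0, 1]
  pcols <- unlist(tb[, grepl("^p_", names(tb))])
  expect_true(all(pcols >= 0 & pcols <= 1, na.rm = TRUE))
  # stratum BMI means are plausible for their category bins
  expect_lt(tb[tb$variable == "BMI (kg/m2)", "male_lean_mean"], 25)
  expect_gt(tb[tb$variable == "BMI (kg/m2)", "male_obese_mean"], 30)
  # TSV writer produces one line per variable plus header
  path <- tempfile(fileext = ".tsv")
  write_table1_tsv(tb, path)
  expect_equal(length(readLines(path)), 23L)
})
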