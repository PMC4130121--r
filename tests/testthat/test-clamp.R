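test_that("steady-state summary of a flat trace is exact", {
  tr <- flat_trace(gir = 700, glucose = 100, insulin_ss = 150)
  ss <- steady_state_summary(tr)
  expect_equal(ss$mean_gir, 700)
  expect_equal(ss$ss_glucose, 100)
  expect_equal(ss$cv_glucose, 0)
  expect_equal(ss$ss_insulin, 150)
})

test_that("steady-state summary matches an independent recomputation", {
  set.seed(21)
  times <- seq(0, 100, 5)
  glucose <- 100 + rnorm(length(times), 0, 2)
  gir <- 600 + rnorm(length(times), 0, 30)
  tr <- clamp_trace("X", times, glucose, gir)
  ss <- steady_state_summary(tr)
  # spreadsheet-style oracle: direct subsetting and base mean/sd
  inw <- times >= 80 & times <= 100
  expect_equal(ss$mean_gir, sum(gir[inw]) / sum(inw))
  expect_equal(ss$ss_glucose, sum(glucose[inw]) / sum(inw))
  expect_equal(ss$cv_glucose, 100 * sd(glucose[inw]) / mean(glucose[inw]))
  expect_true(is.na(ss$ss_insulin))  # no insulin sampled
})

test_that("window and sampling preconditions are enforced", {
  short <- clamp_trace("S", seq(0, 60, 5), rep(100, 13), rep(500, 13))
  expect_error(steady_state_summary(short), "window")
  sparse <- clamp_trace("S", c(0, 40, 80, 100), rep(100, 4), rep(500, 4))
  expect_error(steady_state_summary(sparse), "fewer than 3")
  expect_error(clamp_trace("S", c(0, 5, 5), rep(100, 3), rep(1, 3)),
               "increasing")
  expect_error(clamp_trace("S", c(0, 5, 10), c(100, -1, 100), rep(1, 3)),
               "glucose")
})

test_that("high within-window glucose variability is flagged, not dropped", {
  times <- seq(0, 100, 5)
  glucose <- rep(100, length(times))
  glucose[times >= 80] <- c(90, 100, 110, 95, 105)
  tr <- clamp_trace("CV", times, glucose, rep(500, length(times)))
  expect_warning(ss <- steady_state_summary(tr), "CV")
  expect_gt(ss$cv_glucose, 5)
  expect_equal(ss$mean_gir, 500)
})

test_that("glucose-space correction is group mean over individual", {
  expect_equal(glucose_space_correction(100, 100), 1)
  expect_equal(glucose_space_correction(90, 100), 100 / 90)
  expect_equal(glucose_space_correction(110, 100), 100 / 110)
  expect_error(glucose_space_correction(0, 100), "individual")
})

test_that("M value normalises corrected GIR by FFM and weight", {
  tr <- flat_trace(gir = 700, glucose = 100)
  m <- m_value(tr, weight = 100, fat_free_mass = 70,
               group_mean_ss_glucose = 100)
  expect_equal(m$space_correction, 1)
  expect_equal(m$m_adjusted, 10)
  expect_equal(m$m_unadjusted, 7)
  expect_equal(m$m_over_i, 10 / 150)
  expect_gte(m$m_adjusted, m$m_unadjusted)  # FFM <= weight
  expect_error(m_value(tr, weight = 0, fat_free_mass = 70, 100), "weight")
})

test_that("M value is invariant to time shifts keeping the window on the plateau", {
  times <- seq(0, 100, 5)
  gir <- 650 * pmin(1, times / 60)
  glucose <- rep(100, length(times))
  base <- m_value(clamp_trace("A", times, glucose, gir), 90, 60, 100)
  shifted <- m_value(clamp_trace("A", times + 5, glucose, gir), 90, 60, 100)
  expect_equal(shifted$m_adjusted, base$m_adjusted)
  expect_equal(shifted$m_unadjusted, base$m_unadjusted)
})

test_that("scaling GIR by c scales both M outputs by c exactly", {
  set.seed(4)
  times <- seq(0, 100, 5)
  gir <- 500 + rnorm(length(times), 0, 20)
  glucose <- 100 + rnorm(length(times), 0, 1.5)
  for (c_fac in c(0.5, 2, 7.3)) {
    m1 <- m_value(clamp_trace("A", times, glucose, gir), 80, 55, 100)
    m2 <- m_value(clamp_trace("A", times, glucose, c_fac * gir), 80, 55,
                  100)
    expect_equal(m2$m_adjusted, c_fac * m1$m_adjusted)
    expect_equal(m2$m_unadjusted, c_fac * m1$m_unadjusted)
  }
})

test_that("cohort M computation uses the analysis-set group mean glucose", {
  subjects <- data.frame(subject_id = c("A", "B"),
                         weight_kg = c(80, 90),
                         fat_free_mass_kg = c(60, 65))
  traces <- list(flat_trace("A", gir = 600, glucose = 95),
                 flat_trace("B", gir = 700, glucose = 105))
  mv <- m_value_cohort(traces, subjects)
  expect_equal(attr(mv, "group_mean_ss_glucose"), 100)
  expect_equal(mv$space_correction, c(100 / 95, 100 / 105))
  expect_equal(mv$m_adjusted, c(600 * 100 / 95 / 60, 700 * 100 / 105 / 65))
  # identical steady-state glucose in all subjects -> corrections all 1
  traces_eq <- list(flat_trace("A", gir = 600, glucose = 100),
                    flat_trace("B", gir = 700, glucose = 100))
  mv_eq <- m_value_cohort(traces_eq, subjects)
  expect_equal(mv_eq$space_correction, c(1, 1))
  expect_error(m_value_cohort(traces, subjects[1, ]), "missing ids")
})
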