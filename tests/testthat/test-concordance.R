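test_that("tertile assignment follows ranks and direction", {
  inc <- assign_thirds(1:9, "increasing")
  expect_equal(as.character(inc),
               rep(c("low", "medium", "high"), each = 3))
  dec <- assign_thirds(1:9, "decreasing")
  expect_equal(as.character(dec),
               rep(c("high", "medium", "low"), each = 3))
  # order of input values does not matter, only their ranks
  shuffled <- c(5, 9, 1, 7, 3, 8, 2, 6, 4)
  expect_equal(as.character(assign_thirds(shuffled, "increasing")),
               c("medium", "high", "low", "high", "low", "high", "low",
                 "medium", "medium"))
})

test_that("uneven group sizes put the extra members at the extremes", {
  t7 <- table(assign_thirds(1:7, "increasing"))
  expect_equal(unname(as.vector(t7)), c(3, 2, 2))
  t8 <- table(assign_thirds(1:8, "increasing"))
  expect_equal(unname(as.vector(t8)), c(3, 2, 3))
  expect_error(assign_thirds(1:2), "at least 3")
  expect_error(assign_thirds(c(1, NA, 3, 4)), "missing")
})

test_that("boundary ties resolve by stable original-order ranking", {
  expect_warning(out <- assign_thirds(c(1, 2, 2, 2, 3, 4), "increasing"),
                 "tie")
  # ranks (ties first): 1,2,3,4,5,6 -> groups of 2
  expect_equal(as.character(out),
               c("low", "low", "medium", "medium", "high", "high"))
  # deterministic: repeated calls agree
  expect_identical(suppressWarnings(assign_thirds(c(1, 2, 2, 2, 3, 4))),
                   suppressWarnings(assign_thirds(c(1, 2, 2, 2, 3, 4))))
})

test_that("sexwise thirds are assigned within sex and pooled", {
  vals <- c(1:6, 101:106)
  sex <- rep(c("M", "F"), each = 6)
  th <- sexwise_thirds(vals, sex, "increasing")
  expect_equal(as.character(th[1:6]),
               c("low", "low", "medium", "medium", "high", "high"))
  expect_equal(as.character(th[7:12]),
               c("low", "low", "medium", "medium", "high", "high"))
})

test_that("cross-classification counts, percentages and kappa are coherent", {
  lv <- c("low", "medium", "high")
  ref <- factor(rep(lv, each = 5), levels = lv)
  # identical categorisation: diagonal table, 100% per category, kappa 1
  cc <- cross_classify(ref, ref)
  expect_equal(unname(diag(cc$table)), c(5, 5, 5))
  expect_equal(unname(cc$pct_correct_by_ref), c(100, 100, 100))
  expect_equal(cc$overall_correct, 1)
  expect_equal(cc$kappa, 1)
  # complete relabeling low->medium->high->low: zero diagonal
  shifted <- factor(lv[c(2, 3, 1)][as.integer(ref)], levels = lv)
  cc0 <- cross_classify(ref, shifted)
  expect_equal(sum(diag(cc0$table)), 0)
  expect_equal(cc0$overall_correct, 0)
  expect_lt(cc0$kappa, 0)
  expect_error(cross_classify(ref, ref[1:5]), "lengths differ")
})

test_that("independent categorisations agree about a third of the time", {
  set.seed(301)
  n <- 1e4
  a <- assign_thirds(runif(n))
  b <- assign_thirds(runif(n))
  cc <- cross_classify(a, b)
  expect_lt(abs(cc$overall_correct - 1 / 3), 0.02)
  expect_lt(abs(cc$kappa), 0.03)
})

test_that("Cohen's kappa matches hand calculations and reference code", {
  expect_equal(cohen_kappa(diag(c(5, 5, 5))), 1)
  # all rows identical: observed = expected, kappa 0
  tb <- matrix(rep(c(2, 3, 5), 3), 3, byrow = TRUE)
  expect_equal(cohen_kappa(tb), 0)
  # uniform margins 15/15/15 with diagonal 30 of 45: po=2/3, pe=1/3
  tb3 <- matrix(c(10, 2.5, 2.5, 2.5, 10, 2.5, 2.5, 2.5, 10), 3)
  expect_equal(cohen_kappa(tb3), 0.5)
  # agreement with the reference implementation on a random table
  set.seed(302)
  tb4 <- matrix(rpois(9, 8) + 1, 3)
  expect_equal(cohen_kappa(tb4),
               e1071::classAgreement(tb4)$kappa, tolerance = 1e-12)
  expect_error(cohen_kappa(matrix(c(3, 0, 0, 0), 2)), "degenerate")
  expect_error(cohen_kappa(matrix(1:6, 2)), "square")
})

test_that("kappa is invariant to simultaneous relabeling", {
  set.seed(303)
  tb <- matrix(rpois(9, 5) + 1, 3)
  perm <- c(3, 1, 2)
  expect_equal(cohen_kappa(tb[perm, perm]), cohen_kappa(tb))
})

test_that("tertile kappa is invariant to monotone transforms of the index", {
  set.seed(304)
  m <- rlnorm(79, 2.3, 0.3)
  homa <- rlnorm(79, 0.2, 0.5)
  ref <- assign_thirds(m, "increasing")
  k_homa <- cross_classify(ref, assign_thirds(homa, "decreasing"))$kappa
  k_firi <- cross_classify(ref, assign_thirds(0.9 * homa,
                                              "decreasing"))$kappa
  k_log <- cross_classify(ref, assign_thirds(log(homa),
                                             "decreasing"))$kappa
  expect_identical(k_homa, k_firi)
  expect_identical(k_homa, k_log)
  # a surrogate that is a monotone transform of the reference agrees fully
  k_perfect <- cross_classify(ref, assign_thirds(exp(-m),
                                                 "decreasing"))$kappa
  expect_equal(k_perfect, 1)
})

test_that("bootstrap kappa interval is deterministic and collapses under perfect agreement", {
  set.seed(305)
  m <- rlnorm(30, 2.3, 0.3)
  perfect <- bootstrap_kappa_ci(m, exp(-m), direction = "decreasing",
                                B = 200, seed = 99)
  expect_equal(unname(perfect), c(1, 1), ignore_attr = TRUE)
  x <- rlnorm(30, 0.2, 0.5)
  ci1 <- bootstrap_kappa_ci(m, x, direction = "decreasing", B = 300,
                            seed = 42)
  ci2 <- bootstrap_kappa_ci(m, x, direction = "decreasing", B = 300,
                            seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
  expect_error(bootstrap_kappa_ci(m[1:4], x[1:4], B = 200), "at least 6")
})

test_that("bootstrap kappa interval approximately covers the true kappa", {
  # population truth estimated once by a large Monte Carlo draw from the
  # same bivariate lognormal model
  rho <- 0.6
  draw <- function(n) {
    z <- MASS::mvrnorm(n, c(0, 0),
                       matrix(c(1, rho, rho, 1), 2))
    list(m = exp(2.3 + 0.3 * z[, 1]), x = exp(0.2 + 0.5 * z[, 2]))
  }
  set.seed(306)
  big <- draw(2e5)
  kappa_true <- cross_classify(assign_thirds(big$m),
                               assign_thirds(big$x))$kappa
  hits <- 0L
  n_rep <- 120
  for (i in seq_len(n_rep)) {
    d <- draw(60)
    ci <- suppressWarnings(bootstrap_kappa_ci(d$m, d$x, B = 250))
    if (ci[1] <= kappa_true && kappa_true <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.85)
  expect_lte(hits / n_rep, 1.0)
})
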