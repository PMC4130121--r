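test_that("Box-Cox transform matches its closed form", {
  x <- c(0.5, 1, 2, 3, 10)
  expect_equal(boxcox_transform(x, 1), x - 1)
  expect_equal(boxcox_transform(exp(1), 0), 1)
  expect_equal(boxcox_transform(3, 2), 4)
  expect_equal(boxcox_transform(x, 0), log(x))
  expect_error(boxcox_transform(c(1, -1), 1), "positive")
})

test_that("Box-Cox lambda selection maximises the profile likelihood", {
  set.seed(77)
  # lognormal data: MLE exponent near 0
  x <- exp(rnorm(1e4))
  expect_lte(abs(boxcox_lambda(x)), 0.05)

  # shifted-normal data: grid argmax within resolution of a continuous
  # optimiser over an independently coded profile likelihood
  y <- 100 + rnorm(1e4)
  oracle_ll <- function(lam) {
    z <- if (abs(lam) < 1e-8) log(y) else (y^lam - 1) / lam
    -length(y) / 2 * log(mean((z - mean(z))^2)) + (lam - 1) * sum(log(y))
  }
  opt <- optimize(oracle_ll, c(-3, 3), maximum = TRUE)$maximum
  expect_lte(abs(boxcox_lambda(y) - opt), 0.011)

  # agreement with the classical profile-likelihood implementation
  xm <- exp(rnorm(500, sd = 0.6))
  bc <- MASS::boxcox(xm ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  expect_equal(boxcox_lambda(xm), bc$x[which.max(bc$y)], tolerance = 0.011)

  expect_error(boxcox_lambda(rep(2, 10)), "constant")
  expect_error(boxcox_lambda(c(1, 2, 3)), "at least 5")
})

test_that("t-EM covariance approaches Pearson as df grows", {
  set.seed(101)
  n <- 2000
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  X <- cbind(x, y)
  fit <- t_cov_em(X, df = 1e6)
  expect_lt(abs(fit$correlation[1, 2] - cor(x, y)), 1e-3)
  expect_equal(fit$location, colMeans(X), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("t-EM matches the reference multivariate-t fit and resists outliers", {
  set.seed(102)
  n <- 500
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = 0.8)
  X <- cbind(x, y)
  # independent implementation of the same estimator
  ref <- MASS::cov.trob(X, nu = 4, tol = 1e-10, maxit = 500)
  fit <- t_cov_em(X, df = 4)
  expect_equal(fit$correlation, cov2cor(ref$cov), tolerance = 1e-5)
  expect_equal(fit$location, ref$center, tolerance = 1e-5,
               ignore_attr = TRUE)

  # one gross outlier: t-EM stays near the clean Pearson value
  r_clean <- cor(x, y)
  Xc <- X
  Xc[1, 1] <- Xc[1, 1] * 50
  r_contam <- cor(Xc[, 1], Xc[, 2])
  r_tem <- t_cov_em(Xc, df = 4)$correlation[1, 2]
  expect_lt(abs(r_tem - r_clean), abs(r_contam - r_clean))
})

test_that("t-EM correlation is equivariant to affine column rescaling", {
  set.seed(103)
  X <- MASS::mvrnorm(300, c(0, 0), matrix(c(1, 0.4, 0.4, 1), 2))
  r0 <- t_cov_em(X, df = 4)$correlation[1, 2]
  Xr <- cbind(-5 + 37 * X[, 1], 2 + 0.01 * X[, 2])
  expect_equal(t_cov_em(Xr, df = 4)$correlation[1, 2], r0,
               tolerance = 1e-6)
})

test_that("t-EM rejects degenerate input", {
  X <- cbind(rnorm(50), rep(1, 50))
  expect_error(t_cov_em(X), "constant")
  expect_error(t_cov_em(matrix(rnorm(4), 2, 2)), "more observations")
  expect_error(t_cov_em(matrix(rnorm(30), 10, 3)[, 1, drop = FALSE]),
               "2 columns")
})

test_that("Fisher-z intervals behave as intervals should", {
  ci0 <- corr_ci(0, 50)
  expect_equal(ci0[1], -ci0[2])  # symmetric about 0
  # width strictly decreasing in n at fixed r
  widths <- vapply(c(10, 30, 100, 500), function(n)
    diff(corr_ci(0.4, n)), numeric(1))
  expect_true(all(diff(widths) < 0))
  # bounds contain r and respect [-1, 1]
  for (r in c(-0.9, -0.3, 0.29, 0.8)) {
    ci <- corr_ci(r, 79)
    expect_true(ci[1] < r && r < ci[2])
    expect_true(all(abs(ci) < 1))
  }
  expect_error(corr_ci(0.5, 3), "exceed 3")
  expect_error(corr_ci(1, 50), "correlation")
})

test_that("Williams-Steiger statistic matches an independently coded formula", {
  # textbook form coded afresh, kept separate from the implementation
  oracle <- function(rjk, rjh, rkh, n) {
    detR <- 1 - rjk^2 - rjh^2 - rkh^2 + 2 * rjk * rjh * rkh
    rb <- (rjk + rjh) / 2
    (rjk - rjh) * sqrt((n - 1) * (1 + rkh) /
      (2 * detR * (n - 1) / (n - 3) + rb^2 * (1 - rkh)^3))
  }
  cases <- list(c(0.5, 0.3, 0.4, 100), c(-0.3, 0.29, -0.8, 79),
                c(0.1, 0.6, 0.2, 30))
  for (cs in cases) {
    st <- steiger_test(cs[1], cs[2], cs[3], cs[4])
    expect_equal(st$t_stat, oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6)
    expect_equal(st$df, cs[4] - 3)
    expect_equal(st$p_value,
                 2 * pt(-abs(st$t_stat), cs[4] - 3))
  }
})

test_that("Steiger test is null at equal correlations and rejects bad triples", {
  st <- steiger_test(0.42, 0.42, 0.3, 79)
  expect_equal(st$t_stat, 0)
  expect_equal(st$p_value, 1)
  expect_error(steiger_test(0.9, -0.9, 0.9, 50), "inconsistent")
})

test_that("robust_cor composes Box-Cox, t-EM and the Fisher interval", {
  set.seed(104)
  n <- 400
  z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, -0.5, -0.5, 1), 2))
  x <- exp(1 + 0.4 * z[, 1])
  y <- exp(2 + 0.3 * z[, 2])
  rc <- robust_cor(x, y)
  expect_lt(abs(rc$r - (-0.5)), 0.1)
  expect_lte(abs(rc$lambda_x), 0.25)  # near-log for lognormal margins
  expect_equal(c(rc$ci_low, rc$ci_high), corr_ci(rc$r, n))
  expect_equal(rc$n, n)
  # matrix version agrees with the pairwise scalar version
  rm <- robust_cor_matrix(cbind(a = x, b = y))
  expect_equal(rm$r["a", "b"], rc$r, tolerance = 1e-8)
  # perfectly collinear pair is recorded as +/-1, not an error
  rm2 <- robust_cor_matrix(cbind(a = x, b = x * 0.9, c = y))
  expect_equal(rm2$r["a", "b"], 1)
})
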