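test_that("Pearson residuals follow their definition", {
  expect_equal(pearson_residuals(5, 4), 0.5)
  y <- c(3, 8, 2)
  expect_equal(pearson_residuals(y, y), c(0, 0, 0))
  expect_error(pearson_residuals(c(1, 2), c(1, 0)), "positive")
})

test_that("deviance R-squared is 1 at the saturated fit and 0 at the mean-only fit", {
  set.seed(1)
  y <- rpois(50, 10) + 1
  expect_equal(deviance_r2(y, y), 1)
  expect_equal(deviance_r2(y, rep(mean(y), 50)), 0, tolerance = 1e-12)
  expect_error(deviance_r2(rep(4, 10), rep(3, 10)), "saturated null")
})

test_that("deviance R-squared evaluates the printed formula", {
  y <- c(2, 4)
  mu <- c(2.5, 3.5)
  num <- 2 * log(2.5 / 3) + 0.5 + 4 * log(3.5 / 3) - 0.5
  den <- 2 * log(2 / 3) + 4 * log(4 / 3)
  expect_equal(deviance_r2(y, mu), num / den)
  expect_equal(deviance_r2(y, mu), 0.7415, tolerance = 1e-4)
  # zero counts use the 0 log 0 = 0 convention
  expect_no_error(deviance_r2(c(0, 3, 5), c(1, 3, 4)))
})

test_that("deviance R-squared is invariant to jointly permuting days", {
  set.seed(2)
  y <- rpois(30, 8) + 1
  mu <- y + runif(30, -1, 1)
  p <- sample(30)
  expect_equal(deviance_r2(y, mu), deviance_r2(y[p], mu[p]))
})

test_that("the overdispersion regression reproduces hand calculations", {
  # (y - mu)^2 - y = 0 exactly: phi_hat 0, boundary p = 0.5
  y <- c(4, 9, 1)
  mu <- c(2, 6, 2)
  r <- overdispersion_test(y, mu)
  expect_equal(r$phi_hat, 0)
  expect_equal(r$p, 0.5)

  r2 <- overdispersion_test(c(6, 0, 6), c(3, 3, 3))
  # Y* = (9-6)/3, (9-0)/3, (9-6)/3 = (1, 3, 1)
  expect_equal(r2$phi_hat, 5 / 3)
  expect_error(overdispersion_test(c(6, 0), c(3, 3)), "at least 3")
})

test_that("the auxiliary-regression statistic equals its closed form", {
  set.seed(3)
  y <- rpois(100, 20)
  mu <- pmax(y + rnorm(100), 1)
  r <- overdispersion_test(y, mu)
  ystar <- ((y - mu)^2 - y) / mu
  expect_equal(r$phi_hat, mean(ystar))
  expect_equal(r$z, mean(ystar) / (sd(ystar) / 10))
  expect_equal(r$p, pnorm(r$z, lower.tail = FALSE))
  # the robust variant differs only by the finite-sample factor here
  rr <- overdispersion_test(y, mu, robust = TRUE)
  expect_equal(rr$z, r$z * sqrt(100 / 99), tolerance = 1e-10)
})

test_that("mean square error follows its definition", {
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(mse(c(5, 5), c(5, 5)), 0)
})

test_that("the diagnostics report is internally consistent", {
  sim <- simulate_calls(sim_config(n_days = 120, seed = 5))
  fit <- svcm(sim$series, bandwidth = 10)
  dg <- svcm_diagnostics(fit)
  r <- pearson_residuals(fit$design$y_resp, fit$mu)
  expect_equal(dg$pearson_mean, mean(r))
  expect_equal(dg$pearson_var, var(r))
  expect_equal(dg$mse, mean((fit$design$y_resp - fit$mu)^2))
  expect_lte(dg$deviance_r2, 1)
  # Poisson noise: dispersion close to 1, test not strongly significant
  expect_lt(dg$phi_test$phi_hat, 1)
})
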