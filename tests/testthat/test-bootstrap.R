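test_that("the dispersion moment estimator follows its definition", {
  expect_equal(estimate_dispersion(c(4, 1), c(2, 2)), 1.25)
  expect_warning(phi <- estimate_dispersion(c(3, 5), c(3, 5)), "degenerate")
  expect_equal(phi, 0)
  expect_error(estimate_dispersion(c(1, 2), c(1, -1)), "positive")
})

test_that("a large Poisson sample has dispersion near 1", {
  set.seed(10)
  mu <- rep(5, 1e5)
  y <- rpois(1e5, mu)
  expect_lt(abs(estimate_dispersion(y, mu) - 1), 0.05)
})

test_that("the default number of bootstrap replicates is 5000", {
  expect_equal(eval(formals(boot_svcm)$B), 5000L)
})

boot_fixture <- local({
  sim <- simulate_calls(sim_config(n_days = 120, seed = 21))
  fit <- svcm(sim$series, bandwidth = 7)
  list(sim = sim, fit = fit)
})

test_that("the bootstrap is reproducible under a fixed seed", {
  fit <- boot_fixture$fit
  b1 <- boot_svcm(fit, B = 25, seed = 99)
  b2 <- boot_svcm(fit, B = 25, seed = 99)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$se, b2$se)
  b3 <- boot_svcm(fit, B = 25, seed = 100)
  expect_false(identical(b1$draws, b3$draws))
})

test_that("pseudo-responses reproduce the fit's first two moments", {
  fit <- boot_fixture$fit
  b <- boot_svcm(fit, B = 2000, seed = 1)
  mu <- fit$mu
  # aggregate relative agreement across days, 5% tolerance
  expect_lt(mean(abs(b$pseudo_mean - mu)) / mean(mu), 0.05)
  expect_lt(abs(mean(b$pseudo_var / (b$phi * mu)) - 1), 0.05)
  expect_identical(nrow(b$draws), 2000L)
})

test_that("the Wald table is definitional and in the reporting order", {
  fit <- boot_fixture$fit
  b <- boot_svcm(fit, B = 40, seed = 3)
  tab <- wald_table(fit, b)
  expect_identical(tab$label,
                   c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                     "Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                     "TARPs Quit", "TARPs NRT"))
  expect_equal(tab$z, tab$estimate / tab$se)
  expect_equal(tab$p, 2 * (1 - pnorm(abs(tab$z))))
  expect_equal(tab$estimate, unname(coef(fit)))
})

test_that("the pointwise band contains the estimate and widens at the ends", {
  fit <- boot_fixture$fit
  b <- boot_svcm(fit, B = 150, seed = 5)
  band <- alpha_band(fit, b, level = 0.95)
  expect_true(all(band$lower <= fit$alpha + 1e-12))
  expect_true(all(band$upper >= fit$alpha - 1e-12))
  wd <- band$upper - band$lower
  n <- length(wd)
  ends <- c(1:7, (n - 6):n)
  interior <- setdiff(seq_len(n), ends)
  expect_gt(mean(wd[ends]), mean(wd[interior]))
  expect_error(alpha_band(fit, b, level = 1.2), "level")
})

test_that("a genuine advertising effect is detected with high power", {
  # gamma_TARPs_Quit > 0 in the generator; the Wald test should reject at
  # the 5% level in at least 80% of small replicate studies
  reject <- logical(10)
  for (r in seq_len(10)) {
    sim <- simulate_calls(sim_config(n_days = 180, seed = 300 + r))
    fit <- suppressWarnings(svcm(sim$series, bandwidth = 7))
    b <- boot_svcm(fit, B = 60, seed = r)
    tab <- wald_table(fit, b)
    reject[r] <- tab$p[tab$parameter == "gamma_TARPs_Quit"] < 0.05
  }
  expect_gte(mean(reject), 0.8)
})
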