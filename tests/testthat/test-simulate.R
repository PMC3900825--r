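test_that("advertising flights have the configured support", {
  cfg <- sim_config(n_days = 360,
                    tarp_quit = data.frame(start = 10 / 360,
                                           duration = 21 / 360,
                                           height = 50),
                    tarp_nrt = data.frame(start = 100 / 360,
                                          duration = 20 / 360,
                                          height = 30),
                    seed = 2)
  tarps <- simulate_tarps(cfg)
  on <- which(tarps$tarp_quit > 0)
  expect_gte(min(on), 10)
  expect_lte(max(on), 30)
  expect_true(all(tarps$tarp_quit >= 0))
})

test_that("the Quit campaign concentrates on Monday-Wednesday, NRT does not", {
  cfg <- sim_config(seed = 3)
  tarps <- simulate_tarps(cfg)
  dow <- as.POSIXlt(tarps$date)$wday
  share <- function(x) sum(x[dow %in% 1:3]) / sum(x)
  expect_gt(share(tarps$tarp_quit), 0.6)
  expect_lt(share(tarps$tarp_nrt), 0.55)
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- sim_config(n_days = 60, seed = 11)
  expect_identical(simulate_tarps(cfg), simulate_tarps(cfg))
  expect_identical(simulate_calls(cfg)$series, simulate_calls(cfg)$series)
})

test_that("zero effects and a zero start give the absorbing all-zero series", {
  cfg <- sim_config(n_days = 30, beta = rep(0, 6), gamma = rep(0, 8),
                    y0 = 0, seed = 1)
  sim <- simulate_calls(cfg)
  expect_true(all(sim$series$calls == 0))
})

test_that("one-step Monte-Carlo means match the conditional-mean recursion", {
  # no advertising, so the day-2 mean depends only on the fixed first day
  no_ads <- data.frame(start = 0.5, duration = 0.1, height = 0)
  cfg <- sim_config(n_days = 14, tarp_quit = no_ads, tarp_nrt = no_ads,
                    seed = 5)
  # day 2 conditions only on the fixed y0, so its mean is deterministic
  draws <- vapply(seq_len(3000), function(b) {
    simulate_calls(cfg, seed = 5000 + b)$series$calls[2]
  }, numeric(1))
  sim1 <- simulate_calls(cfg, seed = 5001)
  d <- build_design(sim1$series)
  m2 <- conditional_mean(list(alpha = sim1$truth$alpha,
                              beta = sim1$truth$beta,
                              gamma = sim1$truth$gamma), d)[1]
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m2), 3 * se + 1e-9)
})

test_that("negative-binomial noise is recovered by the dispersion estimator", {
  cfg <- sim_config(noise = "negbin", phi = 5, seed = 6)
  sim <- simulate_calls(cfg)
  d <- build_design(sim$series)
  mu <- conditional_mean(sim$truth, d)
  phi_hat <- estimate_dispersion(sim$series$calls[-1], mu)
  expect_gt(phi_hat, 4)
  expect_lt(phi_hat, 6)
})

test_that("an infeasible truth aborts with the offending day", {
  cfg <- sim_config(n_days = 30, alpha = function(u) rep(-2, length(u)),
                    y0 = 50, seed = 1)
  expect_error(simulate_calls(cfg), "negative conditional mean")
})

test_that("the default scenario shows the study's qualitative fingerprints", {
  sim <- simulate_calls(sim_config(seed = 4))
  s <- sim$series
  dow <- as.POSIXlt(s$date)$wday
  daily <- tapply(s$calls, dow, mean)
  # weekly cycle: Monday-Wednesday peak, declining into the weekend (the
  # minimum falls on Saturday or Sunday, which have the weakest immigration)
  expect_gt(mean(daily[c("1", "2", "3")]), mean(s$calls))
  expect_true(names(which.min(daily)) %in% c("0", "6"))
  expect_true(all(daily["0"] < daily[c("1", "2", "3", "4", "5")]))
  # calls surge when advertising is on
  on <- s$tarp_quit + s$tarp_nrt > 0
  expect_gt(mean(s$calls[on]), mean(s$calls[!on]))
  # the carryover curve is elevated during the no-advertising holiday block
  u <- (seq_len(360) - 1) / 359
  hol <- u > 0.37 & u < 0.43
  expect_true(all(s$tarp_quit[hol] == 0))
  cfg_alpha <- sim$truth$alpha
  expect_gt(max(cfg_alpha[hol[-1]]), 1.2)
})

test_that("the chain-binomial depletion chain conserves its cohort", {
  cfg <- sim_config(n_days = 60, N0 = 1e6, y0 = 50, seed = 9)
  out <- simulate_chain_binomial(cfg)
  y <- out$series$calls
  expect_equal(out$N[-1], out$N[-60] - y[-60])
  expect_true(all(out$N > 0))
})

test_that("zero calling probability freezes the chain", {
  cfg <- sim_config(n_days = 30, alpha = function(u) rep(0, length(u)),
                    beta = rep(0, 6), y0 = 0, seed = 2)
  out <- simulate_chain_binomial(cfg)
  expect_true(all(out$series$calls == 0))
  expect_true(all(out$N == cfg$N0))
})

test_that("with a large cohort the chain is close to its Poisson limit", {
  # one-step law vs Poisson(y_prev * alpha'): compare mean and variance
  cfg <- sim_config(n_days = 14, alpha = function(u) rep(0.9, length(u)),
                    beta = rep(0, 6), N0 = 1e6, y0 = 100, seed = 7)
  y2 <- vapply(seq_len(4000), function(b) {
    simulate_chain_binomial(cfg, seed = 20000 + b)$series$calls[2]
  }, numeric(1))
  target <- 100 * 0.9
  expect_lt(abs(mean(y2) - target) / target, 0.05)
  expect_lt(abs(var(y2) - target) / target, 0.05)
})
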