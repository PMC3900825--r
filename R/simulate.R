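# Synthetic-data generator: Quitline-like daily call series with known
# ground truth, for testing every stage of the pipeline.

#' Published parametric effect estimates for the Victorian Quitline study
#'
#' Day-of-week carryover modifiers (beta) and immigration effects (gamma)
#' estimated for daily calls to Quitline Victoria (August 2000 - July 2001),
#' with bootstrap standard errors. Used as a realistic anchor for the
#' synthetic-data generator and for the package's worked examples (e.g. the
#' expected number of additional Monday calls after a quiet or a busy
#' Sunday); they are reference values, not quantities a fit to new data is
#' expected to reproduce.
#'
#' @return data.frame with columns `parameter`, `label`, `estimate`, `se`.
#' @examples
#' eff <- quitline_effects()
#' # additional Monday calls after a Sunday with 0 and with 100 calls:
#' round(eff$estimate[eff$parameter == "gamma_Mon"])
#' round(eff$estimate[eff$parameter == "gamma_Mon"] +
#'       100 * eff$estimate[eff$parameter == "beta_Mon"])
#' @export
quitline_effects <- function() {
  data.frame(
    parameter = c(paste0("beta_", DAY_LABELS), paste0("gamma_", DAY_LABELS),
                  "gamma_TARPs_Quit", "gamma_TARPs_NRT"),
    label = c(DAY_LABELS, DAY_LABELS, "TARPs Quit", "TARPs NRT"),
    estimate = c(0.080, -0.201, -0.394, -0.487, -0.433, -0.754,
                 51.09, -3.292, 28.25, 23.29, 14.75, 7.712, 0.488, 0.226),
    se = c(0.217, 0.101, 0.103, 0.118, 0.131, 0.117,
           8.569, 9.944, 10.27, 11.38, 10.03, 6.982, 0.083, 0.099))
}

# Generator defaults: the published estimates rounded to a convenient
# simulation truth (order Mon..Sat; TARP slopes last).
default_beta_true <- function() c(0.08, -0.20, -0.39, -0.49, -0.43, -0.75)
default_gamma_true <- function() c(51, -3, 28, 23, 15, 8, 0.49, 0.23)

# Smooth varying-coefficient presets, as functions of normalized time
# u = day/n_days in [0, 1] so that trend features stretch with the series
# length. "seasonal-troughs" is a smooth annual wave (troughs over the long
# no-advertising blocks) plus two brief surges whose duration is fixed in
# DAYS, not series fractions: a New-Year holiday surge inside the
# advertising gap (late December for a series starting in August) and a
# smaller late-May surge. Holiday surges last a few days regardless of how
# long the series is observed, so their widths do not stretch with n_days.
alpha_preset <- function(name, n_days) {
  switch(name,
         constant = function(u) rep(0.9, length(u)),
         `seasonal-troughs` = function(u) {
           0.80 + 0.12 * sin(2 * pi * (u - 0.05)) +
             0.70 * exp(-((u - 0.400) * n_days / 4.7)^2) +
             0.50 * exp(-((u - 0.800) * n_days / 4.3)^2)
         },
         stop("unknown alpha preset: '", name,
              "' (available: constant, seasonal-troughs)"))
}

# Default advertising flight schedules (start and duration as fractions of
# the series, height = flight-average TARPs/day). Gaps: the holiday block
# around u = 0.38-0.46 and the long March-May block u = 0.58-0.83 carry no
# advertising; late-series flights are small (winter lull).
default_tarp_quit <- function() {
  data.frame(start = c(0.02, 0.12, 0.22, 0.30, 0.47, 0.53, 0.86, 0.93),
             duration = c(0.07, 0.07, 0.06, 0.06, 0.05, 0.04, 0.05, 0.05),
             height = c(36, 44, 32, 40, 36, 28, 16, 18))
}
default_tarp_nrt <- function() {
  data.frame(start = c(0.04, 0.15, 0.25, 0.31, 0.48, 0.53, 0.87, 0.94),
             duration = c(0.08, 0.07, 0.06, 0.06, 0.05, 0.04, 0.06, 0.05),
             height = c(24, 28, 22, 26, 24, 20, 14, 12))
}

# Within-week placement weights (Sun..Sat). The Quit campaign concentrates
# its weight Monday-Wednesday; NRT is spread evenly.
quit_week_weights <- function() {
  c(Sun = 0.03, Mon = 0.27, Tue = 0.25, Wed = 0.22,
    Thu = 0.11, Fri = 0.07, Sat = 0.05)
}
nrt_week_weights <- function() rep(1 / 7, 7)

#' Configuration for the synthetic call-series generator
#'
#' @param n_days series length (default 360, one advertising year).
#' @param start_date first calendar day (default Sunday 2000-08-06; the
#'   day-of-week structure follows the calendar, so any start day works).
#' @param alpha `"seasonal-troughs"` (default), `"constant"`, or a function
#'   of normalized time u in \[0, 1\] returning the varying coefficient.
#' @param beta,gamma true parametric coefficients (6 carryover modifiers
#'   Mon...Sat; 6 day-of-week immigration effects, then the two TARP
#'   slopes). Defaults are the published Quitline estimates rounded.
#' @param tarp_quit,tarp_nrt flight schedules: data.frames with columns
#'   `start`, `duration` (fractions of the series) and `height`
#'   (flight-average TARPs/day). Overlapping flights are summed.
#' @param week_weights_quit,week_weights_nrt within-week placement weights
#'   (Sun...Sat, summing to 1).
#' @param noise `"poisson"` (default), `"negbin"` (conditional variance
#'   `phi * mu`), or `"chain_binomial"`.
#' @param phi overdispersion for `"negbin"` (> 1).
#' @param N0 initial at-risk cohort size for `"chain_binomial"`; must be
#'   large relative to the expected total number of calls.
#' @param y0 count on the (fixed) first day.
#' @param seed integer seed governing all draws.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_days = 360L, start_date = as.Date("2000-08-06"),
                       alpha = "seasonal-troughs",
                       beta = default_beta_true(),
                       gamma = default_gamma_true(),
                       tarp_quit = default_tarp_quit(),
                       tarp_nrt = default_tarp_nrt(),
                       week_weights_quit = quit_week_weights(),
                       week_weights_nrt = nrt_week_weights(),
                       noise = c("poisson", "negbin", "chain_binomial"),
                       phi = 5, N0 = 1e6, y0 = 20L, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_days >= 14L, length(beta) == 6L, length(gamma) == 8L,
            all(is.finite(beta)), all(is.finite(gamma)), y0 >= 0)
  for (sched in list(tarp_quit, tarp_nrt)) {
    stopifnot(is.data.frame(sched),
              all(c("start", "duration", "height") %in% names(sched)),
              all(sched$height >= 0), all(sched$duration > 0))
  }
  if (noise == "negbin" && phi <= 1) stop("negbin noise needs phi > 1")
  alpha_fn <- if (is.function(alpha)) alpha else alpha_preset(alpha, n_days)
  structure(list(n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 alpha_fn = alpha_fn,
                 alpha_name = if (is.function(alpha)) "custom" else alpha,
                 beta = beta, gamma = gamma,
                 tarp_quit = tarp_quit, tarp_nrt = tarp_nrt,
                 week_weights_quit = week_weights_quit,
                 week_weights_nrt = week_weights_nrt,
                 noise = noise, phi = phi, N0 = N0, y0 = y0,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One campaign's daily TARP series: flight envelope times within-week
# placement weight (scaled so a flat week averages `height`), with mild
# day-to-day gamma jitter. Overlapping flights are summed.
tarp_series <- function(n_days, schedule, week_weights, dow) {
  tarp <- numeric(n_days)
  for (k in seq_len(nrow(schedule))) {
    a <- max(1L, round(schedule$start[k] * n_days))
    b <- min(n_days, a + max(1L, round(schedule$duration[k] * n_days)) - 1L)
    days <- a:b
    jitter <- stats::rgamma(length(days), shape = 6, rate = 6)
    tarp[days] <- tarp[days] +
      schedule$height[k] * 7 * week_weights[dow[days] + 1L] * jitter
  }
  tarp
}

#' Simulate the two advertising (TARP) series
#'
#' Pulse-like flights separated by zero-advertising gaps; the Quit
#' campaign's weight is concentrated Monday-Wednesday, the NRT campaign's
#' is spread evenly across the week.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return data.frame with columns `date`, `tarp_quit`, `tarp_nrt`.
#' @export
simulate_tarps <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  dates <- config$start_date + 0:(config$n_days - 1L)
  dow <- day_of_week(dates)
  data.frame(date = dates,
             tarp_quit = tarp_series(config$n_days, config$tarp_quit,
                                     config$week_weights_quit, dow),
             tarp_nrt = tarp_series(config$n_days, config$tarp_nrt,
                                    config$week_weights_nrt, dow))
}

draw_count <- function(n, mu, dispersion = 1) {
  if (mu <= 0) return(rep(0L, n))
  if (dispersion <= 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = mu / (dispersion - 1), mu = mu)
  }
}

#' Simulate a daily call series with known ground truth
#'
#' Sequentially draws Y_j from the configured noise law with conditional
#' mean Y_{j-1} (alpha(t_j) + X_j'beta) + Z_j'gamma, after generating the
#' TARP series. Day 1 is fixed at `config$y0`.
#'
#' @param config a [sim_config()] with `noise` `"poisson"` or `"negbin"`
#'   (use [simulate_chain_binomial()] for the depletion chain).
#' @param seed overrides `config$seed`.
#' @return list with `series` (a [quitline_series]), and `truth`: the true
#'   `alpha` evaluated on response days 2...J, `beta`, `gamma`, and the
#'   `config` (provenance).
#' @details A conditional mean of exactly 0 is drawn as a (degenerate)
#'   Poisson(0) — the all-zero state is absorbing; a strictly negative mean
#'   aborts with the offending day, since it indicates an inconsistent
#'   truth (e.g. a trough in alpha too deep for the configured beta).
#' @export
simulate_calls <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            config$noise %in% c("poisson", "negbin"))
  set.seed(seed)
  n <- config$n_days
  dates <- config$start_date + 0:(n - 1L)
  dow <- day_of_week(dates)
  tarps <- data.frame(
    tarp_quit = tarp_series(n, config$tarp_quit,
                            config$week_weights_quit, dow),
    tarp_nrt = tarp_series(n, config$tarp_nrt,
                           config$week_weights_nrt, dow))
  u <- (seq_len(n) - 1) / (n - 1)
  alpha <- config$alpha_fn(u)
  beta_day <- c(0, config$beta)   # indexed by dow: Sun, Mon..Sat
  gamma_day <- c(0, config$gamma[1:6])
  disp <- if (config$noise == "negbin") config$phi else 1

  y <- numeric(n)
  y[1L] <- config$y0
  for (j in 2:n) {
    d <- dow[j]
    m <- y[j - 1L] * (alpha[j] + beta_day[d + 1L]) + gamma_day[d + 1L] +
      config$gamma[7L] * tarps$tarp_quit[j] +
      config$gamma[8L] * tarps$tarp_nrt[j]
    if (m < 0) {
      stop("negative conditional mean (", signif(m, 4), ") at day ", j,
           " (", format(dates[j]), "); the configured truth is ",
           "inconsistent - raise alpha, soften beta, or increase the ",
           "immigration effects")
    }
    y[j] <- draw_count(1L, m, disp)
  }
  series <- quitline_series(data.frame(date = dates, calls = y,
                                       tarp_quit = tarps$tarp_quit,
                                       tarp_nrt = tarps$tarp_nrt))
  list(series = series,
       truth = list(alpha = alpha[2:n], beta = config$beta,
                    gamma = config$gamma, config = config))
}

#' Simulate calls from the chain-binomial depletion model
#'
#' The sequential cohort model whose small-p, large-N limit motivates the
#' conditional Poisson formulation: N_j at-risk individuals each call with
#' probability p_j on day j, Y_j ~ binomial(N_j, p_j), and the cohort
#' depletes as N_{j+1} = N_j - Y_j. The calling probability is linked to
#' the configured carryover by p_j = Y_{j-1} alpha'_j / N_j with
#' alpha'_j = alpha(t_j) + X_j'beta (a generator convention making
#' E(Y_j | F_{j-1}) = Y_{j-1} alpha'_j exact); there is no immigration
#' term, and the TARP columns are carried in the output only for format
#' compatibility.
#'
#' @param config a [sim_config()]; `N0` must be large relative to the
#'   expected total number of calls.
#' @param seed overrides `config$seed`.
#' @return list with `series` (a [quitline_series], zero TARPs), `N` (the
#'   latent at-risk trace, length n_days), and `truth`.
#' @export
simulate_chain_binomial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_days
  dates <- config$start_date + 0:(n - 1L)
  dow <- day_of_week(dates)
  u <- (seq_len(n) - 1) / (n - 1)
  alpha <- config$alpha_fn(u)
  beta_day <- c(0, config$beta)
  y <- numeric(n)
  N <- numeric(n)
  y[1L] <- config$y0
  N[1L] <- config$N0
  for (j in 2:n) {
    N[j] <- N[j - 1L] - y[j - 1L]
    if (N[j] <= 0) {
      stop("at-risk cohort exhausted at day ", j,
           " - configuration too aggressive (increase N0)")
    }
    ap <- alpha[j] + beta_day[dow[j] + 1L]
    p <- min(1, max(0, y[j - 1L] * ap / N[j]))
    y[j] <- stats::rbinom(1L, N[j], p)
  }
  series <- quitline_series(data.frame(date = dates, calls = y,
                                       tarp_quit = 0, tarp_nrt = 0))
  list(series = series, N = N,
       truth = list(alpha = alpha[2:n], beta = config$beta,
                    config = config))
}
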