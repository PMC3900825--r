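# Overdispersion-adjusted residual bootstrap for the parametric component,
# Wald tests, and pointwise bands for the varying coefficient.

#' Moment estimate of the dispersion parameter
#'
#' Under Var(Y_j | F_{j-1}) = phi mu_j, estimates phi as the value making
#' the modified Pearson residuals r*_j = (y_j - mu_j) / sqrt(phi mu_j) have
#' unit second moment: phi_hat = mean((y - mu)^2 / mu).
#'
#' @param y observed counts.
#' @param mu fitted conditional means (all positive).
#' @return phi_hat (dimensionless; 1 under Poisson noise).
#' @export
estimate_dispersion <- function(y, mu) {
  stopifnot(length(y) == length(mu))
  if (any(mu <= 0)) stop("all fitted means must be positive")
  phi <- mean((y - mu)^2 / mu)
  if (phi == 0) {
    warning("zero residuals: dispersion degenerate at 0 ",
            "(data cannot be Poisson-noisy)")
  }
  phi
}

#' Overdispersion-adjusted nonparametric bootstrap standard errors
#'
#' Residual bootstrap of the parametric coefficients (beta, gamma), adjusted
#' for overdispersion: modified Pearson residuals
#' r*_j = (y_j - mu_hat_j)/sqrt(phi_hat mu_hat_j) are re-centred and
#' resampled with replacement, pseudo-responses
#' Y^b_j = mu_hat_j + r*_j^b sqrt(phi_hat mu_hat_j) are formed (day 1 and
#' the design, including the previous-day counts, stay fixed), and the full
#' model is refitted with the bandwidth frozen at the original fit's value.
#' Standard errors are the per-coefficient standard deviations across the B
#' replicate estimates.
#'
#' @param fit a converged [svcm()] fit.
#' @param B number of bootstrap replicates (default 5000).
#' @param seed integer seed; the same seed and B reproduce the result
#'   bit-identically.
#' @param method `"residual"` (default, the phi-adjusted nonparametric
#'   bootstrap) or `"poisson"` (parametric bootstrap drawing
#'   Y^b_j ~ Poisson(mu_hat_j), no dispersion adjustment).
#' @param phi override the dispersion estimate (e.g. `phi = 1` to disable
#'   the adjustment while keeping the nonparametric resampling).
#' @return object of class `svcm_boot`: `phi`, `B`, `draws` (B x 14 matrix
#'   of replicate (beta, gamma)), `alpha_draws` (B x (J-1) replicate
#'   curves, used by [alpha_band()]), `se`, `z`, `p` (two-sided normal),
#'   `seed`, `n_truncated` (negative pseudo-responses truncated at 0),
#'   `n_refit_failed` (replicates re-drawn after a failed refit).
#' @details Pseudo-responses are not rounded to integers (the refit is
#'   quasi-likelihood and needs only first and second moments); negative
#'   values are truncated at zero and counted. Failed refits are re-drawn,
#'   never dropped; more than 10% failures is an error.
#' @export
boot_svcm <- function(fit, B = 5000L, seed = 1L,
                      method = c("residual", "poisson"), phi = NULL) {
  stopifnot(inherits(fit, "svcm"))
  method <- match.arg(method)
  if (!fit$converged) {
    warning("bootstrapping a fit flagged as non-converged")
  }
  stopifnot(B >= 2L)
  des <- fit$design
  y <- des$y_resp
  mu <- fit$mu
  n <- length(y)
  if (is.null(phi)) phi <- estimate_dispersion(y, mu)
  sd_j <- sqrt(pmax(phi, .Machine$double.eps) * mu)
  rstar <- (y - mu) / sd_j
  rstar <- rstar - mean(rstar)

  W <- kernel_matrix(des$time, fit$bandwidth, fit$kernel)
  init <- list(alpha = fit$alpha, beta = unname(fit$coefficients[1:6]),
               gamma = unname(fit$coefficients[7:14]))
  ctl <- fit$control

  set.seed(seed)
  draws <- matrix(NA_real_, B, 14L,
                  dimnames = list(NULL, names(fit$coefficients)))
  alpha_draws <- matrix(NA_real_, B, n)
  ps_sum <- numeric(n)   # running moments of the pseudo-responses,
  ps_sum2 <- numeric(n)  # for calibration diagnostics
  ps_n <- 0L
  n_trunc <- 0L
  n_fail <- 0L
  max_fail <- ceiling(0.10 * B)
  b <- 1L
  while (b <= B) {
    yb <- if (method == "residual") {
      mu + sample(rstar, n, replace = TRUE) * sd_j
    } else {
      stats::rpois(n, mu)
    }
    neg <- yb < 0
    n_trunc <- n_trunc + sum(neg)
    yb[neg] <- 0
    ps_sum <- ps_sum + yb
    ps_sum2 <- ps_sum2 + yb^2
    ps_n <- ps_n + 1L
    des_b <- des
    des_b$y_resp <- yb
    bf <- tryCatch(
      suppressWarnings(
        svcm_backfit(des_b, W, include_beta = TRUE,
                     variance_weights = fit$variance_weights,
                     tol = ctl$tol, max_iter = ctl$max_iter, eps = ctl$eps,
                     init = init, time = des$time,
                     bandwidth = fit$bandwidth, kernel = fit$kernel)),
      error = function(e) NULL)
    if (is.null(bf) || !bf$converged) {
      n_fail <- n_fail + 1L
      if (n_fail > max_fail) {
        stop("more than 10% of bootstrap replicates failed to converge (",
             n_fail, " failures after ", b - 1L, " successes)")
      }
      next
    }
    draws[b, ] <- c(bf$beta, bf$gamma)
    alpha_draws[b, ] <- bf$alpha
    b <- b + 1L
  }
  se <- apply(draws, 2L, stats::sd)
  est <- fit$coefficients
  z <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  pseudo_mean <- ps_sum / ps_n
  pseudo_var <- (ps_sum2 - ps_n * pseudo_mean^2) / (ps_n - 1L)
  out <- list(phi = phi, B = B, draws = draws, alpha_draws = alpha_draws,
              se = se, z = z, p = p, seed = seed, method = method,
              n_truncated = n_trunc, n_refit_failed = n_fail,
              pseudo_mean = pseudo_mean, pseudo_var = pseudo_var,
              estimate = est)
  class(out) <- "svcm_boot"
  out
}

#' @export
print.svcm_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap (", x$method, "), B = ", x$B,
      ", dispersion phi_hat = ", format(x$phi, digits = digits), "\n",
      sep = "")
  if (x$n_truncated > 0L) {
    cat("  pseudo-responses truncated at 0: ", x$n_truncated, "\n", sep = "")
  }
  if (x$n_refit_failed > 0L) {
    cat("  failed refits re-drawn: ", x$n_refit_failed, "\n", sep = "")
  }
  tab <- data.frame(estimate = signif(x$estimate, digits),
                    se = signif(x$se, digits), z = signif(x$z, digits),
                    p = signif(x$p, digits))
  print(tab)
  invisible(x)
}

#' Pointwise confidence band for the varying coefficient
#'
#' Percentile band across the bootstrap replicate alpha curves recorded by
#' [boot_svcm()], clipped outward so that the point estimate always lies
#' inside the band.
#'
#' @param fit the original [svcm()] fit.
#' @param boot the matching [boot_svcm()] result.
#' @param level coverage level in (0, 1); default 0.95.
#' @return data.frame with columns `date`, `alpha`, `lower`, `upper`.
#' @export
alpha_band <- function(fit, boot, level = 0.95) {
  stopifnot(inherits(fit, "svcm"), inherits(boot, "svcm_boot"))
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  qs <- apply(boot$alpha_draws, 2L, stats::quantile, probs = c(a, 1 - a))
  data.frame(date = fit$design$dates, alpha = fit$alpha,
             lower = pmin(qs[1L, ], fit$alpha),
             upper = pmax(qs[2L, ], fit$alpha))
}

#' Wald table of the parametric effects
#'
#' One row per parametric coefficient, in the model's fixed order:
#' the six carryover modifiers beta (Mon...Sat), the six day-of-week
#' immigration effects gamma (Mon...Sat), then the two TARP slopes.
#'
#' @param fit an [svcm()] fit.
#' @param boot the matching [boot_svcm()] result.
#' @return data.frame with columns `parameter`, `label`, `estimate`, `se`,
#'   `z` (estimate/se), `p` (two-sided normal).
#' @export
wald_table <- function(fit, boot) {
  stopifnot(inherits(fit, "svcm"), inherits(boot, "svcm_boot"))
  if (!identical(names(fit$coefficients), colnames(boot$draws))) {
    stop("fit and bootstrap do not match")
  }
  data.frame(parameter = names(fit$coefficients),
             label = c(DAY_LABELS, DAY_LABELS, "TARPs Quit", "TARPs NRT"),
             estimate = unname(fit$coefficients),
             se = unname(boot$se), z = unname(boot$z), p = unname(boot$p))
}
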