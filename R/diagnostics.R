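# Goodness of fit and overdispersion diagnostics.

#' Pearson residuals
#'
#' r_j = (y_j - mu_j) / sqrt(mu_j). Under a correct Poisson fit these have
#' mean near 0 and variance near 1; a much larger variance is an informal
#' sign of overdispersion.
#'
#' @param y observed counts.
#' @param mu fitted conditional means (all positive).
#' @return numeric vector of residuals.
#' @export
pearson_residuals <- function(y, mu) {
  stopifnot(length(y) == length(mu))
  if (any(mu <= 0)) stop("all fitted means must be positive")
  (y - mu) / sqrt(mu)
}

#' Poisson deviance R-squared
#'
#' R2 = sum(y ln(mu/ybar) - (y - mu)) / sum(y ln(y/ybar)), with the
#' convention 0 ln 0 = 0. Equals 1 at the saturated fit (mu = y) and 0 at
#' the mean-only fit (mu = ybar).
#'
#' @param y observed counts.
#' @param mu fitted means (all positive).
#' @return the statistic (<= 1; can be negative for fits worse than the
#'   mean).
#' @export
deviance_r2 <- function(y, mu) {
  stopifnot(length(y) == length(mu))
  if (any(mu <= 0)) stop("all fitted means must be positive")
  ybar <- mean(y)
  if (ybar <= 0) stop("mean count must be positive")
  xlogx <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  den <- sum(xlogx(y, ybar))
  if (den == 0) {
    stop("saturated null: all counts equal, deviance R-squared undefined")
  }
  num <- sum(ifelse(y == 0, 0, y * log(mu / ybar)) - (y - mu))
  num / den
}

#' Regression test for overdispersion
#'
#' Tests the Poisson assumption against negative-binomial-type
#' overdispersion Var(Y_j|F_{j-1}) = phi mu_j by the intercept-only
#' auxiliary regression Y*_j = phi + u_j with
#' Y*_j = ((y_j - mu_j)^2 - y_j) / mu_j. Under the null phi = 0;
#' the statistic is asymptotically normal.
#'
#' @param y observed counts.
#' @param mu fitted means (all positive); at least 3 days.
#' @param robust use the heteroskedasticity-robust (HC0) standard error
#'   instead of the usual intercept-only least-squares one.
#' @return list with `phi_hat` (mean of Y*), `z`, and the one-sided `p`
#'   against overdispersion (phi > 0).
#' @export
overdispersion_test <- function(y, mu, robust = FALSE) {
  stopifnot(length(y) == length(mu))
  if (any(mu <= 0)) stop("all fitted means must be positive")
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  ystar <- ((y - mu)^2 - y) / mu
  phi_hat <- mean(ystar)
  se <- if (robust) {
    sqrt(sum((ystar - phi_hat)^2)) / n
  } else {
    stats::sd(ystar) / sqrt(n)
  }
  z <- if (se > 0) phi_hat / se else 0
  list(phi_hat = phi_hat, z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Mean square error
#'
#' @param y observed counts.
#' @param fitted fitted values, same length.
#' @return mean((y - fitted)^2); the five-model comparison scores every
#'   model on the common window of response days 2...J.
#' @export
mse <- function(y, fitted) {
  stopifnot(length(y) == length(fitted))
  mean((y - fitted)^2)
}

#' Diagnostics report for a fitted model
#'
#' @param fit an [svcm()] fit.
#' @param robust passed to [overdispersion_test()].
#' @return list of class `svcm_diagnostics`: `deviance_r2`, `pearson_mean`,
#'   `pearson_var`, `phi_test` (list `phi_hat`, `z`, `p`), `mse`.
#' @export
svcm_diagnostics <- function(fit, robust = FALSE) {
  stopifnot(inherits(fit, "svcm"))
  y <- fit$design$y_resp
  mu <- fit$mu
  r <- pearson_residuals(y, mu)
  out <- list(deviance_r2 = deviance_r2(y, mu),
              pearson_mean = mean(r),
              pearson_var = stats::var(r),
              phi_test = overdispersion_test(y, mu, robust = robust),
              mse = mse(y, mu))
  class(out) <- "svcm_diagnostics"
  out
}

#' @export
print.svcm_diagnostics <- function(x, digits = 4, ...) {
  cat("Deviance R-squared:", format(x$deviance_r2, digits = digits), "\n")
  cat("Pearson residuals: mean", format(x$pearson_mean, digits = digits),
      ", variance", format(x$pearson_var, digits = digits), "\n")
  cat("Overdispersion: phi_hat =", format(x$phi_test$phi_hat,
                                          digits = digits),
      ", z =", format(x$phi_test$z, digits = digits),
      ", P =", format.pval(x$phi_test$p, digits = digits), "\n")
  cat("MSE:", format(x$mse, digits = digits), "\n")
  invisible(x)
}
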