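# S3 methods for fitted svcm objects.

#' @export
print.svcm <- function(x, digits = 4, ...) {
  cat("Semi-varying coefficient conditional Poisson model\n")
  cat("  ", length(x$design$y_resp) + 1L, " days (",
      format(x$series$date[1L]), " to ",
      format(x$series$date[nrow(x$series)]), "), bandwidth ",
      format(x$bandwidth, digits = 4), " days, ", x$kernel, " kernel\n",
      sep = "")
  cat("  backfit: ", x$n_iter, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("\nCarryover modifiers (beta, relative to Sunday):\n")
  print(round(stats::setNames(x$coefficients[1:6], DAY_LABELS), digits))
  cat("\nImmigration effects (gamma):\n")
  print(round(stats::setNames(x$coefficients[7:14],
                              colnames(x$design$Z)), digits))
  cat("\nVarying coefficient alpha(t): range [",
      format(min(x$alpha), digits = digits), ", ",
      format(max(x$alpha), digits = digits), "]\n", sep = "")
  invisible(x)
}

#' @export
coef.svcm <- function(object, ...) object$coefficients

#' @export
fitted.svcm <- function(object, ...) object$fitted.values

#' Extract the fitted varying-coefficient curve
#'
#' @param fit an `svcm` (or Model-4 `svcm_ref`) object.
#' @return data.frame with columns `date` and `alpha` over response days.
#' @export
alpha_curve <- function(fit) {
  if (inherits(fit, "svcm")) {
    data.frame(date = fit$design$dates, alpha = fit$alpha)
  } else if (inherits(fit, "svcm_ref") && !is.null(fit$alpha)) {
    data.frame(alpha = fit$alpha)
  } else {
    stop("no varying-coefficient curve in this fit")
  }
}

#' @export
residuals.svcm <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$design$y_resp - object$mu
  if (type == "pearson") r / sqrt(object$mu) else r
}

#' @export
summary.svcm <- function(object, boot = NULL, ...) {
  dg <- svcm_diagnostics(object)
  tab <- if (is.null(boot)) {
    data.frame(parameter = names(object$coefficients),
               estimate = unname(object$coefficients))
  } else {
    wald_table(object, boot)
  }
  out <- list(fit = object, table = tab, diagnostics = dg, boot = boot)
  class(out) <- "summary.svcm"
  out
}

#' @export
print.summary.svcm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nParametric effects:\n")
  tt <- x$table
  tt[] <- lapply(tt, function(v) if (is.numeric(v)) signif(v, digits) else v)
  print(tt, row.names = FALSE)
  cat("\nDeviance R-squared: ",
      format(x$diagnostics$deviance_r2, digits = digits), "\n", sep = "")
  cat("Pearson residuals: mean ",
      format(x$diagnostics$pearson_mean, digits = digits), ", variance ",
      format(x$diagnostics$pearson_var, digits = digits), "\n", sep = "")
  ph <- x$diagnostics$phi_test
  cat("Overdispersion test: phi_hat = ",
      format(ph$phi_hat, digits = digits), ", z = ",
      format(ph$z, digits = digits), ", one-sided P = ",
      format.pval(ph$p, digits = digits), "\n", sep = "")
  cat("MSE: ", format(x$diagnostics$mse, digits = digits), "\n", sep = "")
  invisible(x)
}

#' One-step-ahead conditional means
#'
#' Without `newdata`, returns the fitted conditional means. With `newdata`
#' (a [quitline_series] whose dates fall inside the fitted range), evaluates
#' the fitted model on the new record: alpha is interpolated linearly
#' between fitted days; extrapolation outside the fitted date range is an
#' error (the curve estimate carries no information there).
#'
#' @param object an `svcm` fit.
#' @param newdata optional [quitline_series].
#' @param ... unused.
#' @return numeric vector of conditional means for the response days of
#'   `newdata` (or the fitted values).
#' @export
predict.svcm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (!inherits(newdata, "quitline_series")) {
    newdata <- quitline_series(newdata)
  }
  design <- build_design(newdata)
  t_fit <- as.numeric(object$design$dates)
  t_new <- as.numeric(design$dates)
  if (any(t_new < min(t_fit) | t_new > max(t_fit))) {
    stop("newdata contains dates outside the fitted range; the varying ",
         "coefficient cannot be extrapolated")
  }
  alpha <- stats::approx(t_fit, object$alpha, xout = t_new)$y
  beta <- object$coefficients[1:6]
  gamma <- object$coefficients[7:14]
  mu <- design$y_prev * (alpha + drop(design$X %*% beta)) +
    drop(design$Z %*% gamma)
  if (any(mu <= 0)) {
    warning("non-positive predicted mean at ", sum(mu <= 0), " day(s)")
  }
  mu
}

#' Simulate new series from a fitted model
#'
#' Sequentially regenerates daily counts from the fitted conditional mean,
#' starting from the observed first day (which the model treats as fixed),
#' with Poisson noise or, if `dispersion > 1`, negative-binomial noise with
#' variance `dispersion * mu`.
#'
#' @param object an `svcm` fit.
#' @param nsim number of series.
#' @param seed optional integer seed.
#' @param dispersion conditional variance inflation factor (1 = Poisson).
#' @param ... unused.
#' @return data.frame with the calendar dates and one column per simulated
#'   series (full length J; day 1 equals the observed count).
#' @export
simulate.svcm <- function(object, nsim = 1, seed = NULL, dispersion = 1,
                          ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  beta <- object$coefficients[1:6]
  gamma <- object$coefficients[7:14]
  J <- nrow(object$series)
  out <- matrix(NA_real_, J, nsim)
  zg <- drop(des$Z %*% gamma)
  xb <- drop(des$X %*% beta)
  for (s in seq_len(nsim)) {
    y <- numeric(J)
    y[1L] <- object$series$calls[1L]
    for (j in 2:J) {
      m <- max(y[j - 1L] * (object$alpha[j - 1L] + xb[j - 1L]) + zg[j - 1L],
               0)
      y[j] <- draw_count(1L, m, dispersion)
    }
    out[, s] <- y
  }
  colnames(out) <- paste0("sim_", seq_len(nsim))
  data.frame(date = object$series$date, out)
}

#' Decompose the fitted mean into its three components
#'
#' Splits each day's fitted conditional mean into the previous-day carryover
#' term Y_{j-1}(alpha_j + X_j'beta), the day-of-week immigration term, and
#' the advertising term (TARP columns of Z times their slopes).
#'
#' @param fit an `svcm` fit.
#' @return data.frame with columns `date`, `y`, `carryover`, `day_of_week`,
#'   `advertising`, `mu` (their sum).
#' @export
decompose_fit <- function(fit) {
  stopifnot(inherits(fit, "svcm"))
  des <- fit$design
  beta <- fit$coefficients[1:6]
  gamma <- fit$coefficients[7:14]
  carry <- des$y_prev * (fit$alpha + drop(des$X %*% beta))
  dow <- drop(des$X %*% gamma[1:6])
  adv <- drop(des$Z[, 7:8, drop = FALSE] %*% gamma[7:8])
  data.frame(date = des$dates, y = des$y_resp, carryover = carry,
             day_of_week = dow, advertising = adv,
             mu = carry + dow + adv)
}

#' Plot a fitted semi-varying coefficient model
#'
#' Three panels: observed counts with the fitted conditional mean, the
#' estimated varying coefficient (with a bootstrap band when supplied), and
#' the decomposition of the fitted mean.
#'
#' @param x an `svcm` fit.
#' @param band optional output of [alpha_band()].
#' @param ... unused.
#' @export
plot.svcm <- function(x, band = NULL, ...) {
  des <- x$design
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(des$dates, des$y_resp, type = "l", col = "grey40",
                 xlab = "", ylab = "calls", main = "Observed and fitted")
  graphics::lines(des$dates, x$mu, col = "red3")
  graphics::plot(des$dates, x$alpha, type = "l", xlab = "",
                 ylab = expression(alpha(t)),
                 ylim = if (is.null(band)) range(x$alpha) else
                   range(band$lower, band$upper),
                 main = "Varying coefficient")
  if (!is.null(band)) {
    graphics::lines(des$dates, band$lower, lty = 2)
    graphics::lines(des$dates, band$upper, lty = 2)
  }
  dec <- decompose_fit(x)
  graphics::plot(des$dates, dec$carryover, type = "l", xlab = "",
                 ylab = "calls",
                 ylim = range(dec$carryover, dec$day_of_week,
                              dec$advertising),
                 main = "Decomposition")
  graphics::lines(des$dates, dec$day_of_week, col = "blue3")
  graphics::lines(des$dates, dec$advertising, col = "red3")
  graphics::legend("topright",
                   c("carryover", "day of week", "advertising"),
                   col = c("black", "blue3", "red3"), lty = 1, bty = "n")
  invisible(x)
}
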