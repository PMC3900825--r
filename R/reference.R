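# The four simpler comparator models scored against the full semi-varying
# coefficient fit (Model 5) by in-sample mean square error.

#' Fit one of the four reference models
#'
#' Comparators for the full semi-varying coefficient model, all scored on
#' response days 2...J so that conditional and unconditional models see the
#' same responses:
#' \describe{
#'   \item{Model 1}{ordinary least squares of Y_j on (1, TARPs Quit,
#'     TARPs NRT) — the fixed-effects regression of earlier call-volume
#'     studies (Gaussian response).}
#'   \item{Model 2}{the same mean, fitted as an identity-link Poisson.}
#'   \item{Model 3}{the full conditional model with the varying coefficient
#'     replaced by a single constant carryover alpha, fitted by the same
#'     quasi-Poisson machinery with the constant as an ordinary parametric
#'     coefficient.}
#'   \item{Model 4}{a varying carryover alpha_j and the immigration term
#'     Z_j'gamma, but no day-of-week modifiers of the carryover (no
#'     X_j'beta).}
#' }
#'
#' @param series a [quitline_series].
#' @param model_id integer 1-4.
#' @param bandwidth,kernel smoothing settings for Model 4 (ignored
#'   otherwise); `"auto"` selects by the same CV rule as [svcm()].
#' @param ... passed to the backfit (`variance_weights`, `tol`, `max_iter`).
#' @return an object of class `svcm_ref`: list with `model_id`,
#'   `coefficients`, `mu` (fitted means on days 2...J), `mse`, and for
#'   Model 4 the fitted `alpha` curve.
#' @export
fit_reference_model <- function(series, model_id, bandwidth = "auto",
                                kernel = c("epanechnikov", "gaussian"),
                                ...) {
  kernel <- match.arg(kernel)
  if (!inherits(series, "quitline_series")) series <- quitline_series(series)
  stopifnot(model_id %in% 1:4)
  design <- build_design(series)
  y <- design$y_resp
  n <- length(y)

  if (model_id %in% 1:2) {
    D <- cbind(`(Intercept)` = rep(1, n),
               TARPs_Quit = design$Z[, "TARPs_Quit"],
               TARPs_NRT = design$Z[, "TARPs_NRT"])
    if (model_id == 1L) {
      f <- stats::lm.fit(D, y)
      co <- f$coefficients
      mu <- drop(D %*% co)
    } else {
      f <- irls_identity(y, D)
      co <- f$coefficients
      mu <- f$mu
    }
    alpha <- NULL
  } else if (model_id == 3L) {
    D <- cbind(alpha = design$y_prev, design$y_prev * design$X, design$Z)
    colnames(D) <- c("alpha", paste0("beta_", DAY_LABELS),
                     paste0("gamma_", colnames(design$Z)))
    f <- irls_identity(y, D)
    co <- f$coefficients
    mu <- f$mu
    alpha <- NULL
  } else {
    if (identical(bandwidth, "auto")) bandwidth <- default_bandwidth(n)
    W <- kernel_matrix(design$time, bandwidth, kernel)
    bf <- svcm_backfit(design, W, include_beta = FALSE,
                       time = design$time, bandwidth = bandwidth,
                       kernel = kernel, ...)
    co <- c(bf$gamma)
    names(co) <- paste0("gamma_", colnames(design$Z))
    mu <- bf$mu
    alpha <- bf$alpha
  }
  out <- list(model_id = model_id, coefficients = co, mu = mu,
              alpha = alpha, mse = mean((y - mu)^2),
              description = reference_model_labels()[model_id])
  class(out) <- "svcm_ref"
  out
}

reference_model_labels <- function() {
  c("Model 1: E(Y) = a + g7 TARPs_Quit + g8 TARPs_NRT (Gaussian)",
    "Model 2: E(Y) = a + g7 TARPs_Quit + g8 TARPs_NRT (Poisson)",
    "Model 3: E(Y|F) = Y_prev (a + X'b) + Z'g (constant carryover)",
    "Model 4: E(Y|F) = Y_prev a_j + Z'g (no day modifiers)",
    "Model 5: E(Y|F) = Y_prev (a_j + X'b) + Z'g (semi-varying coefficient)")
}

#' @export
print.svcm_ref <- function(x, ...) {
  cat(x$description, "\n  MSE:", format(x$mse, digits = 6), "\n")
  invisible(x)
}

#' Five-model mean-square-error comparison
#'
#' Fits the four reference models and the full semi-varying coefficient
#' model and reports each in-sample MSE on the common window of response
#' days 2...J.
#'
#' @param series a [quitline_series].
#' @param bandwidth smoothing bandwidth for Models 4 and 5 (days), or
#'   `"auto"`.
#' @param ... passed to [svcm()] and [fit_reference_model()].
#' @return data.frame with columns `model`, `description`, `mse`.
#' @export
compare_models <- function(series, bandwidth = "auto", ...) {
  if (!inherits(series, "quitline_series")) series <- quitline_series(series)
  if (identical(bandwidth, "auto")) {
    bandwidth <- as.numeric(select_bandwidth(series))
  }
  fits <- lapply(1:4, function(m) {
    fit_reference_model(series, m, bandwidth = bandwidth, ...)
  })
  f5 <- svcm(series, bandwidth = bandwidth, ...)
  mse5 <- mean((f5$design$y_resp - f5$mu)^2)
  data.frame(model = 1:5,
             description = reference_model_labels(),
             mse = c(vapply(fits, function(f) f$mse, numeric(1)), mse5))
}
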