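# Shared fixtures and independent oracles, built in code.

# Quick series builder: consecutive days from a Sunday start.
make_series <- function(calls, start = "2000-08-06", tarp_quit = NULL,
                        tarp_nrt = NULL) {
  J <- length(calls)
  if (is.null(tarp_quit)) tarp_quit <- rep(0, J)
  if (is.null(tarp_nrt)) tarp_nrt <- rep(0, J)
  quitline_series(data.frame(date = as.Date(start) + 0:(J - 1),
                             calls = calls, tarp_quit = tarp_quit,
                             tarp_nrt = tarp_nrt))
}

# A small synthetic design object (bypasses series validation) for smoother
# unit tests where exact non-integer responses are needed.
make_design <- function(time, y_prev, y_resp,
                        X = matrix(0, length(time), 6),
                        Z = cbind(X, 0, 0)) {
  colnames(X) <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
  colnames(Z) <- c(colnames(X), "TARPs_Quit", "TARPs_NRT")
  structure(list(X = X, Z = Z, y_prev = y_prev, y_resp = y_resp,
                 dates = as.Date("2000-08-06") + time,
                 time = as.numeric(time)),
            class = "svcm_design")
}

# Independent brute-force local-linear oracle: per-target-point weighted
# lm() on the partial residuals.
brute_alpha <- function(design, beta, gamma, bandwidth,
                        kernel = "epanechnikov", weights = NULL) {
  t <- design$time
  n <- length(t)
  R <- design$y_resp - design$y_prev * as.vector(design$X %*% beta) -
    as.vector(design$Z %*% gamma)
  K <- function(u) {
    if (kernel == "epanechnikov") 0.75 * pmax(0, 1 - u^2) * (abs(u) < 1)
    else dnorm(u)
  }
  vapply(seq_len(n), function(i) {
    w <- K((t - t[i]) / bandwidth)
    if (!is.null(weights)) w <- w * weights
    u1 <- design$y_prev
    u2 <- design$y_prev * (t - t[i])
    keep <- w > 0
    fit <- lm(R[keep] ~ 0 + u1[keep] + u2[keep], weights = w[keep])
    unname(coef(fit)[1])
  }, numeric(1))
}

# Independent identity-link quasi-Poisson solver (plain fixed-point IRLS
# written differently from the package's QR-based path).
oracle_irls <- function(y, D, offset = 0, iter = 200) {
  th <- solve(crossprod(D), crossprod(D, y - offset))
  for (i in seq_len(iter)) {
    mu <- pmax(offset + as.vector(D %*% th), 0.5)
    w <- 1 / mu
    th <- solve(t(D) %*% (D * w), t(D) %*% ((y - offset) * w))
  }
  as.vector(th)
}
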