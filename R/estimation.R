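# Estimation machinery: local-linear kernel smoothing of the varying
# coefficient alpha(t), identity-link quasi-Poisson estimating equations for
# the parametric part, and the profile backfitting loop tying them together.

MU_EPS <- 1e-8

# Variance weights 1/mu explode when an identity-link working mean crosses
# zero (the mean is clipped at MU_EPS for positivity, giving weights of
# 1e8 that let a few degenerate days dominate the weighted solve). Working
# weights are therefore floored at half a count, which is inert whenever
# the fit is healthy (means of count data are >> 0.5) and stabilising when
# it is not.
W_FLOOR <- 0.5

kernel_fun <- function(kernel) {
  switch(kernel,
         epanechnikov = function(u) ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0),
         gaussian = function(u) stats::dnorm(u),
         stop("unknown kernel: ", kernel))
}

# Kernel weight matrix W[i, j] = K((t_j - t_i)/h); rows index target points.
kernel_matrix <- function(time, bandwidth, kernel) {
  K <- kernel_fun(kernel)
  U <- outer(time, time, "-") / bandwidth
  K(-U) # K symmetric in both kernels; sign kept for clarity
}

#' Rule-of-thumb smoothing bandwidth
#'
#' Ten days for a year-long daily series - narrow enough to resolve
#' week-scale surges while averaging over the weekly cycle - scaled at the
#' local-linear optimal rate n^(4/5), under which both the variance and the
#' squared bias of the smooth-trend estimate rescale by the same factor
#' when the observation window doubles.
#'
#' @param n number of response days.
#' @return bandwidth in days.
#' @export
default_bandwidth <- function(n) 10 * (n / 360)^(4 / 5)

#' Local-linear estimate of the varying coefficient
#'
#' For each target day t0, solves the kernel-weighted least-squares problem
#' min over (a, b) of sum_j w_j(t0) (R_j - y_prev_j (a + b (t_j - t0)))^2,
#' where R_j = Y_j - y_prev_j X_j'beta - Z_j'gamma is the partial residual
#' with the parametric part removed, and returns alpha_hat(t0) = a.
#'
#' @param design an `svcm_design` from [build_design()].
#' @param beta,gamma current parametric coefficients (lengths 6 and 8).
#' @param bandwidth kernel bandwidth in days.
#' @param kernel `"epanechnikov"` (default, compact support) or `"gaussian"`.
#' @param weights optional extra multiplicative weights per day (the backfit
#'   passes quasi-Poisson variance weights 1/mu); default all 1.
#' @return numeric vector alpha_hat at every response day.
#' @details Days with `y_prev = 0` carry no information about the carryover
#'   rate and receive zero weight automatically. If fewer than 2 such
#'   informative days fall inside a target day's kernel window, the window is
#'   widened at that point (bandwidth doubled until 2 are covered) and a
#'   warning is issued. Local-linear fitting uses asymmetric windows as-is at
#'   the series ends; no reflection.
#' @export
local_linear_alpha <- function(design, beta, gamma, bandwidth,
                               kernel = c("epanechnikov", "gaussian"),
                               weights = NULL) {
  kernel <- match.arg(kernel)
  W <- kernel_matrix(design$time, bandwidth, kernel)
  ll_smooth(design, beta, gamma, W, weights = weights,
            time = design$time, bandwidth = bandwidth, kernel = kernel)
}

# Vectorized local-linear solve given a precomputed kernel matrix W.
# loo = TRUE zeroes the self-weight (leave-one-out, for cross-validation).
ll_smooth <- function(design, beta, gamma, W, weights = NULL, time,
                      bandwidth, kernel, loo = FALSE) {
  yp <- design$y_prev
  n <- length(yp)
  R <- design$y_resp - yp * drop(design$X %*% beta) - drop(design$Z %*% gamma)
  v <- if (is.null(weights)) rep(1, n) else weights
  if (loo) diag(W) <- 0

  active <- yp > 0 & v > 0
  if (sum(active) < 2L) {
    warning("fewer than 2 days with positive previous-day counts; ",
            "varying coefficient not identifiable, returning zeros")
    return(rep(0, n))
  }

  cw <- v * yp^2
  dw <- v * yp * R
  t1 <- time
  M0 <- drop(W %*% cw)
  M1 <- drop(W %*% (cw * t1))
  M2 <- drop(W %*% (cw * t1^2))
  B0 <- drop(W %*% dw)
  B1 <- drop(W %*% (dw * t1))
  S11 <- M0
  S12 <- M1 - t1 * M0
  S22 <- M2 - 2 * t1 * M1 + t1^2 * M0
  b1 <- B0
  b2 <- B1 - t1 * B0
  det <- S11 * S22 - S12^2

  alpha <- rep(NA_real_, n)
  ok <- det > 1e-10 * pmax(S11 * S22, .Machine$double.xmin)
  alpha[ok] <- (S22[ok] * b1[ok] - S12[ok] * b2[ok]) / det[ok]
  # fall back to a local-constant solve where the local design is singular
  lc <- !ok & S11 > 0
  alpha[lc] <- b1[lc] / S11[lc]

  # effective local sample: informative days with positive kernel weight
  n_eff <- drop((W > 0) %*% as.numeric(active))
  starved <- which(n_eff < 2 | !(ok | lc))
  if (length(starved) > 0L) {
    span <- diff(range(time))
    for (i in starved) {
      h <- bandwidth
      repeat {
        h <- 2 * h
        w <- kernel_fun(kernel)((time - time[i]) / h)
        if (loo) w[i] <- 0
        if (sum(w > 0 & active) >= 2L || h > 4 * span) break
      }
      alpha[i] <- ll_point(time[i], time, w * v, yp, R)
    }
    warning("kernel window widened at ", length(starved),
            " target day(s) with fewer than 2 informative neighbours")
  }
  alpha
}

# Single-point weighted local-linear solve (scalar fallback path).
ll_point <- function(t0, time, w, yp, R) {
  u1 <- yp
  u2 <- yp * (time - t0)
  S11 <- sum(w * u1^2); S12 <- sum(w * u1 * u2); S22 <- sum(w * u2^2)
  b1 <- sum(w * u1 * R); b2 <- sum(w * u2 * R)
  det <- S11 * S22 - S12^2
  if (det > 1e-10 * max(S11 * S22, .Machine$double.xmin)) {
    (S22 * b1 - S12 * b2) / det
  } else if (S11 > 0) {
    b1 / S11
  } else {
    0
  }
}

# Identity-link quasi-Poisson IRLS: solves sum_j (y_j - mu_j)/mu_j d_j = 0
# with mu = offset + D theta, weights 1/max(mu, eps).
irls_identity <- function(y, D, offset = 0, eps = MU_EPS, init = NULL,
                          max_iter = 50L, tol = 1e-10,
                          on_singular = c("error", "warn"),
                          fixed_weights = NULL) {
  on_singular <- match.arg(on_singular)
  D <- as.matrix(D)
  p <- ncol(D)
  yo <- y - offset
  theta <- if (is.null(init)) NULL else init
  singular_cols <- character(0)

  solve_wls <- function(w) {
    sw <- sqrt(w)
    qr_d <- qr(D * sw)
    if (qr_d$rank < p) {
      aliased <- colnames(D)[qr_d$pivot[(qr_d$rank + 1L):p]]
      msg <- paste0("collinear design column(s): ",
                    paste(aliased, collapse = ", "))
      if (on_singular == "error") stop(msg)
      if (length(singular_cols) == 0L) {
        warning(msg, "; degenerate fit, aliased coefficients set to 0")
      }
      singular_cols <<- aliased
      co <- rep(0, p)
      keep <- qr_d$pivot[seq_len(qr_d$rank)]
      co[keep] <- qr.coef(qr(D[, keep, drop = FALSE] * sw), yo * sw)
      co
    } else {
      drop(qr.coef(qr_d, yo * sw))
    }
  }

  if (is.null(theta)) theta <- solve_wls(rep(1, length(y)))
  if (!is.null(fixed_weights)) {
    theta <- solve_wls(fixed_weights)
    mu <- offset + drop(D %*% theta)
    return(list(coefficients = theta, mu = mu, n_iter = 1L,
                converged = TRUE, aliased = singular_cols))
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- offset + drop(D %*% theta)
    w <- 1 / pmax(mu, W_FLOOR)
    theta_new <- solve_wls(w)
    delta <- max(abs(theta_new - theta) / pmax(abs(theta), 1))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- offset + drop(D %*% theta)
  list(coefficients = theta, mu = mu, n_iter = it, converged = converged,
       aliased = singular_cols)
}

#' Quasi-Poisson fit of the parametric coefficients given the curve
#'
#' Solves the identity-link quasi-Poisson estimating equations for
#' (beta, gamma) with the varying-coefficient term as a fixed offset
#' o_j = y_prev_j alpha_j, i.e. iteratively reweighted least squares of the
#' conditional mean mu_j = o_j + y_prev_j X_j'beta + Z_j'gamma with working
#' weights 1/max(mu_j, eps).
#'
#' @param design an `svcm_design`.
#' @param alpha fixed varying-coefficient values (length J-1, or scalar).
#' @param variance_weights if `FALSE`, a single unit-weight least-squares
#'   solve is returned instead (ordinary least squares on the
#'   offset-adjusted response).
#' @param eps positivity clip for the working mean inside the solver.
#' @return list with `beta` (6), `gamma` (8), `mu`, `converged`.
#' @export
fit_parametric_given_alpha <- function(design, alpha, variance_weights = TRUE,
                                       eps = MU_EPS) {
  yp <- design$y_prev
  n <- length(yp)
  if (length(alpha) == 1L) alpha <- rep(alpha, n)
  D <- cbind(design$X * yp, design$Z)
  colnames(D) <- c(paste0("beta_", DAY_LABELS),
                   paste0("gamma_", colnames(design$Z)))
  fw <- if (variance_weights) NULL else rep(1, n)
  fit <- irls_identity(design$y_resp, D, offset = yp * alpha, eps = eps,
                       on_singular = "error", fixed_weights = fw)
  list(beta = unname(fit$coefficients[1:6]),
       gamma = unname(fit$coefficients[7:14]),
       mu = fit$mu, converged = fit$converged)
}

# Initial values per the package's scheme: gamma from an identity-link
# Poisson of Y on day dummies + TARPs (intercept absorbed), beta = 0, alpha
# constant at the profiled estimate given those.
svcm_init <- function(design, eps = MU_EPS) {
  n <- length(design$y_resp)
  D2 <- cbind(`(Intercept)` = rep(1, n), design$Z)
  f2 <- irls_identity(design$y_resp, D2, eps = eps, on_singular = "warn")
  gamma0 <- unname(f2$coefficients[-1L])
  off <- drop(design$Z %*% gamma0)
  a0 <- irls_identity(design$y_resp, cbind(alpha = design$y_prev),
                      offset = off, eps = eps,
                      on_singular = "warn")$coefficients[[1L]]
  list(alpha = rep(a0, n), beta = rep(0, 6), gamma = gamma0)
}

# Profile backfitting core shared by the full model and the no-beta variant
# (reference Model 4). Alternates the local-linear smoother (parametric part
# held fixed) with a weighted least-squares update of the parametric
# coefficients (curve held fixed), the quasi-Poisson variance weights being
# refreshed from the current mean at each iteration (IRLS interleaved with
# the smoothing). Backfitting converges linearly and the rate can approach 1
# when the smooth term is nearly collinear with the pulsed advertising
# covariates (several slow modes), so the plain alternation is wrapped in
# Anderson acceleration (depth 5) on the joint state (alpha, beta, gamma);
# the accelerated candidate is accepted only if it does not increase the
# iteration's weighted RSS relative to the plain step. The criterion is
# evaluated on the affine (unclipped) mean, where the weighted LS objective
# is exactly quadratic; clipping applies to the variance weights (floored at
# W_FLOOR) and the returned fitted means. A catastrophic-divergence
# safeguard reverts to the best iterate seen if the criterion ever blows up
# past 10 times its running minimum.
svcm_backfit <- function(design, W, include_beta = TRUE,
                         variance_weights = TRUE, tol = 1e-6,
                         max_iter = 300L, eps = MU_EPS, init = NULL,
                         time, bandwidth, kernel) {
  yp <- design$y_prev
  y <- design$y_resp
  n <- length(y)
  if (is.null(init)) init <- svcm_init(design, eps)
  alpha <- init$alpha
  beta <- if (include_beta) init$beta else rep(0, 6)
  gamma <- init$gamma

  Dpar <- if (include_beta) {
    cbind(design$X * yp, design$Z)
  } else {
    design$Z
  }

  mu_of <- function(alpha, beta, gamma) {
    yp * (alpha + drop(design$X %*% beta)) + drop(design$Z %*% gamma)
  }
  mu <- mu_of(alpha, beta, gamma)

  # one plain backfit sweep: smoother given (beta, gamma), then WLS given
  # the new curve, under the supplied variance weights
  sweep <- function(state, v) {
    alpha_c <- state[seq_len(n)]
    beta_c <- state[n + seq_len(6L)]
    gamma_c <- state[n + 6L + seq_len(8L)]
    alpha_new <- ll_smooth(design, beta_c, gamma_c, W, weights = v,
                           time = time, bandwidth = bandwidth,
                           kernel = kernel)
    fpar <- irls_identity(y, Dpar, offset = yp * alpha_new, eps = eps,
                          on_singular = "warn", fixed_weights = v)
    theta_new <- fpar$coefficients
    beta_new <- if (include_beta) unname(theta_new[1:6]) else rep(0, 6)
    gamma_new <- if (include_beta) {
      unname(theta_new[7:14])
    } else {
      unname(theta_new[1:8])
    }
    c(alpha_new, beta_new, gamma_new)
  }
  wrss_of <- function(state, v) {
    m <- mu_of(state[seq_len(n)], state[n + seq_len(6L)],
               state[n + 6L + seq_len(8L)])
    sum(v * (y - m)^2)
  }

  state <- c(alpha, beta, gamma)
  depth <- 5L
  S_hist <- NULL # states s_k
  F_hist <- NULL # residuals G(s_k) - s_k
  wrss_trace <- numeric(0)
  converged <- FALSE
  diverged <- FALSE
  it <- 0L
  best <- list(wrss = Inf, state = state)
  for (it in seq_len(max_iter)) {
    v <- if (variance_weights) 1 / pmax(mu, W_FLOOR) else rep(1, n)
    g_state <- sweep(state, v)
    f_res <- g_state - state
    delta <- max(abs(f_res) / pmax(abs(state), 1))
    wrss_plain <- wrss_of(g_state, v)

    S_hist <- cbind(S_hist, state)
    F_hist <- cbind(F_hist, f_res)
    if (ncol(S_hist) > depth) {
      S_hist <- S_hist[, -1L, drop = FALSE]
      F_hist <- F_hist[, -1L, drop = FALSE]
    }

    accepted <- g_state
    wrss_after <- wrss_plain
    m <- ncol(F_hist)
    if (m >= 2L) {
      dF <- F_hist[, -1L, drop = FALSE] - F_hist[, -m, drop = FALSE]
      dS <- S_hist[, -1L, drop = FALSE] - S_hist[, -m, drop = FALSE]
      th <- tryCatch(qr.solve(dF, f_res, tol = 1e-12),
                     error = function(e) NULL)
      if (!is.null(th) && all(is.finite(th))) {
        cand <- g_state - (dS + dF) %*% th
        cand <- drop(cand)
        if (all(is.finite(cand))) {
          wrss_cand <- wrss_of(cand, v)
          # the extrapolated state may sit slightly uphill in the current
          # iteration's criterion while being much closer to the fixed
          # point, so allow a generous factor; the divergence safeguard
          # below bounds the damage of a bad jump
          if (is.finite(wrss_cand) && wrss_cand <= 1.5 * wrss_plain) {
            accepted <- cand
            wrss_after <- wrss_cand
          }
        }
      }
    }
    state <- accepted
    mu <- mu_of(state[seq_len(n)], state[n + seq_len(6L)],
                state[n + 6L + seq_len(8L)])
    wrss_trace <- c(wrss_trace, wrss_after)
    if (is.finite(wrss_after) && wrss_after < best$wrss) {
      best <- list(wrss = wrss_after, state = state)
    } else if (!is.finite(wrss_after) || wrss_after > 10 * best$wrss) {
      state <- best$state
      mu <- mu_of(state[seq_len(n)], state[n + seq_len(6L)],
                  state[n + 6L + seq_len(8L)])
      diverged <- TRUE
      break
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  alpha <- state[seq_len(n)]
  beta <- state[n + seq_len(6L)]
  gamma <- state[n + 6L + seq_len(8L)]
  list(alpha = alpha, beta = beta, gamma = gamma, mu = pmax(mu, eps),
       converged = converged, diverged = diverged, n_iter = it,
       wrss = wrss_trace)
}

#' Fit the semi-varying coefficient conditional Poisson model
#'
#' Fits E(Y_j | F_{j-1}) = Y_{j-1} (alpha_j + X_j' beta) + Z_j' gamma to a
#' daily call series: a smooth time-varying carryover rate alpha(t),
#' day-of-week modifiers beta of the carryover, and an immigration term with
#' day-of-week effects and TARP (advertising weight) slopes gamma.
#' Estimation alternates a local-linear kernel smoother for alpha(t) on
#' partial residuals with identity-link quasi-Poisson estimating equations
#' for (beta, gamma), until joint convergence (profile backfitting).
#'
#' @param series a [quitline_series] (or a data.frame coercible to one).
#' @param bandwidth smoothing bandwidth in days, or `"auto"` for
#'   leave-one-out cross-validation over `bandwidth_grid`.
#' @param kernel `"epanechnikov"` (default) or `"gaussian"`.
#' @param variance_weights use quasi-Poisson weights 1/mu in the smoother
#'   and the parametric step (default `TRUE`).
#' @param tol convergence threshold on the maximum relative parameter change
#'   across (beta, gamma) and the alpha grid.
#' @param max_iter cap on backfit iterations; non-convergence is returned
#'   with `converged = FALSE` and a warning, never silently.
#' @param bandwidth_grid candidate bandwidths for `bandwidth = "auto"`.
#' @param eps positivity clip applied to the working conditional mean inside
#'   the solvers (the public [conditional_mean()] contract remains strict).
#' @return an object of class `svcm` with components `coefficients` (named
#'   vector: beta_Mon...beta_Sat, gamma_Mon...gamma_Sat, gamma_TARPs_Quit,
#'   gamma_TARPs_NRT), `alpha` (curve on response days), `fitted.values`,
#'   `bandwidth`, `converged`, `n_iter`, `wrss` (per-iteration weighted RSS
#'   trace), `series`, `design`.
#' @seealso [boot_svcm()] for standard errors, [svcm_diagnostics()],
#'   [compare_models()].
#' @examples
#' sim <- simulate_calls(sim_config(n_days = 120, seed = 1))
#' fit <- svcm(sim$series, bandwidth = 14)
#' coef(fit)
#' @export
svcm <- function(series, bandwidth = "auto",
                 kernel = c("epanechnikov", "gaussian"),
                 variance_weights = TRUE, tol = 1e-6, max_iter = 300L,
                 bandwidth_grid = c(7, 10, 14, 21, 30), eps = MU_EPS) {
  kernel <- match.arg(kernel)
  if (!inherits(series, "quitline_series")) series <- quitline_series(series)
  design <- build_design(series)
  n <- length(design$y_resp)
  if (n < 20L) {
    warning("only ", n, " response days; fits with fewer than 20 days ",
            "are unreliable")
  }
  for (nm in c("tarp_quit", "tarp_nrt")) {
    if (all(series[[nm]] == 0)) {
      stop("degenerate design: column '", nm, "' is identically zero")
    }
  }
  if (stats::sd(design$y_resp) == 0) {
    warning("constant call counts: degenerate fit (day-of-week terms are ",
            "collinear with the carryover)")
  }

  cv <- NULL
  if (identical(bandwidth, "auto")) {
    bw <- select_bandwidth(series, bandwidth_grid = bandwidth_grid,
                           kernel = kernel,
                           variance_weights = variance_weights,
                           tol = tol, max_iter = max_iter, eps = eps)
    cv <- attr(bw, "cv")
    bandwidth <- as.numeric(bw)
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)

  W <- kernel_matrix(design$time, bandwidth, kernel)
  bf <- svcm_backfit(design, W, include_beta = TRUE,
                     variance_weights = variance_weights, tol = tol,
                     max_iter = max_iter, eps = eps,
                     time = design$time, bandwidth = bandwidth,
                     kernel = kernel)
  if (bf$diverged) {
    warning("backfitting diverged; returning the best iterate seen")
  } else if (!bf$converged) {
    warning("backfitting did not converge in ", max_iter,
            " iterations (returning the last iterate)")
  }
  theta <- c(bf$beta, bf$gamma)
  names(theta) <- c(paste0("beta_", DAY_LABELS),
                    paste0("gamma_", colnames(design$Z)))
  out <- list(coefficients = theta, alpha = bf$alpha, mu = bf$mu,
              fitted.values = bf$mu, bandwidth = bandwidth, kernel = kernel,
              variance_weights = variance_weights, converged = bf$converged,
              n_iter = bf$n_iter, wrss = bf$wrss, cv = cv,
              series = series, design = design,
              control = list(tol = tol, max_iter = max_iter, eps = eps),
              call = match.call())
  class(out) <- "svcm"
  out
}

#' Cross-validated bandwidth selection
#'
#' For each candidate bandwidth the full model is fitted (warm-started along
#' the grid) and scored by leave-one-out cross-validation of the squared
#' prediction error: each day's alpha_hat is recomputed with that day's
#' kernel weight removed, the parametric part held fixed. Selection follows
#' the one-standard-error rule: the largest (smoothest) bandwidth whose
#' score lies within one standard error of the minimum, so flat CV curves
#' and exact ties both resolve toward the smoother fit.
#'
#' @param series a [quitline_series].
#' @param bandwidth_grid candidate bandwidths in days.
#' @inheritParams svcm
#' @return the selected bandwidth, with the CV table (score and its
#'   standard error per candidate) as attribute `"cv"`.
#' @export
select_bandwidth <- function(series, bandwidth_grid = c(7, 10, 14, 21, 30),
                             kernel = c("epanechnikov", "gaussian"),
                             variance_weights = TRUE, tol = 1e-6,
                             max_iter = 300L, eps = MU_EPS) {
  kernel <- match.arg(kernel)
  if (!inherits(series, "quitline_series")) series <- quitline_series(series)
  stopifnot(length(bandwidth_grid) >= 1L, all(bandwidth_grid > 0))
  if (length(bandwidth_grid) == 1L) {
    message("bandwidth grid has a single value; returning it as-is")
    return(structure(bandwidth_grid,
                     cv = data.frame(bandwidth = bandwidth_grid,
                                     cv = NA_real_, cv_se = NA_real_)))
  }
  design <- build_design(series)
  grid <- sort(unique(bandwidth_grid))
  n <- length(design$y_resp)
  scores <- numeric(length(grid))
  score_se <- numeric(length(grid))
  init <- NULL
  for (k in seq_along(grid)) {
    h <- grid[k]
    W <- kernel_matrix(design$time, h, kernel)
    bf <- svcm_backfit(design, W, include_beta = TRUE,
                       variance_weights = variance_weights, tol = tol,
                       max_iter = max_iter, eps = eps, init = init,
                       time = design$time, bandwidth = h, kernel = kernel)
    init <- list(alpha = bf$alpha, beta = bf$beta, gamma = bf$gamma)
    v <- if (variance_weights) 1 / pmax(bf$mu, W_FLOOR) else NULL
    alpha_loo <- ll_smooth(design, bf$beta, bf$gamma, W, weights = v,
                           time = design$time, bandwidth = h,
                           kernel = kernel, loo = TRUE)
    mu_loo <- design$y_prev *
      (alpha_loo + drop(design$X %*% bf$beta)) +
      drop(design$Z %*% bf$gamma)
    sq <- (design$y_resp - mu_loo)^2
    scores[k] <- mean(sq)
    score_se[k] <- stats::sd(sq) / sqrt(n)
  }
  # one-standard-error rule: among bandwidths whose CV score is within one
  # standard error of the minimum, prefer the largest (smoothest); a flat
  # CV curve therefore resolves to the smoothest candidate
  k_min <- which.min(scores)
  best <- max(grid[scores <= scores[k_min] + score_se[k_min]])
  structure(best, cv = data.frame(bandwidth = grid, cv = scores,
                                  cv_se = score_se))
}
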