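#' Construct and validate a daily call-count series
#'
#' A `quitline_series` is the package's basic data object: one row per
#' consecutive calendar day, holding the observed call count and the
#' television advertising weight (TARPs, target audience rating points) of
#' the two campaigns ("Quit" and nicotine replacement therapy, "NRT").
#'
#' @param data a data.frame with columns `date` (Date or ISO-8601 string),
#'   `calls` (non-negative integer), `tarp_quit` and `tarp_nrt`
#'   (non-negative numeric).
#' @return an object of class `quitline_series`: a data.frame with the four
#'   columns coerced and validated, `J = nrow(data)` consecutive days.
#' @details Dates must advance by exactly one day with no gaps, and at least
#'   8 days (one full week plus the conditioning day) are required. Day 1 is
#'   used only as the conditioning day of the autoregression.
#' @examples
#' d <- data.frame(date = as.Date("2000-08-06") + 0:13,
#'                 calls = rpois(14, 30), tarp_quit = 0, tarp_nrt = 0)
#' s <- quitline_series(d)
#' @export
quitline_series <- function(data) {
  required <- c("date", "calls", "tarp_quit", "tarp_nrt")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  date <- tryCatch(as.Date(data$date), error = function(e) {
    stop("column 'date' is not interpretable as calendar dates: ",
         conditionMessage(e))
  })
  if (anyNA(date)) stop("column 'date' contains missing or unparseable dates")
  J <- length(date)
  if (J < 8L) stop("need at least 8 consecutive days (got ", J, ")")
  dd <- diff(as.integer(date))
  if (any(dd != 1L)) {
    k <- which(dd != 1L)[1L]
    stop("dates must be consecutive days; gap between ",
         format(date[k]), " and ", format(date[k + 1L]))
  }
  y <- data$calls
  if (!is.numeric(y)) stop("column 'calls' must be numeric")
  if (anyNA(y) || any(!is.finite(y))) stop("column 'calls' contains missing values")
  if (any(y < 0)) {
    stop("negative call count at row ", which(y < 0)[1L])
  }
  if (any(abs(y - round(y)) > 1e-8)) {
    stop("non-integer call count at row ", which(abs(y - round(y)) > 1e-8)[1L])
  }
  for (nm in c("tarp_quit", "tarp_nrt")) {
    v <- data[[nm]]
    if (!is.numeric(v)) stop("column '", nm, "' must be numeric")
    if (anyNA(v) || any(!is.finite(v))) stop("column '", nm, "' contains non-finite values")
    if (any(v < 0)) stop("negative TARP value in '", nm, "' at row ", which(v < 0)[1L])
  }
  out <- data.frame(date = date, calls = as.integer(round(y)),
                    tarp_quit = as.numeric(data$tarp_quit),
                    tarp_nrt = as.numeric(data$tarp_nrt))
  class(out) <- c("quitline_series", "data.frame")
  out
}

#' Read a daily series from CSV
#'
#' @param path CSV file with columns `date`, `calls`, `tarp_quit`, `tarp_nrt`.
#' @return a validated [quitline_series].
#' @export
read_series <- function(path) {
  quitline_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a daily series to CSV
#'
#' @param series a [quitline_series].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.quitline_series <- function(x, ...) {
  cat("Daily call series: ", nrow(x), " days, ",
      format(x$date[1L]), " to ", format(x$date[nrow(x)]), "\n", sep = "")
  cat("  calls: median ", stats::median(x$calls),
      ", range [", min(x$calls), ", ", max(x$calls), "]\n", sep = "")
  cat("  days with advertising: Quit ", sum(x$tarp_quit > 0),
      ", NRT ", sum(x$tarp_nrt > 0), "\n", sep = "")
  invisible(x)
}

# Locale-independent day-of-week: 0 = Sunday ... 6 = Saturday.
day_of_week <- function(date) as.POSIXlt(date)$wday

DAY_LABELS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat")

#' Build the model's design matrices
#'
#' Aligns the series to response days j = 2...J (day 1 conditions the
#' autoregression) and constructs the day-of-week indicator matrix `X`
#' (Sunday is the reference: an all-zero row) and the immigration design
#' `Z = [X | tarp_quit | tarp_nrt]`.
#'
#' @param series a [quitline_series].
#' @return a list of class `svcm_design` with elements `X` ((J-1) x 6),
#'   `Z` ((J-1) x 8), `y_prev` (Y_{j-1}), `y_resp` (Y_j), `dates` (response
#'   days), `time` (response-day index, in days, used by the smoother).
#' @details Day of week is taken from the calendar date, not row position,
#'   so arbitrary start days and partial weeks are handled. Column order is
#'   fixed as (Mon, Tue, Wed, Thu, Fri, Sat) and, for `Z`, the two TARP
#'   columns last.
#' @export
build_design <- function(series) {
  stopifnot(inherits(series, "quitline_series"))
  J <- nrow(series)
  idx <- 2:J
  dow <- day_of_week(series$date[idx])
  X <- matrix(0, nrow = J - 1L, ncol = 6L,
              dimnames = list(NULL, DAY_LABELS))
  for (d in 1:6) X[dow == d, d] <- 1
  Z <- cbind(X,
             TARPs_Quit = series$tarp_quit[idx],
             TARPs_NRT = series$tarp_nrt[idx])
  out <- list(X = X, Z = Z,
              y_prev = as.numeric(series$calls[idx - 1L]),
              y_resp = as.numeric(series$calls[idx]),
              dates = series$date[idx],
              time = as.numeric(idx))
  class(out) <- "svcm_design"
  out
}

#' Evaluate the model's conditional mean
#'
#' Computes mu_j = Y_{j-1} (alpha_j + X_j' beta) + Z_j' gamma for every
#' response day, the conditional mean of the semi-varying coefficient
#' autoregressive Poisson model.
#'
#' @param params list with `alpha` (length J-1), `beta` (length 6, carryover
#'   modifiers Mon...Sat), `gamma` (length 8, immigration effects: Mon...Sat
#'   in calls/day, then the two TARP slopes in calls per TARP).
#' @param design an `svcm_design` from [build_design()].
#' @return numeric vector of strictly positive conditional means, in day
#'   order.
#' @details Positivity is part of the contract: an identity-link Poisson
#'   mean must be positive, so any mu_j <= 0 is an error naming the
#'   offending day. (Iterative solvers clip internally instead; see
#'   [svcm()].)
#' @export
conditional_mean <- function(params, design) {
  stopifnot(inherits(design, "svcm_design"))
  alpha <- params$alpha
  beta <- params$beta
  gamma <- params$gamma
  n <- length(design$y_prev)
  if (length(alpha) == 1L) alpha <- rep(alpha, n)
  stopifnot(length(alpha) == n, length(beta) == 6L, length(gamma) == 8L)
  mu <- design$y_prev * (alpha + drop(design$X %*% beta)) +
    drop(design$Z %*% gamma)
  bad <- which(mu <= 0)
  if (length(bad) > 0L) {
    stop("non-positive conditional mean at response day index ", bad[1L],
         " (", format(design$dates[bad[1L]]), "): mu = ",
         signif(mu[bad[1L]], 4))
  }
  mu
}
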