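#' Fit a specific growth rate from an OD600 time series
#'
#' Ordinary least squares of `log(od600)` on time over the exponential
#' window.  The window is defined as the points whose OD lies between
#' `window[1]` and `window[2]` times the maximum observed OD (default
#' 5--60%, approximating early-to-mid exponential phase).  If fewer than
#' three points fall in the window but the curve has at least three
#' positive-OD points, the fit falls back to the full curve with a
#' warning; the window actually used is reported.
#'
#' @param curve a data frame with columns `time_h` and `od600` (a
#'   `culture_id` column is carried into the result if present), or the
#'   output of [generate_growth_curve()].
#' @param window numeric pair: lower and upper OD fraction of the curve
#'   maximum delimiting the fitting window.
#' @return An object of class `rate_estimate`: a list with `mu` (per
#'   hour), `mu_se`, `doubling_time` (hours, `NA` when `mu <= 0`),
#'   `r_squared`, `window` (index range used), `n_points`, and
#'   `culture_id`.
#' @examples
#' gc <- generate_growth_curve(mu = 0.16, od0 = 0.01, times = 0:20)
#' fit_growth_rate(gc)$mu   # 0.16
#' @export
fit_growth_rate <- function(curve, window = c(0.05, 0.60)) {
  times <- curve$time_h
  od <- curve$od600
  id <- if (!is.null(curve$culture_id)) curve$culture_id[1] else NA_character_
  if (length(times) != length(od)) {
    stop("time and OD vectors must align", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing (culture ", id, ")",
         call. = FALSE)
  }
  ok <- !is.na(od) & od > 0
  if (sum(ok) < 3) {
    stop("fewer than 3 positive OD points (culture ", id, ")", call. = FALSE)
  }
  mx <- max(od[ok])
  sel <- ok & od >= window[1] * mx & od <= window[2] * mx
  window_used <- "window"
  if (sum(sel) < 3) {
    warning("fewer than 3 points in the exponential window; ",
            "fitting the full curve (culture ", id, ")")
    sel <- ok
    window_used <- "full"
  }
  fit <- stats::lm(log(od[sel]) ~ times[sel])
  sm <- summary(fit)
  mu <- unname(coef(fit)[2])
  mu_se <- sm$coefficients[2, 2]
  structure(
    list(
      mu = mu,
      mu_se = mu_se,
      doubling_time = if (mu > 0) log(2) / mu else NA_real_,
      r_squared = sm$r.squared,
      window = range(which(sel)),
      window_used = window_used,
      n_points = sum(sel),
      culture_id = id
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> mu = %.4f +/- %.4f / h, T_D = %.2f h, R2 = %.4f (%d pts%s)\n",
    x$mu, x$mu_se, x$doubling_time, x$r_squared, x$n_points,
    if (identical(x$window_used, "full")) ", full curve" else ""
  ))
  invisible(x)
}

#' Doubling time from a specific growth rate
#'
#' \deqn{T_D\,(hours) = \ln(2)/\mu}
#'
#' @param mu specific growth rate in per hour; must be positive.
#' @return Doubling time in hours.
#' @examples
#' doubling_time(log(2))   # 1 hour
#' doubling_time(0.0990)   # 7.0 hours
#' @export
doubling_time <- function(mu) {
  if (any(is.na(mu)) || any(mu <= 0)) {
    stop("doubling time is undefined for mu <= 0", call. = FALSE)
  }
  log(2) / mu
}
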