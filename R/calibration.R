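#' Fit a VSMOW calibration from co-run standards
#'
#' Fits the "inverted" calibration regression with the measured raw value
#' as the response:
#' \deqn{\delta^2H_{raw} = \beta_0 + \beta_1\,\delta_{accepted} +
#'   \beta_2 A + \beta_3\,\delta_{accepted}A}
#' where \eqn{A} is peak amplitude.  \eqn{\beta_0} captures the offset
#' from the working reference gas, \eqn{\beta_1} the scale compression,
#' and the optional size terms the peak-amplitude (linearity) effect.
#' Fitting raw-on-accepted and later solving for the accepted-scale value
#' is the standard errors-in-calibration arrangement; the direct
#' orientation (accepted on raw) is available via `orientation =
#' "direct"` for comparison.
#'
#' An amplitude-dependent repeatability model is estimated from the
#' standards' residuals by amplitude-quantile bin (RMS residual per bin)
#' and stored with the fit for use in [apply_calibration()] prediction
#' errors.
#'
#' @param standards peak table (tibble/data.frame) with columns
#'   `compound`, `amplitude`, `d2h_raw`.
#' @param defs standards definitions with columns `compound`,
#'   `accepted_d2h` (and optionally `accepted_sigma`).
#' @param size_term include the linear amplitude term (default `TRUE`).
#' @param interaction include the accepted-by-amplitude interaction
#'   (default `FALSE`).
#' @param orientation `"inverted"` (raw on accepted; default) or
#'   `"direct"`.
#' @param robust if `TRUE`, drop standards with |studentized residual| > 4
#'   and refit once (logged in the fit).
#' @param n_bins number of amplitude-quantile bins for the repeatability
#'   model (reduced automatically for small standard sets).
#' @return An object of class `calibration_fit` with elements
#'   `coefficients` (named `offset`, `scale`, `size`, `interaction`),
#'   `covariance`, `residual_rmse`, `n_standards`, `amp_range`,
#'   `repeatability` (per-bin tibble), `model` (the `lm` fit), and
#'   bookkeeping flags.
#' @export
fit_calibration <- function(standards, defs, size_term = TRUE,
                            interaction = FALSE,
                            orientation = c("inverted", "direct"),
                            robust = FALSE, n_bins = 6) {
  orientation <- match.arg(orientation)
  need <- c("compound", "amplitude", "d2h_raw")
  if (!all(need %in% names(standards))) {
    stop("standards table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(unique(standards$compound), defs$compound)
  if (length(unmapped)) {
    stop("standard compound(s) without accepted values: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  d <- merge(as.data.frame(standards),
             as.data.frame(defs)[, c("compound", "accepted_d2h")],
             by = "compound")
  if (length(unique(d$accepted_d2h)) < 2) {
    stop("calibration needs >= 2 distinct accepted values", call. = FALSE)
  }
  if (size_term && length(unique(d$amplitude)) < 2) {
    stop("size terms need >= 2 distinct amplitudes", call. = FALSE)
  }
  n_coef <- 2 + size_term + interaction
  if (nrow(d) < n_coef + 1) {
    stop("too few standards (", nrow(d), ") for ", n_coef, " coefficients",
         call. = FALSE)
  }

  fit_once <- function(dd) {
    fo <- if (orientation == "inverted") {
      if (interaction) d2h_raw ~ accepted_d2h * amplitude
      else if (size_term) d2h_raw ~ accepted_d2h + amplitude
      else d2h_raw ~ accepted_d2h
    } else {
      if (interaction) accepted_d2h ~ d2h_raw * amplitude
      else if (size_term) accepted_d2h ~ d2h_raw + amplitude
      else accepted_d2h ~ d2h_raw
    }
    stats::lm(fo, data = dd)
  }

  model <- fit_once(d)
  dropped <- character(0)
  if (robust) {
    rs <- stats::rstudent(model)
    bad <- which(!is.na(rs) & abs(rs) > 4)
    if (length(bad)) {
      dropped <- d$compound[bad]
      d <- d[-bad, , drop = FALSE]
      model <- fit_once(d)
    }
  }
  cf <- coef(model)
  if (any(is.na(cf))) {
    stop("rank-deficient calibration design (collinear standards)",
         call. = FALSE)
  }
  # canonical names: offset, scale, size, interaction
  beta <- c(offset = unname(cf[1]),
            scale = unname(cf[2]),
            size = if (size_term) unname(cf["amplitude"]) else 0,
            interaction = if (interaction) unname(cf[4]) else 0)
  res <- stats::residuals(model)
  rmse <- sqrt(mean(res^2))

  # amplitude-binned repeatability (RMS residual per quantile bin)
  nb <- max(1L, min(as.integer(n_bins), nrow(d) %/% 6L))
  if (nb > 1) {
    brk <- unique(stats::quantile(d$amplitude, probs = seq(0, 1,
                                                           length.out = nb + 1)))
    bin <- cut(d$amplitude, brk, include.lowest = TRUE)
  } else {
    bin <- factor(rep("all", nrow(d)))
  }
  rep_tab <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- bin == b
    tibble::tibble(amp_mid = stats::median(d$amplitude[i]),
                   rms = sqrt(mean(res[i]^2)), n = sum(i))
  }))
  rep_tab <- rep_tab[order(rep_tab$amp_mid), , drop = FALSE]
  # smooth the binned estimates with a shot-noise law sigma(A) = a + b/A
  # (non-negative coefficients), so repeatability is non-increasing in
  # amplitude; degenerate cases collapse to a constant floor
  rep_law <- fit_repeatability_law(rep_tab)

  structure(
    list(
      coefficients = beta,
      covariance = vcov(model),
      residual_rmse = rmse,
      n_standards = nrow(d),
      amp_range = range(d$amplitude),
      repeatability = rep_tab,
      repeatability_law = rep_law,
      model = model,
      orientation = orientation,
      size_term = size_term,
      interaction = interaction,
      dropped = dropped
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> offset = %.3f permil, scale = %.4f, size = %.2e, RMSE = %.3f permil (n = %d)\n",
    x$coefficients["offset"], x$coefficients["scale"],
    x$coefficients["size"], x$residual_rmse, x$n_standards))
  if (length(x$dropped)) {
    cat("  robust refit dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

# weighted least squares of bin RMS on 1/amp_mid with both coefficients
# constrained non-negative
fit_repeatability_law <- function(rep_tab) {
  if (nrow(rep_tab) < 2) {
    return(c(base = rep_tab$rms[1], inv_amp = 0))
  }
  w <- rep_tab$n
  x <- 1 / rep_tab$amp_mid
  y <- rep_tab$rms
  fit <- stats::lm(y ~ x, weights = w)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  if (b < 0) {
    a <- sum(w * y) / sum(w); b <- 0
  } else if (a < 0) {
    a <- 0; b <- sum(w * x * y) / sum(w * x^2)
  }
  c(base = a, inv_amp = b)
}

# repeatability sigma (raw-scale permil) at given amplitudes
repeatability_sigma <- function(fit, amplitude) {
  law <- fit$repeatability_law
  law[["base"]] + law[["inv_amp"]] / amplitude
}

#' Calibrate raw peaks to the VSMOW scale
#'
#' Inverts the fitted calibration to solve for the accepted-scale value
#' given the measured raw value and peak amplitude:
#' \deqn{\delta_{cal} = \frac{\delta_{raw} - \beta_0 - \beta_2 A}
#'   {\beta_1 + \beta_3 A}.}
#' Per-peak 1-sigma combines (in quadrature) the regression prediction
#' uncertainty from the coefficient covariance (delta method) with the
#' amplitude-binned repeatability mapped through the local slope, so
#' smaller peaks get larger errors.
#'
#' @param fit a [fit_calibration()] result (inverted orientation).
#' @param peaks peak table with columns `amplitude` and `d2h_raw`.
#' @param amp_warn_factor warn when a peak's amplitude is outside the
#'   standards' amplitude range widened by this factor.
#' @return The peak table as a tibble with columns `d2h_cal` and
#'   `d2h_cal_sigma` appended.
#' @export
apply_calibration <- function(fit, peaks, amp_warn_factor = 1.5) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$orientation != "inverted") {
    stop("apply_calibration() requires an inverted-orientation fit",
         call. = FALSE)
  }
  b <- fit$coefficients
  A <- peaks$amplitude
  raw <- peaks$d2h_raw
  denom <- b["scale"] + b["interaction"] * A
  if (abs(b["scale"]) < 1e-6 || any(abs(denom) < 1e-8)) {
    stop("calibration not invertible: scale coefficient is ~0",
         call. = FALSE)
  }
  lo <- fit$amp_range[1] / amp_warn_factor
  hi <- fit$amp_range[2] * amp_warn_factor
  if (any(A < lo | A > hi)) {
    warning(sum(A < lo | A > hi),
            " peak(s) outside the calibrated amplitude range")
  }
  x <- (raw - b["offset"] - b["size"] * A) / denom

  # delta-method variance from the coefficient covariance
  V <- fit$covariance
  p <- nrow(V)
  var_coef <- numeric(length(A))
  for (i in seq_along(A)) {
    g <- c(-1 / denom[i],                 # d x / d offset
           -x[i] / denom[i],              # d x / d scale
           if (fit$size_term) -A[i] / denom[i] else NULL,
           if (fit$interaction) -x[i] * A[i] / denom[i] else NULL)
    g <- g[seq_len(p)]
    var_coef[i] <- as.numeric(t(g) %*% V %*% g)
  }
  sig_rep <- repeatability_sigma(fit, A) / abs(denom)
  out <- tibble::as_tibble(peaks)
  out$d2h_cal <- as.numeric(x)
  out$d2h_cal_sigma <- sqrt(var_coef + sig_rep^2)
  out
}

#' Correct for isotope dilution during hydrogenation
#'
#' Hydrogenation of the alkyl iodides released by ether cleavage adds
#' `n_added` hydrogens of composition `delta_added` to each molecule's
#' `n_total`-H pool, diluting the biosynthetic signal.  The correction
#' inverts that pool mass balance:
#' \deqn{\delta_{corr} = \frac{n_{tot}\,\delta_{meas} -
#'   n_{add}\,\delta_{add}}{n_{tot} - n_{add}}}
#' with uncertainties propagated in quadrature using the same weights.
#' The applied correction magnitude (`corrected - measured`) is attached
#' as attribute `"correction"`.
#'
#' @param measured measured delta-2H (`iso_value` or numeric, permil).
#' @param delta_added delta-2H of the added hydrogen (`iso_value` or
#'   numeric, permil).
#' @param n_added number of hydrogens added per molecule (default 2: one
#'   at each cleaved ether terminus).
#' @param n_total total hydrogens per molecule (default 82, C40H82
#'   biphytane).
#' @return An `iso_value` of corrected values.
#' @examples
#' hydrogenation_correct(iso_value(-250, 3), iso_value(-750, 50))
#' @export
hydrogenation_correct <- function(measured, delta_added, n_added = 2,
                                  n_total = 82) {
  if (n_added < 0 || n_added >= n_total) {
    stop("need 0 <= n_added < n_total", call. = FALSE)
  }
  m <- as_iso_value(measured)
  a <- as_iso_value(delta_added)
  if (n_added == 0) {
    out <- m
    attr(out, "correction") <- rep(0, length(m))
    return(out)
  }
  wm <- n_total / (n_total - n_added)
  wa <- n_added / (n_total - n_added)
  corrected <- wm * m$value - wa * rep_len(a$value, length(m$value))
  sig <- sqrt((wm * m$sigma)^2 + (wa * rep_len(a$sigma, length(m$value)))^2)
  out <- iso_value(corrected, sig, m$n)
  attr(out, "correction") <- corrected - m$value
  out
}

#' Residual diagnostics for a standards calibration
#'
#' Per-standard residuals, leverages, and summary RMSE for run reports.
#'
#' @param fit a [fit_calibration()] result.
#' @param standards,defs the inputs used for the fit.
#' @return A list with `per_standard` (tibble: compound, amplitude,
#'   accepted, raw, fitted, residual, leverage, high_leverage flag) and
#'   `residual_rmse`.
#' @export
calibration_diagnostics <- function(fit, standards, defs) {
  stopifnot(inherits(fit, "calibration_fit"))
  d <- merge(as.data.frame(standards),
             as.data.frame(defs)[, c("compound", "accepted_d2h")],
             by = "compound")
  if (length(fit$dropped)) {
    d <- d[!(d$compound %in% fit$dropped), , drop = FALSE]
  }
  fitted_raw <- as.numeric(predict(fit$model, newdata = d))
  resp <- if (fit$orientation == "inverted") d$d2h_raw else d$accepted_d2h
  res <- resp - fitted_raw
  lev <- stats::hatvalues(fit$model)
  p <- length(coef(fit$model))
  tab <- tibble::tibble(
    compound = d$compound,
    amplitude = d$amplitude,
    accepted = d$accepted_d2h,
    raw = d$d2h_raw,
    fitted = fitted_raw,
    residual = res,
    leverage = as.numeric(lev),
    high_leverage = as.numeric(lev) > 2 * p / nrow(d)
  )
  list(per_standard = tab, residual_rmse = sqrt(mean(res^2)))
}
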