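#' Delta notation conversions
#'
#' Convert between isotope-ratio space and delta notation on the VSMOW
#' scale: \eqn{\delta = (R_{sample}/R_{standard} - 1)\cdot 1000}.
#'
#' @param ratio_sample,ratio_standard positive 2H/1H ratios.
#' @return `delta_from_ratio()` returns the delta value in permil;
#'   `ratio_from_delta()` returns the ratio of sample to standard,
#'   \eqn{R_{sample}/R_{standard} = 1 + \delta/1000}.
#' @examples
#' delta_from_ratio(0.5, 1)    # -500 permil
#' ratio_from_delta(-500)      # 0.5
#' @export
delta_from_ratio <- function(ratio_sample, ratio_standard) {
  if (any(ratio_sample <= 0) || any(ratio_standard <= 0)) {
    stop("isotope ratios must be positive", call. = FALSE)
  }
  (ratio_sample / ratio_standard - 1) * 1000
}

#' @rdname delta_from_ratio
#' @param delta delta value in permil; must exceed -1000.
#' @export
ratio_from_delta <- function(delta) {
  r <- 1 + delta / 1000
  if (any(r <= 0)) {
    stop("delta values at or below -1000 permil imply non-positive ratios",
         call. = FALSE)
  }
  r
}

#' Lipid/water hydrogen-isotope fractionation (epsilon notation)
#'
#' The fractionation between a lipid and its growth water is
#' \deqn{{}^2\varepsilon_{L/W} = \left(\frac{1000 + \delta^2H_{BP}}
#'   {1000 + \delta^2H_{W}} - 1\right)\cdot 1000}
#' i.e. \eqn{(\alpha_{L/W} - 1)\cdot 1000} where \eqn{\alpha_{L/W}} is the
#' ratio of the lipid to the water 2H/1H ratios.  Uncertainties on both
#' inputs are propagated to first order.
#'
#' @param delta_bp lipid delta-2H in permil (`iso_value` or numeric).
#' @param delta_water growth-water delta-2H in permil (`iso_value` or
#'   numeric).
#' @return An `iso_value` of epsilon values in permil.
#' @examples
#' epsilon_lw(iso_value(-280, 7), iso_value(-59.7, 0.5))  # about -234 permil
#' @export
epsilon_lw <- function(delta_bp, delta_water) {
  b <- as_iso_value(delta_bp)
  w <- as_iso_value(delta_water)
  if (any(!is.na(w$value) & w$value <= -1000) ||
      any(!is.na(b$value) & b$value <= -1000)) {
    stop("delta values must exceed -1000 permil", call. = FALSE)
  }
  eps <- ((1000 + b$value) / (1000 + w$value) - 1) * 1000
  # first-order propagation: d(eps)/d(b) and d(eps)/d(w)
  db <- 1000 / (1000 + w$value)
  dw <- -1000 * (1000 + b$value) / (1000 + w$value)^2
  sig <- sqrt((db * b$sigma)^2 + (dw * rep_len(w$sigma, length(b$value)))^2)
  iso_value(eps, sig, pmax(b$n, rep_len(w$n, length(b$value))))
}

#' Inverse-variance weighted mean with the replicate-scatter error rule
#'
#' Combines replicate isotope measurements as a weighted mean with
#' \eqn{1/\sigma^2} weights.  The reported uncertainty is the larger of
#' (a) the standard deviation of the replicates (weighted, reducing to the
#' ordinary sample SD for equal weights) and (b) the uncertainty of the
#' weighted mean propagated from the individual measurement errors,
#' \eqn{1/\sqrt{\sum 1/\sigma_i^2}}.  This conservative "max rule" guards
#' against over-tight errors when replicates scatter more than their
#' individual uncertainties suggest.
#'
#' @param x an `iso_value` (length >= 1); `NA` values are dropped.
#' @param sigma_floor substitute 1-sigma (permil) for measurements that
#'   report zero uncertainty, so weights stay finite.
#' @return A length-1 `iso_value`; `n` is the total number of contributing
#'   measurements.
#' @examples
#' weighted_mean(iso_value(c(-200, -100), sigma = c(1, 10)))  # -199.01
#' @export
weighted_mean <- function(x, sigma_floor = 0.5) {
  x <- as_iso_value(x)
  keep <- !is.na(x$value)
  x <- x[keep]
  if (length(x) == 0) stop("no non-missing values to combine", call. = FALSE)
  if (sigma_floor <= 0 && any(x$sigma == 0)) {
    stop("zero-uncertainty values require a positive `sigma_floor`",
         call. = FALSE)
  }
  s <- ifelse(x$sigma > 0, x$sigma, sigma_floor)
  w <- 1 / s^2
  m <- sum(w * x$value) / sum(w)
  sig_prop <- sqrt(1 / sum(w))
  k <- length(x)
  if (k > 1) {
    # weighted replicate SD; equals the sample SD for equal weights
    sig_rep <- sqrt(sum(w * (x$value - m)^2) / sum(w) * k / (k - 1))
  } else {
    sig_rep <- 0
  }
  iso_value(m, max(sig_rep, sig_prop), sum(x$n))
}

#' Abundance-weighted mean across biphytane moieties
#'
#' Averages per-moiety values (delta-2H or epsilon) weighted by the
#' relative abundance of each moiety.  Moieties at or below the abundance
#' threshold, or with missing values (below detection), are excluded; the
#' abundances of the included moieties are renormalised to sum to one.
#' The threshold is applied to the abundances as supplied, i.e. relative
#' to all detected moieties before any exclusion.
#'
#' @param abundances numeric vector of relative abundances (same length as
#'   `values`); need not sum exactly to one.
#' @param values an `iso_value` (or numeric) of per-moiety values; `NA`
#'   marks moieties below detection.
#' @param threshold abundance inclusion threshold; moieties with abundance
#'   strictly greater than this are included (default 0.05, the ">5%"
#'   rule).
#' @return A length-1 `iso_value` with attribute `"excluded"` giving the
#'   indices of excluded moieties.
#' @examples
#' abundance_weighted_mean(c(0.06, 0.13, 0.60, 0.21),
#'                         iso_value(c(-220, -214, -226, -227)))
#' @export
abundance_weighted_mean <- function(abundances, values, threshold = 0.05) {
  v <- as_iso_value(values)
  if (length(abundances) != length(v)) {
    stop("`abundances` and `values` must have the same length", call. = FALSE)
  }
  if (any(abundances < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  inc <- !is.na(abundances) & abundances > threshold & !is.na(v$value)
  if (!any(inc)) {
    stop("no moiety passes the abundance threshold with a measured value",
         call. = FALSE)
  }
  w <- abundances[inc] / sum(abundances[inc])
  m <- sum(w * v$value[inc])
  sig <- sqrt(sum((w * v$sigma[inc])^2))
  out <- iso_value(m, sig, sum(v$n[inc]))
  attr(out, "excluded") <- which(!inc)
  out
}

#' Ring indices for biphytane and iGDGT distributions
#'
#' The Ring Index is the abundance-weighted mean number of cyclopentane
#' rings in a lipid distribution:
#' \deqn{RI = \frac{\sum_i i \cdot x_i}{\sum_i x_i}}
#' where \eqn{x_i} is the relative abundance of the moiety with \eqn{i}
#' rings.  `ring_index_bp()` takes the four biphytane moieties BP-0..BP-3
#' (range 0-3); `ring_index_gdgt()` takes the nine tetraethers
#' iGDGT-0..iGDGT-8 (range 0-8).  Abundances are normalised internally by
#' their sum, so the result is invariant to rescaling.
#'
#' @param abundances non-negative abundance vector of length 4 (BP) or 9
#'   (iGDGT).
#' @return The ring index (dimensionless scalar).
#' @examples
#' ring_index_bp(c(0.18, 0.31, 0.36, 0.15))  # 1.48
#' @export
ring_index_bp <- function(abundances) {
  ring_index_impl(abundances, n_moieties = 4L)
}

#' @rdname ring_index_bp
#' @export
ring_index_gdgt <- function(abundances) {
  ring_index_impl(abundances, n_moieties = 9L)
}

ring_index_impl <- function(abundances, n_moieties) {
  if (length(abundances) != n_moieties) {
    stop("expected ", n_moieties, " abundances, got ", length(abundances),
         call. = FALSE)
  }
  if (any(is.na(abundances)) || any(abundances < 0)) {
    stop("abundances must be non-negative and non-missing", call. = FALSE)
  }
  tot <- sum(abundances)
  if (tot <= 0) stop("abundance vector sums to zero", call. = FALSE)
  rings <- seq_len(n_moieties) - 1L
  sum(rings * abundances) / tot
}

#' Per-moiety ring differences in lipid/water fractionation
#'
#' The ring difference quantifies how fractionation changes per additional
#' cyclopentane ring.  For every ordered pair of moieties with ring
#' numbers \eqn{X > Y} it is
#' \deqn{\Delta\varepsilon/ring = \frac{\varepsilon(X) - \varepsilon(Y)}{X - Y}.}
#' `ring_difference()` reports, for each moiety \eqn{X > 0}, the mean of
#' the pairwise values over all \eqn{Y < X} (BP-0 is 0 by definition);
#' `mean_ring_difference()` pools *all* pairwise combinations into a
#' single treatment-level mean, the quantity reported alongside
#' abundance-weighted means in result tables.  Pair uncertainties are
#' propagated in quadrature and averaged.
#'
#' @param eps an `iso_value` of per-moiety epsilon values, ordered by ring
#'   number; `NA` marks moieties without data.
#' @param rings integer ring numbers matching `eps` (default
#'   `0:(length(eps)-1)`).
#' @return `ring_difference()`: a tibble with columns `ring`,
#'   `d_eps_ring`, `sigma`, and `n_pairs` (rows only for moieties with
#'   data).  `mean_ring_difference()`: a length-1 `iso_value` (`NA` with a
#'   warning when fewer than two moieties have data).
#' @examples
#' eps <- iso_value(c(-214, -214, -210, -189), sigma = c(6, 6, 5, 20))
#' ring_difference(eps)       # BP-3 row: about 13.9 permil/ring
#' mean_ring_difference(eps)  # about 8 permil/ring
#' @export
ring_difference <- function(eps, rings = seq_along(iso_val(eps)) - 1L) {
  eps <- as_iso_value(eps)
  if (length(eps) != length(rings)) {
    stop("`eps` and `rings` must align", call. = FALSE)
  }
  has <- !is.na(eps$value)
  if (sum(has) < 2) {
    warning("fewer than two moieties with data; no ring differences")
    return(tibble::tibble(ring = integer(), d_eps_ring = numeric(),
                          sigma = numeric(), n_pairs = integer()))
  }
  rows <- lapply(which(has), function(i) {
    X <- rings[i]
    if (X == min(rings[has])) {
      return(tibble::tibble(ring = X, d_eps_ring = 0, sigma = 0,
                            n_pairs = 0L))
    }
    js <- which(has & rings < X)
    vals <- (eps$value[i] - eps$value[js]) / (X - rings[js])
    sigs <- sqrt(eps$sigma[i]^2 + eps$sigma[js]^2) / (X - rings[js])
    tibble::tibble(
      ring = X,
      d_eps_ring = mean(vals),
      sigma = sqrt(sum(sigs^2)) / length(vals),
      n_pairs = length(vals)
    )
  })
  do.call(rbind, rows)
}

#' @rdname ring_difference
#' @export
mean_ring_difference <- function(eps, rings = seq_along(iso_val(eps)) - 1L) {
  eps <- as_iso_value(eps)
  has <- !is.na(eps$value)
  if (sum(has) < 2) {
    warning("fewer than two moieties with data; mean ring difference is NA")
    return(iso_value(NA_real_, 0, 1L))
  }
  idx <- which(has)
  vals <- numeric(0)
  sigs <- numeric(0)
  for (a in idx) {
    for (b in idx) {
      if (rings[a] > rings[b]) {
        d <- rings[a] - rings[b]
        vals <- c(vals, (eps$value[a] - eps$value[b]) / d)
        sigs <- c(sigs, sqrt(eps$sigma[a]^2 + eps$sigma[b]^2) / d)
      }
    }
  }
  iso_value(mean(vals), sqrt(sum(sigs^2)) / length(vals), length(vals))
}
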