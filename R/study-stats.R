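#' Regression of fractionation on a condition level
#'
#' Ordinary least squares of a response (typically abundance-weighted
#' epsilon, permil) on a condition level (temperature, pH, doubling time,
#' ...), with a two-sided t-test on the slope.  By default regressions
#' are run on treatment means, which is what study figures display; pass
#' replicate-level vectors for replicate-level fits.
#'
#' @param x condition levels (numeric).
#' @param y response values in permil (numeric).
#' @param alpha significance threshold for the `significant` flag.
#' @return An object of class `regression_summary`: `slope`, `slope_se`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `significant`.
#' @export
condition_regression <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 (x, y) pairs", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("condition level is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      slope_se = sm$coefficients[2, 2],
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2, 4],
      n = length(x),
      significant = sm$coefficients[2, 4] < alpha
    ),
    class = "regression_summary"
  )
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf(
    "<regression> slope = %.3f +/- %.3f permil/unit, R2 = %.3f, P = %.3g (n = %d)%s\n",
    x$slope, x$slope_se, x$r_squared, x$p_value, x$n,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Pairwise Pearson correlations over the columns of a numeric table,
#' with two-sided p-values and star coding at p < 0.05 (`*`), < 0.001
#' (`**`), and < 0.0001 (`***`).  No multiple-testing correction is
#' applied by default (matching how such matrices are usually starred);
#' `adjust = "BH"` switches on Benjamini-Hochberg adjustment.
#'
#' @param variables data frame of numeric columns.
#' @param min_n minimum complete pairs required per correlation.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list of class `correlation_matrix` with matrices `r`, `p`,
#'   `n`, and character `stars`.  Pairs with fewer than `min_n` complete
#'   rows or a zero-variance column are `NA`.
#' @export
correlation_matrix <- function(variables, min_n = 3, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  variables <- as.data.frame(variables)
  k <- ncol(variables)
  nm <- names(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- variables[[i]]; xj <- variables[[j]]
      ok <- stats::complete.cases(xi, xj)
      n[i, j] <- sum(ok)
      if (sum(ok) < min_n) next
      if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else {
        ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  if (adjust == "BH") {
    off <- upper.tri(p)
    p[off] <- stats::p.adjust(p[off], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  stars <- matrix("", k, k, dimnames = list(nm, nm))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.001] <- "**"
  stars[!is.na(p) & p < 0.0001] <- "***"
  structure(list(r = r, p = p, n = n, stars = stars),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("<correlation_matrix>\n")
  m <- matrix(paste0(formatC(x$r, format = "f", digits = digits), x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  invisible(x)
}

#' Bartlett's test for homogeneity of variances
#'
#' Compares the variances of two or more groups of fractionation values
#' (e.g. epsilon values from different domains of life) with Bartlett's
#' K-squared statistic, chi-square distributed with k-1 degrees of
#' freedom under the null of equal variances.
#'
#' @param groups a list of numeric vectors, each of length >= 2.
#' @return A list with `statistic` (K-squared), `df`, and `p_value`.
#' @examples
#' bartlett_homogeneity(list(rnorm(20), rnorm(20, sd = 3)))
#' @export
bartlett_homogeneity <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(vapply(groups, stats::var, 1) == 0)) {
    stop("a group has zero variance; Bartlett's statistic is undefined",
         call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  bt <- stats::bartlett.test(values, g)
  list(statistic = unname(bt$statistic),
       df = unname(bt$parameter),
       p_value = bt$p.value)
}

#' Two-endmember water/substrate H mass balance
#'
#' In a heterotroph, lipid H derives from growth water and from the
#' organic substrate.  Modelling the lipid composition as a linear mix of
#' two endmember lipid values,
#' \deqn{\delta_L = f_w(\delta_W + \varepsilon_w) +
#'   (1 - f_w)(\delta_S + \varepsilon_s),}
#' the fraction of lipid H from water is
#' \deqn{f_w = \frac{\delta_L - (\delta_S + \varepsilon_s)}
#'   {(\delta_W + \varepsilon_w) - (\delta_S + \varepsilon_s)}.}
#' The pathway fractionations must be supplied explicitly; `lower_bound =
#' TRUE` sets the substrate-pathway fractionation to zero, which yields a
#' conservative lower bound on \eqn{f_w} when the true substrate-pathway
#' fractionation is negative.
#'
#' @param delta_lipid lipid delta-2H (`iso_value` or numeric, permil).
#' @param delta_water water delta-2H (`iso_value` or numeric, permil).
#' @param delta_substrate substrate delta-2H (`iso_value` or numeric,
#'   permil).
#' @param eps_water_path fractionation of the water-to-lipid pathway
#'   (permil).
#' @param eps_substrate_path fractionation of the substrate-to-lipid
#'   pathway (permil); ignored when `lower_bound = TRUE`.
#' @param lower_bound set the substrate-pathway fractionation to zero.
#' @return A list of class `mass_balance_result`: `f_water`,
#'   `f_water_sigma`, `assumptions`, `substrate_delta`.
#' @export
water_h_fraction <- function(delta_lipid, delta_water, delta_substrate,
                             eps_water_path, eps_substrate_path,
                             lower_bound = FALSE) {
  if (lower_bound) eps_substrate_path <- 0
  if (missing(eps_water_path) ||
      (!lower_bound && missing(eps_substrate_path))) {
    stop("pathway fractionations must be supplied explicitly",
         call. = FALSE)
  }
  L <- as_iso_value(delta_lipid)
  W <- as_iso_value(delta_water)
  S <- as_iso_value(delta_substrate)
  end_w <- W$value + eps_water_path
  end_s <- S$value + eps_substrate_path
  denom <- end_w - end_s
  if (abs(denom) < 1e-9) {
    stop("endmembers coincide; the mixing fraction is unidentifiable",
         call. = FALSE)
  }
  f <- (L$value - end_s) / denom
  sig <- sqrt((L$sigma / denom)^2 +
                (f * W$sigma / denom)^2 +
                ((1 - f) * S$sigma / denom)^2)
  if (f < 0 || f > 1) {
    warning("mixing fraction outside [0, 1]; check endmember assumptions")
  }
  structure(
    list(
      f_water = f,
      f_water_sigma = sig,
      assumptions = list(eps_water_path = eps_water_path,
                         eps_substrate_path = eps_substrate_path,
                         lower_bound = lower_bound),
      substrate_delta = S$value
    ),
    class = "mass_balance_result"
  )
}

#' @export
print.mass_balance_result <- function(x, ...) {
  cat(sprintf(
    "<mass_balance> f_water = %.3f +/- %.3f (eps_w = %.0f, eps_s = %.0f%s)\n",
    x$f_water, x$f_water_sigma, x$assumptions$eps_water_path,
    x$assumptions$eps_substrate_path,
    if (x$assumptions$lower_bound) ", lower bound" else ""))
  invisible(x)
}

#' Summarise an experiment's treatment-level results
#'
#' Collapses a table of per-treatment results into the study-level
#' summary: range (max - min) of abundance-weighted epsilon, pooled mean
#' and SD, ring-index range, and delta-2H range.  Ranges are invariant to
#' treatment ordering.
#'
#' @param results a tibble with (at least) columns `eps_wm` (permil),
#'   and optionally `d2h_wm`, `ri`, `experiment`, `treatment` — the
#'   format produced by [reduce_treatments()].
#' @return A list of class `experiment_summary` with `n_treatments`,
#'   `eps_range`, `eps_mean`, `eps_sd`, `ri_range`, `d2h_range`.
#' @export
summarize_experiment <- function(results) {
  if (nrow(results) < 1) stop("need >= 1 treatment", call. = FALSE)
  eps <- results$eps_wm
  out <- list(
    n_treatments = nrow(results),
    eps_range = diff(range(eps, na.rm = TRUE)),
    eps_mean = mean(eps, na.rm = TRUE),
    eps_sd = if (sum(!is.na(eps)) > 1) stats::sd(eps, na.rm = TRUE) else 0,
    ri_range = if (!is.null(results$ri)) {
      diff(range(results$ri, na.rm = TRUE))
    } else NA_real_,
    d2h_range = if (!is.null(results$d2h_wm)) {
      diff(range(results$d2h_wm, na.rm = TRUE))
    } else NA_real_
  )
  structure(out, class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf(
    "<experiment_summary> %d treatments; eps range %.1f permil, mean %.1f +/- %.1f permil\n",
    x$n_treatments, x$eps_range, x$eps_mean, x$eps_sd))
  invisible(x)
}
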