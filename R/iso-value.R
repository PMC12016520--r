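#' Isotope values with 1-sigma uncertainty
#'
#' A lightweight vectorised container for delta or epsilon values in permil
#' (\eqn{\textperthousand}) together with their 1-sigma analytical
#' uncertainty and the number of contributing measurements.  All reduction
#' operations in the package (`epsilon_lw()`, `weighted_mean()`,
#' `hydrogenation_correct()`, ...) consume and return `iso_value` objects so
#' that uncertainties are carried through every step.
#'
#' @param value numeric vector of delta/epsilon values in permil.
#' @param sigma numeric vector of 1-sigma uncertainties in permil
#'   (recycled); must be non-negative.
#' @param n integer vector of contributing measurement counts (recycled).
#' @return An object of class `iso_value`.
#' @examples
#' x <- iso_value(c(-280, -276), sigma = c(7, 4), n = 3)
#' x
#' x[1]
#' @export
iso_value <- function(value, sigma = 0, n = 1L) {
  if (!is.numeric(value) || !is.numeric(sigma)) {
    stop("`value` and `sigma` must be numeric", call. = FALSE)
  }
  if (any(sigma < 0, na.rm = TRUE)) {
    stop("`sigma` must be non-negative", call. = FALSE)
  }
  if (any(n < 1, na.rm = TRUE)) {
    stop("`n` must be >= 1", call. = FALSE)
  }
  k <- length(value)
  structure(
    list(
      value = as.numeric(value),
      sigma = rep_len(as.numeric(sigma), k),
      n = rep_len(as.integer(n), k)
    ),
    class = "iso_value"
  )
}

#' Coerce to an isotope value
#'
#' Numeric vectors become `iso_value`s with zero uncertainty; existing
#' `iso_value`s pass through unchanged.
#'
#' @param x numeric vector or `iso_value`.
#' @return An `iso_value`.
#' @export
as_iso_value <- function(x) {
  if (inherits(x, "iso_value")) return(x)
  iso_value(x)
}

#' @export
length.iso_value <- function(x) length(x$value)

#' @export
`[.iso_value` <- function(x, i) {
  iso_value(x$value[i], x$sigma[i], x$n[i])
}

#' @export
c.iso_value <- function(...) {
  parts <- lapply(list(...), as_iso_value)
  iso_value(
    unlist(lapply(parts, `[[`, "value")),
    unlist(lapply(parts, `[[`, "sigma")),
    unlist(lapply(parts, `[[`, "n"))
  )
}

#' @export
format.iso_value <- function(x, digits = 1, ...) {
  sprintf(
    "%s %s %s‰ (n=%d)",
    formatC(x$value, format = "f", digits = digits),
    "±",
    formatC(x$sigma, format = "f", digits = digits),
    x$n
  )
}

#' @export
print.iso_value <- function(x, ...) {
  cat("<iso_value[", length(x), "]>\n", sep = "")
  if (length(x)) print(format(x, ...), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.iso_value <- function(x, ...) {
  data.frame(value = x$value, sigma = x$sigma, n = x$n)
}

#' @export
mean.iso_value <- function(x, ...) mean(x$value, ...)

# internal: quick accessors tolerant of plain numerics
iso_val <- function(x) if (inherits(x, "iso_value")) x$value else as.numeric(x)
iso_sig <- function(x) if (inherits(x, "iso_value")) x$sigma else rep(0, length(x))
iso_n <- function(x) if (inherits(x, "iso_value")) x$n else rep(1L, length(x))
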