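# Readers for the delimited text interchange formats.  All readers are
# schema-checked (case-insensitive headers, '.' decimal point) and report
# row-level problems with line numbers.

match_columns <- function(df, required, path) {
  hits <- match(tolower(required), tolower(names(df)))
  if (anyNA(hits)) {
    stop("file ", path, " is missing required column(s): ",
         paste(required[is.na(hits)], collapse = ", "), call. = FALSE)
  }
  hits
}

check_numeric <- function(df, cols, path) {
  problems <- character(0)
  for (cl in cols) {
    x <- df[[cl]]
    if (is.numeric(x)) next
    xl <- trimws(as.character(x))
    bad <- which(!is.na(xl) & xl != "" & toupper(xl) != "NA" &
                   is.na(suppressWarnings(as.numeric(xl))))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "column '%s': non-numeric value at data line(s) %s",
        cl, paste(utils::head(bad + 1L, 5), collapse = ", ")))
    }
    df[[cl]] <- suppressWarnings(as.numeric(xl))
  }
  if (length(problems)) {
    stop("invalid rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Read a peak-measurement table
#'
#' Reads a tab-delimited peak table with the documented header `run_id`,
#' `injection`, `compound`, `rt_s`, `amplitude_mV`, `area_Vs`,
#' `d2H_raw_permil` (case-insensitive; extra columns such as
#' `culture_id` and `treatment` are preserved) into the canonical
#' in-memory layout used by [fit_calibration()] and
#' [apply_calibration()].
#'
#' @param path file path.
#' @return A tibble with columns `run_id`, `injection`, `compound`,
#'   `rt`, `amplitude`, `area`, `d2h_raw` (plus any extras).
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("run_id", "injection", "compound", "rt_s", "amplitude_mV",
           "area_Vs", "d2H_raw_permil")
  hits <- match_columns(df, req, path)
  canon <- c("run_id", "injection", "compound", "rt", "amplitude", "area",
             "d2h_raw")
  extras <- df[, -hits, drop = FALSE]
  out <- stats::setNames(df[, hits, drop = FALSE], canon)
  out <- check_numeric(out, c("injection", "rt", "amplitude", "area",
                              "d2h_raw"), path)
  if (any(!is.na(out$amplitude) & out$amplitude <= 0)) {
    stop("non-positive peak amplitude(s) in ", path, call. = FALSE)
  }
  tibble::as_tibble(cbind(out, extras))
}

#' Read per-culture metadata
#'
#' Expects columns `culture_id`, `experiment`, `level`,
#' `d2H_water_permil` (case-insensitive); optional `treatment` and
#' `d2H_water_sigma_permil` columns are used when present (`treatment`
#' defaults to the level, water sigma to 0.5 permil).
#'
#' @param path file path.
#' @return A tibble with columns `culture_id`, `experiment`,
#'   `treatment`, `level`, `d2h_water`, `d2h_water_sigma`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  hits <- match_columns(df, c("culture_id", "experiment", "level",
                              "d2H_water_permil"), path)
  out <- stats::setNames(df[, hits, drop = FALSE],
                         c("culture_id", "experiment", "level", "d2h_water"))
  out <- check_numeric(out, "d2h_water", path)
  tr <- match("treatment", tolower(names(df)))
  out$treatment <- if (!is.na(tr)) as.character(df[[tr]]) else
    as.character(out$level)
  sg <- match("d2h_water_sigma_permil", tolower(names(df)))
  out$d2h_water_sigma <- if (!is.na(sg)) {
    suppressWarnings(as.numeric(df[[sg]]))
  } else 0.5
  tibble::as_tibble(out[, c("culture_id", "experiment", "treatment",
                            "level", "d2h_water", "d2h_water_sigma")])
}

#' Read a growth-curve table
#'
#' Expects columns `culture_id`, `time_h`, `od600` (case-insensitive).
#'
#' @param path file path.
#' @return A tibble with those three columns.
#' @export
read_growth <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  hits <- match_columns(df, c("culture_id", "time_h", "od600"), path)
  out <- stats::setNames(df[, hits, drop = FALSE],
                         c("culture_id", "time_h", "od600"))
  out <- check_numeric(out, c("time_h", "od600"), path)
  tibble::as_tibble(out)
}

#' Read standards definitions
#'
#' Expects columns `compound` and `accepted_d2H_permil`
#' (case-insensitive); an optional `accepted_sigma_permil` column
#' defaults to 0.5 permil.
#'
#' @param path file path.
#' @return A tibble with columns `compound`, `accepted_d2h`,
#'   `accepted_sigma`.
#' @export
read_standard_defs <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  hits <- match_columns(df, c("compound", "accepted_d2H_permil"), path)
  out <- stats::setNames(df[, hits, drop = FALSE],
                         c("compound", "accepted_d2h"))
  out <- check_numeric(out, "accepted_d2h", path)
  sg <- match("accepted_sigma_permil", tolower(names(df)))
  out$accepted_sigma <- if (!is.na(sg)) {
    suppressWarnings(as.numeric(df[[sg]]))
  } else 0.5
  tibble::as_tibble(out)
}
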