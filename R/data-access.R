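#' Published culture-study tables for Sulfolobus acidocaldarius
#'
#' Transcriptions of the treatment-level summary tables from a published
#' culture study of the thermoacidophilic archaeon *Sulfolobus
#' acidocaldarius* grown under varying temperature, pH, aeration
#' (shaking) rate, O2 mixing ratio, and electron-donor (sucrose) flux.
#' These tables serve as worked-example inputs for the reduction
#' functions: the per-moiety values they print can be pushed through
#' [epsilon_lw()], [ring_index_bp()], [abundance_weighted_mean()],
#' [ring_difference()], and [summarize_experiment()].
#'
#' * `saci_culture_conditions()`: one row per treatment — experiment,
#'   treatment label, culture regime (batch / fed-batch / chemostat),
#'   biological replicates, conditions (temperature, pH, RPM, O2),
#'   growth-water delta-2H (permil), growth rate and doubling time
#'   (mean, SD), and maximum OD600.
#' * `saci_bp_abundances()`: relative abundances (fractions) of the four
#'   biphytane moieties BP-0..BP-3 per treatment, with SDs and the
#'   printed ring index.
#' * `saci_bp_isotopes()`: long table of per-moiety delta-2H and
#'   lipid/water epsilon (permil, integer-rounded as printed) with SDs
#'   and per-moiety ring differences; `moiety == "weighted"` rows carry
#'   the printed abundance-weighted means.  `NA` marks moieties below
#'   detection ("n.d.").
#'
#' @return A tibble (see Details).
#' @name saci_tables
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "bpfrac", mustWork = TRUE)
  tibble::as_tibble(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
}

#' @rdname saci_tables
#' @export
saci_culture_conditions <- function() {
  read_extdata("saci_culture_conditions.tsv")
}

#' @rdname saci_tables
#' @export
saci_bp_abundances <- function() {
  read_extdata("saci_bp_abundances.tsv")
}

#' @rdname saci_tables
#' @export
saci_bp_isotopes <- function() {
  read_extdata("saci_bp_isotopes.tsv")
}

#' Treatment-level reduction of per-moiety fractionation results
#'
#' Combines per-moiety isotope values and moiety abundances into the
#' standard treatment-level result row: biphytane ring index,
#' abundance-weighted mean delta-2H and epsilon (">5% abundance" rule),
#' per-moiety ring differences, and the pooled mean ring difference over
#' all pairwise moiety combinations.
#'
#' @param moieties long tibble with columns `experiment`, `treatment`,
#'   `moiety` (`"BP-0"`..`"BP-3"`), `d2h`, `d2h_sd`, `eps`, `eps_sd`
#'   (permil; `NA` for below-detection moieties).  Rows with other
#'   `moiety` labels (e.g. `"weighted"`) are ignored.
#' @param abundances tibble with columns `experiment`, `treatment`,
#'   `bp0`..`bp3`.
#' @param threshold abundance inclusion threshold for the weighted means.
#' @return A tibble with one row per treatment: `experiment`,
#'   `treatment`, `ri`, `d2h_wm`, `d2h_wm_sigma`, `eps_wm`,
#'   `eps_wm_sigma`, `mean_ring_diff`, `mean_ring_diff_sigma`, and
#'   per-moiety ring-difference columns `rd_bp1`..`rd_bp3`.
#' @export
reduce_treatments <- function(moieties, abundances, threshold = 0.05) {
  keys <- unique(abundances[, c("experiment", "treatment")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    ex <- keys$experiment[i]
    tr <- keys$treatment[i]
    ab_row <- abundances[abundances$experiment == ex &
                           abundances$treatment == tr, ]
    ab <- as.numeric(ab_row[1, c("bp0", "bp1", "bp2", "bp3")])
    mo <- moieties[moieties$experiment == ex & moieties$treatment == tr &
                     moieties$moiety %in% sprintf("BP-%d", 0:3), ]
    idx <- match(sprintf("BP-%d", 0:3), mo$moiety)
    eps_v <- mo$eps[idx]
    eps_s <- mo$eps_sd[idx]
    d2h_v <- mo$d2h[idx]
    d2h_s <- mo$d2h_sd[idx]
    eps <- iso_value(eps_v, ifelse(is.na(eps_s), 0, eps_s))
    d2h <- iso_value(d2h_v, ifelse(is.na(d2h_s), 0, d2h_s))
    eps_wm_iso <- abundance_weighted_mean(ab, eps, threshold)
    d2h_wm_iso <- abundance_weighted_mean(ab, d2h, threshold)
    mrd <- mean_ring_difference(eps)
    rd <- ring_difference(eps)
    rd_by <- stats::setNames(rep(NA_real_, 3), sprintf("rd_bp%d", 1:3))
    for (r in 1:3) {
      hit <- rd$ring == r
      if (any(hit)) rd_by[sprintf("rd_bp%d", r)] <- rd$d_eps_ring[hit]
    }
    tibble::tibble(
      experiment = ex, treatment = tr,
      ri = ring_index_bp(ab),
      d2h_wm = d2h_wm_iso$value, d2h_wm_sigma = d2h_wm_iso$sigma,
      eps_wm = eps_wm_iso$value, eps_wm_sigma = eps_wm_iso$sigma,
      mean_ring_diff = mrd$value, mean_ring_diff_sigma = mrd$sigma,
      rd_bp1 = rd_by[["rd_bp1"]], rd_bp2 = rd_by[["rd_bp2"]],
      rd_bp3 = rd_by[["rd_bp3"]]
    )
  })
  do.call(rbind, rows)
}
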