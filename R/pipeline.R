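#' Pipeline configuration
#'
#' Collects file paths and every reduction knob for [run_pipeline()].
#' `read_pipeline_config()` loads the same structure from a YAML file
#' (keys matching the argument names).
#'
#' @param standards,samples,metadata,growth,standard_defs input file
#'   paths (`growth` may be `NULL`).
#' @param out_dir output directory.
#' @param size_term,interaction,robust calibration options (see
#'   [fit_calibration()]).
#' @param n_added,n_total,delta_added,delta_added_sigma hydrogenation
#'   correction parameters (see [hydrogenation_correct()]).
#' @param threshold abundance inclusion threshold for weighted means.
#' @param growth_window exponential-window OD fractions for
#'   [fit_growth_rate()].
#' @param sigma_floor substitute 1-sigma for zero-uncertainty values in
#'   [weighted_mean()].
#' @param seed integer seed recorded in the log (the reduction itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(standards, samples, metadata, growth = NULL,
                            standard_defs = NULL, out_dir = NULL,
                            size_term = TRUE, interaction = FALSE,
                            robust = FALSE, n_added = 2, n_total = 82,
                            delta_added = -650, delta_added_sigma = 50,
                            threshold = 0.05,
                            growth_window = c(0.05, 0.60),
                            sigma_floor = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$threshold < 0 || cfg$threshold >= 0.5) {
    stop("threshold must lie in [0, 0.5)", call. = FALSE)
  }
  if (cfg$n_added < 0 || cfg$n_added >= cfg$n_total) {
    stop("need 0 <= n_added < n_total", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

moiety_ring <- function(compound) {
  as.integer(sub("^BP-", "", compound))
}

#' Reduce a study from peak tables to treatment results
#'
#' The in-memory core of the pipeline, also usable directly on the
#' tibbles of a [generate_study()] dataset.  Stages: per-run standards
#' calibration (offset, scale compression, peak-size terms) ->
#' calibration of sample peaks -> hydrogenation isotope-dilution
#' correction -> per-culture weighted means across injections ->
#' per-culture epsilon vs growth water -> per-treatment weighted means
#' across replicate cultures -> abundance-weighted means, ring index,
#' and ring differences per treatment -> per-experiment summaries.
#' Moiety abundances are estimated from peak areas (mean share across
#' injections).
#'
#' @param standards standards peak tibble (canonical columns, see
#'   [read_peak_table()]).
#' @param samples sample peak tibble with `culture_id` and `treatment`
#'   columns.
#' @param metadata per-culture metadata tibble (see [read_metadata()]).
#' @param defs standards definitions tibble (default: the synthetic
#'   ladder from [a7_standard_ladder()]).
#' @param growth optional growth tibble; when supplied, growth rates and
#'   doubling times are fitted per culture.
#' @param config a [pipeline_config()] (paths ignored here) or a plain
#'   list of the option fields.
#' @return A list of class `results_bundle`: `calibrated` (per-peak
#'   table with calibrated and corrected values), `cultures` (per
#'   culture x moiety), `treatment_moieties`, `abundances`,
#'   `treatments` (one row per treatment, see [reduce_treatments()]),
#'   `rates`, `summaries` (per experiment), `calibrations` (per-run
#'   fits), and `log` (character).
#' @export
reduce_study <- function(standards, samples, metadata,
                         defs = a7_standard_ladder(), growth = NULL,
                         config = pipeline_config("", "", "")) {
  log <- c(sprintf("bpfrac %s", as.character(utils::packageVersion("bpfrac"))),
           sprintf("seed: %s", config$seed),
           sprintf("abundance threshold: %g", config$threshold),
           sprintf("hydrogenation: n_added=%d n_total=%d delta_added=%g+/-%g",
                   config$n_added, config$n_total, config$delta_added,
                   config$delta_added_sigma))

  # --- stage 1-2: per-run calibration, applied to that run's samples
  runs <- unique(samples$run_id)
  fits <- list()
  cal_parts <- list()
  for (r in runs) {
    std_r <- standards[standards$run_id == r, , drop = FALSE]
    if (nrow(std_r) == 0) std_r <- standards  # pooled fallback
    fit <- tryCatch(
      fit_calibration(std_r, defs, size_term = config$size_term,
                      interaction = config$interaction,
                      robust = config$robust),
      error = function(e) stop("calibration failed for run ", r, ": ",
                               conditionMessage(e), call. = FALSE))
    fits[[r]] <- fit
    cal_parts[[r]] <- apply_calibration(fit,
                                        samples[samples$run_id == r, ,
                                                drop = FALSE])
    log <- c(log, sprintf(
      "run %s: offset=%.3f scale=%.4f size=%.2e rmse=%.3f (n=%d)",
      r, fit$coefficients["offset"], fit$coefficients["scale"],
      fit$coefficients["size"], fit$residual_rmse, fit$n_standards))
  }
  calibrated <- do.call(rbind, cal_parts)

  # --- stage 3: hydrogenation correction per peak
  corr <- hydrogenation_correct(
    iso_value(calibrated$d2h_cal, calibrated$d2h_cal_sigma),
    iso_value(config$delta_added, config$delta_added_sigma),
    n_added = config$n_added, n_total = config$n_total)
  calibrated$d2h_corr <- corr$value
  calibrated$d2h_corr_sigma <- corr$sigma
  calibrated$hydrogenation_correction <- attr(corr, "correction")
  log <- c(log, sprintf(
    "hydrogenation correction: %.1f to %.1f permil",
    min(calibrated$hydrogenation_correction),
    max(calibrated$hydrogenation_correction)))

  # --- stage 4: per-culture x moiety weighted means across injections
  meta <- as.data.frame(metadata)
  cultures <- list()
  ab_rows <- list()
  for (cid in unique(calibrated$culture_id)) {
    pk <- calibrated[calibrated$culture_id == cid, , drop = FALSE]
    m <- meta[meta$culture_id == cid, , drop = FALSE]
    if (nrow(m) == 0) {
      stop("sample culture '", cid, "' missing from metadata",
           call. = FALSE)
    }
    water <- iso_value(m$d2h_water[1], m$d2h_water_sigma[1])
    # abundances: mean area share across injections
    shares <- matrix(0, nrow = 0, ncol = 4)
    for (inj in unique(pk$injection)) {
      pi <- pk[pk$injection == inj, , drop = FALSE]
      sh <- numeric(4)
      sh[moiety_ring(pi$compound) + 1L] <- pi$area / sum(pi$area)
      shares <- rbind(shares, sh)
    }
    ab <- colMeans(shares)
    ab_rows[[cid]] <- tibble::tibble(
      experiment = m$experiment[1], treatment = m$treatment[1],
      culture_id = cid,
      bp0 = ab[1], bp1 = ab[2], bp2 = ab[3], bp3 = ab[4])
    for (r in 0:3) {
      pm <- pk[moiety_ring(pk$compound) == r, , drop = FALSE]
      if (nrow(pm) == 0) next
      d2h_iso <- weighted_mean(iso_value(pm$d2h_corr, pm$d2h_corr_sigma),
                               sigma_floor = config$sigma_floor)
      eps_iso <- epsilon_lw(d2h_iso, water)
      cultures[[length(cultures) + 1L]] <- tibble::tibble(
        experiment = m$experiment[1], treatment = m$treatment[1],
        culture_id = cid, moiety = sprintf("BP-%d", r),
        d2h = d2h_iso$value, d2h_sd = d2h_iso$sigma, n = d2h_iso$n,
        eps = eps_iso$value, eps_sd = eps_iso$sigma)
    }
  }
  cultures <- do.call(rbind, cultures)
  culture_ab <- do.call(rbind, ab_rows)

  # --- stage 5: per-treatment x moiety weighted means across cultures
  tm <- list()
  keys <- unique(cultures[, c("experiment", "treatment")])
  for (i in seq_len(nrow(keys))) {
    ex <- keys$experiment[i]; tr <- keys$treatment[i]
    for (r in 0:3) {
      cc <- cultures[cultures$experiment == ex & cultures$treatment == tr &
                       cultures$moiety == sprintf("BP-%d", r), ,
                     drop = FALSE]
      if (nrow(cc) == 0) next
      d2h_iso <- weighted_mean(iso_value(cc$d2h, cc$d2h_sd),
                               sigma_floor = config$sigma_floor)
      eps_iso <- weighted_mean(iso_value(cc$eps, cc$eps_sd),
                               sigma_floor = config$sigma_floor)
      tm[[length(tm) + 1L]] <- tibble::tibble(
        experiment = ex, treatment = tr, moiety = sprintf("BP-%d", r),
        d2h = d2h_iso$value, d2h_sd = d2h_iso$sigma,
        eps = eps_iso$value, eps_sd = eps_iso$sigma,
        n_cultures = nrow(cc))
    }
  }
  treatment_moieties <- do.call(rbind, tm)

  tr_ab <- list()
  for (i in seq_len(nrow(keys))) {
    ex <- keys$experiment[i]; tr <- keys$treatment[i]
    ca <- culture_ab[culture_ab$experiment == ex &
                       culture_ab$treatment == tr, , drop = FALSE]
    tr_ab[[length(tr_ab) + 1L]] <- tibble::tibble(
      experiment = ex, treatment = tr,
      bp0 = mean(ca$bp0), bp1 = mean(ca$bp1),
      bp2 = mean(ca$bp2), bp3 = mean(ca$bp3))
  }
  tr_ab <- do.call(rbind, tr_ab)

  # --- stage 6: treatment-level results and summaries
  treatments <- reduce_treatments(treatment_moieties, tr_ab,
                                  threshold = config$threshold)

  summaries <- lapply(split(treatments, treatments$experiment),
                      summarize_experiment)

  # --- growth rates (chemostat cultures keep their set doubling time)
  rates <- NULL
  if (!is.null(growth)) {
    rates <- do.call(rbind, lapply(unique(growth$culture_id), function(cid) {
      g <- growth[growth$culture_id == cid, , drop = FALSE]
      fit <- fit_growth_rate(g, window = config$growth_window)
      tibble::tibble(culture_id = cid, mu = fit$mu, mu_se = fit$mu_se,
                     doubling_time = fit$doubling_time,
                     r_squared = fit$r_squared,
                     window_used = fit$window_used)
    }))
    log <- c(log, sprintf("growth window: %g-%g of max OD",
                          config$growth_window[1], config$growth_window[2]))
  }

  structure(
    list(calibrated = calibrated, cultures = cultures,
         culture_abundances = culture_ab,
         treatment_moieties = treatment_moieties, abundances = tr_ab,
         treatments = treatments, rates = rates, summaries = summaries,
         calibrations = fits, log = log),
    class = "results_bundle"
  )
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>", nrow(x$treatments), "treatments,",
      nrow(x$cultures), "culture-moiety rows,",
      nrow(x$calibrated), "calibrated peaks\n")
  invisible(x)
}

#' Run the full file-to-report pipeline
#'
#' Reads the peak, metadata, and growth tables named in the config,
#' executes [reduce_study()] (calibrate -> hydrogenation-correct ->
#' epsilon -> weighted means -> ring index -> ring differences ->
#' summaries), and writes the machine-readable results bundle: TSV
#' tables, a JSON run summary, a plain-text report (permil values
#' rounded to integers, indices and abundances to two decimals), and a
#' log recording package version, config hash, seed, and every decision
#' knob.  The reduction involves no random numbers, so identical inputs
#' give identical outputs.
#'
#' @param config a [pipeline_config()] with file paths set.
#' @return The `results_bundle`, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  standards <- read_peak_table(config$standards)
  samples <- read_peak_table(config$samples)
  metadata <- read_metadata(config$metadata)
  growth <- if (!is.null(config$growth)) read_growth(config$growth)
  defs <- if (!is.null(config$standard_defs)) {
    read_standard_defs(config$standard_defs)
  } else {
    a7_standard_ladder()
  }
  bundle <- reduce_study(standards, samples, metadata, defs = defs,
                         growth = growth, config = config)

  out <- config$out_dir
  if (is.null(out)) return(invisible(bundle))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(out, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(bundle$calibrated, "calibrated_peaks.tsv")
  wt(bundle$cultures, "culture_moieties.tsv")
  wt(bundle$treatment_moieties, "treatment_moieties.tsv")
  wt(bundle$abundances, "treatment_abundances.tsv")
  wt(bundle$treatments, "treatment_results.tsv")
  if (!is.null(bundle$rates)) wt(bundle$rates, "growth_rates.tsv")

  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("bpfrac")),
      seed = config$seed,
      n_treatments = nrow(bundle$treatments),
      summaries = lapply(bundle$summaries, unclass)
    ),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)

  writeLines(render_report(bundle), file.path(out, "report.txt"))

  cfg_file <- file.path(out, "config_used.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  log <- c(bundle$log,
           sprintf("config hash: %s", unname(tools::md5sum(cfg_file))))
  writeLines(log, file.path(out, "run.log"))
  message(paste(log, collapse = "\n"))
  invisible(bundle)
}

# plain-text report mirroring the layout of treatment result tables:
# permil values as integers, indices/abundances to 2 decimals
render_report <- function(bundle) {
  tr <- bundle$treatments
  ab <- bundle$abundances
  lines <- c("Treatment results (delta/epsilon in permil, rounded)",
             paste("experiment", "treatment", "BP0", "BP1", "BP2", "BP3",
                   "RI", "d2H_wm", "eps_wm", "dEps_ring", sep = "\t"))
  for (i in seq_len(nrow(tr))) {
    a <- ab[ab$experiment == tr$experiment[i] &
              ab$treatment == tr$treatment[i], ]
    lines <- c(lines, paste(
      tr$experiment[i], tr$treatment[i],
      sprintf("%.2f", a$bp0), sprintf("%.2f", a$bp1),
      sprintf("%.2f", a$bp2), sprintf("%.2f", a$bp3),
      sprintf("%.2f", tr$ri[i]),
      sprintf("%.0f", tr$d2h_wm[i]), sprintf("%.0f", tr$eps_wm[i]),
      sprintf("%.0f", tr$mean_ring_diff[i]), sep = "\t"))
  }
  lines
}
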