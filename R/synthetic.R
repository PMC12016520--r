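#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic instrument and culture-design
#' emulator.  Defaults reflect the archaeal biphytane culture study the
#' package models: lipid/water fractionation centred at -204 permil with
#' 12 permil spread across treatments, a +7.4 permil enrichment per
#' cyclopentane ring, growth waters between -61 and -46 permil, and
#' biphytane abundances averaging roughly 13/30/49/7% for BP-0..BP-3.
#'
#' The instrument model applied to every true value is
#' \deqn{\delta_{raw} = offset + scale\cdot\delta + c_A\cdot A +
#'   c_{int}\cdot\delta\cdot A + N(0, \sigma(A))}
#' with amplitude-dependent noise \eqn{\sigma(A) = a + b/A} (shot-noise
#' shape: small peaks are noisier).  Hydrogenation of alkyl iodides to
#' biphytanes adds `n_added` hydrogens of composition `delta_added_h` to
#' an `n_total`-H pool (C40H82 biphytane with one H added at each cleaved
#' ether terminus by default), diluting the biosynthetic signal.
#'
#' @param n_treatments,replicates_per_treatment design dimensions.
#' @param true_epsilon_mean,true_epsilon_sd mean and SD (permil) of the
#'   treatment-level true lipid/water fractionation for BP-0.
#' @param ring_enrichment_per_ring per-ring increase of true epsilon
#'   (permil/ring).
#' @param water_delta_range range (permil) from which per-culture growth
#'   water delta-2H is drawn.
#' @param abundance_dirichlet positive Dirichlet parameters (length 4)
#'   for per-culture BP-0..BP-3 relative abundances.
#' @param noise_base_sigma,noise_amplitude_coeff noise law parameters `a`
#'   (permil) and `b` (permil.mV) in \eqn{\sigma(A) = a + b/A}; both may
#'   be zero for a noiseless instrument.
#' @param cal_offset,cal_scale,cal_size_coeff,cal_interaction instrument
#'   offset (permil), scale compression (dimensionless, in (0.5, 1.5)),
#'   linear peak-size effect (permil/mV), and optional
#'   delta-by-amplitude interaction.
#' @param delta_added_h delta-2H (permil) of hydrogen added during
#'   hydrogenation (a free parameter of the emulator).
#' @param n_added,n_total hydrogenation stoichiometry: H added vs total H
#'   per molecule.
#' @param amplitude_range peak-amplitude range (mV) for standards.
#' @param sample_total_amplitude summed amplitude (mV) of a sample
#'   injection, split across moieties in proportion to abundance.
#' @param detection_limit amplitude (mV) below which a sample peak is not
#'   reported (emulates below-detection moieties).
#' @param n_injections analytical replicates per culture.
#' @param mu_range range (per hour) of per-culture true growth rates.
#' @param od0,od_max,growth_noise_sd,growth_times growth-curve settings.
#' @param seed optional integer seed stored with the config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_treatments = 5,
                             replicates_per_treatment = 3,
                             true_epsilon_mean = -204,
                             true_epsilon_sd = 12,
                             ring_enrichment_per_ring = 7.4,
                             water_delta_range = c(-61, -46),
                             abundance_dirichlet = c(2.6, 6.0, 9.8, 1.4),
                             noise_base_sigma = 2,
                             noise_amplitude_coeff = 2000,
                             cal_offset = -8,
                             cal_scale = 0.97,
                             cal_size_coeff = 0.002,
                             cal_interaction = 0,
                             delta_added_h = -650,
                             n_added = 2,
                             n_total = 82,
                             amplitude_range = c(500, 8000),
                             sample_total_amplitude = 6000,
                             detection_limit = 50,
                             n_injections = 3,
                             mu_range = c(0.05, 0.30),
                             od0 = 0.005,
                             od_max = 1.5,
                             growth_noise_sd = 0.01,
                             growth_times = seq(0, 48, by = 3),
                             seed = NULL) {
  cfg <- as.list(environment())
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid synthetic config: ", ...,
                                 call. = FALSE)
  if (cfg$n_treatments < 1 || cfg$replicates_per_treatment < 1) {
    stop_cfg("design dimensions must be >= 1")
  }
  if (cfg$true_epsilon_sd < 0) stop_cfg("true_epsilon_sd must be >= 0")
  if (cfg$noise_base_sigma < 0 || cfg$noise_amplitude_coeff < 0) {
    stop_cfg("noise parameters must be >= 0")
  }
  if (cfg$cal_scale <= 0.5 || cfg$cal_scale >= 1.5) {
    stop_cfg("cal_scale must lie in (0.5, 1.5)")
  }
  if (length(cfg$abundance_dirichlet) != 4 ||
      any(cfg$abundance_dirichlet <= 0)) {
    stop_cfg("abundance_dirichlet must be 4 positive values")
  }
  if (any(cfg$amplitude_range <= 0) || cfg$sample_total_amplitude <= 0) {
    stop_cfg("amplitudes must be positive")
  }
  if (diff(cfg$water_delta_range) < 0) {
    stop_cfg("water_delta_range must be ascending")
  }
  if (cfg$n_added < 0 || cfg$n_added >= cfg$n_total) {
    stop_cfg("need 0 <= n_added < n_total")
  }
  if (cfg$mu_range[1] < 0) stop_cfg("growth rates must be >= 0")
  if (cfg$od0 <= 0) stop_cfg("od0 must be positive")
  if (cfg$growth_noise_sd < 0) stop_cfg("growth_noise_sd must be >= 0")
  invisible(cfg)
}

#' Synthetic n-alkane isotope standard ladder
#'
#' A synthetic stand-in for a laboratory n-alkane calibration mixture:
#' sixteen n-alkanes (C15--C30) with accepted delta-2H values evenly
#' spanning -9 to -263 permil vs VSMOW, plus an nC36 alkane at
#' -259.2 permil.  The compound set and value span emulate the ladders
#' used for GC-P-IRMS hydrogen calibration; the individual values are
#' synthetic, not certified reference values.
#'
#' @return A tibble with columns `compound`, `accepted_d2h` (permil vs
#'   VSMOW), and `accepted_sigma` (permil).
#' @export
a7_standard_ladder <- function() {
  chains <- 15:30
  tibble::tibble(
    compound = c(sprintf("nC%d", chains), "nC36"),
    accepted_d2h = c(round(seq(-9, -263, length.out = length(chains)), 1),
                     -259.2),
    accepted_sigma = 0.5
  )
}

# sigma(A) = a + b/A
noise_sigma <- function(cfg, amplitude) {
  cfg$noise_base_sigma + cfg$noise_amplitude_coeff / amplitude
}

# forward instrument model shared by standards and samples
instrument_raw <- function(cfg, true_delta, amplitude, noisy = TRUE) {
  raw <- cfg$cal_offset + cfg$cal_scale * true_delta +
    cfg$cal_size_coeff * amplitude +
    cfg$cal_interaction * true_delta * amplitude
  if (noisy) {
    sig <- noise_sigma(cfg, amplitude)
    raw <- raw + stats::rnorm(length(raw), 0, sig)
  }
  raw
}

#' Generate one synthetic standards run
#'
#' Produces one peak per ladder compound at randomised amplitudes, passed
#' through the configured instrument model (offset, scale compression,
#' peak-size effect, amplitude-dependent noise).
#'
#' @param config a [synthetic_config()].
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (so callers can manage a single stream).
#' @param run_id label for the run.
#' @param injection injection number.
#' @return A tibble of peak measurements with columns `run_id`,
#'   `injection`, `compound`, `rt`, `amplitude`, `area`, `d2h_raw`,
#'   `is_standard`.
#' @export
generate_standards_run <- function(config, seed = NULL, run_id = "std-1",
                                   injection = 1L) {
  validate_synthetic_config(config)
  if (!is.null(seed)) set.seed(seed)
  lad <- a7_standard_ladder()
  k <- nrow(lad)
  amp <- stats::runif(k, config$amplitude_range[1], config$amplitude_range[2])
  raw <- instrument_raw(config, lad$accepted_d2h, amp)
  tibble::tibble(
    run_id = run_id,
    injection = as.integer(injection),
    compound = lad$compound,
    rt = 600 + 60 * seq_len(k),
    amplitude = amp,
    area = amp * 0.003,
    d2h_raw = raw,
    is_standard = TRUE
  )
}

#' Generate one synthetic sample injection
#'
#' Builds the true biphytane delta-2H values from the per-moiety true
#' fractionation and the growth-water delta-2H (inverting the epsilon
#' definition), applies the hydrogenation isotope dilution
#' (`n_total - n_added` biosynthetic H mixed with `n_added` H at
#' `delta_added_h`), then the same instrument distortion and noise as for
#' standards.  Peak amplitudes are proportional to the moiety
#' abundances; peaks below the detection limit are dropped.
#'
#' @param eps_true numeric length-4: true epsilon (permil) for BP-0..BP-3.
#' @param abundances numeric length-4 relative abundances summing to 1
#'   (within 1e-6).
#' @param water_delta growth-water delta-2H (permil).
#' @param config a [synthetic_config()].
#' @param seed optional integer seed (see [generate_standards_run()]).
#' @param run_id,injection,culture_id,treatment labels attached to the
#'   peaks.
#' @return A tibble of sample peak measurements (columns as in
#'   [generate_standards_run()] plus `culture_id` and `treatment`).
#' @export
generate_sample_run <- function(eps_true, abundances, water_delta, config,
                                seed = NULL, run_id = "run-1",
                                injection = 1L, culture_id = "culture-1",
                                treatment = "T1") {
  validate_synthetic_config(config)
  if (length(eps_true) != 4 || length(abundances) != 4) {
    stop("eps_true and abundances must have length 4", call. = FALSE)
  }
  if (abs(sum(abundances) - 1) > 1e-6) {
    stop("abundances must sum to 1 within 1e-6", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # invert the epsilon definition to get the true biosynthetic delta
  d_bio <- (1 + eps_true / 1000) * (1000 + water_delta) - 1000
  d_dil <- dilute_hydrogenation(d_bio, config$delta_added_h,
                                config$n_added, config$n_total)
  total_amp <- config$sample_total_amplitude * stats::runif(1, 0.8, 1.2)
  amp <- total_amp * abundances
  keep <- amp >= config$detection_limit
  raw <- instrument_raw(config, d_dil[keep], amp[keep])
  tibble::tibble(
    run_id = run_id,
    injection = as.integer(injection),
    compound = sprintf("BP-%d", 0:3)[keep],
    rt = 2400 + 90 * (0:3)[keep],
    amplitude = amp[keep],
    area = amp[keep] * 0.003,
    d2h_raw = raw,
    is_standard = FALSE,
    culture_id = culture_id,
    treatment = treatment
  )
}

# forward isotope dilution applied during (synthetic) hydrogenation
dilute_hydrogenation <- function(delta_bio, delta_added, n_added, n_total) {
  ((n_total - n_added) * delta_bio + n_added * delta_added) / n_total
}

#' Generate a synthetic OD600 growth curve
#'
#' Exponential growth \eqn{OD(t) = OD_0 e^{\mu t}}, optionally capped at
#' a plateau `od_max`, with multiplicative Gaussian noise.
#'
#' @param mu specific growth rate (per hour, >= 0).
#' @param od0 initial OD600 (> 0).
#' @param times sampling times in hours (non-negative, increasing).
#' @param noise_sd SD of the multiplicative noise (0 for noiseless).
#' @param seed optional integer seed.
#' @param od_max plateau OD (default `Inf`, no plateau).
#' @param culture_id label.
#' @return A tibble with columns `culture_id`, `time_h`, `od600`.
#' @export
generate_growth_curve <- function(mu, od0, times, noise_sd = 0, seed = NULL,
                                  od_max = Inf, culture_id = "culture-1") {
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (od0 <= 0) stop("od0 must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  od <- pmin(od0 * exp(mu * times), od_max)
  if (noise_sd > 0) {
    od <- od * (1 + stats::rnorm(length(times), 0, noise_sd))
  }
  tibble::tibble(culture_id = culture_id, time_h = times, od600 = od)
}

# Dirichlet draw via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a complete synthetic study
#'
#' Emulates a multi-treatment culture experiment: per treatment a true
#' BP-0 fractionation is drawn from the configured spread and extended
#' across rings by the per-ring enrichment; each replicate culture gets
#' its own growth water, abundances, growth rate, growth curve, a
#' standards run, and `n_injections` sample injections, all passed
#' through the instrument model.  A truth table (hidden inputs) is kept
#' in a separate element so pipeline code cannot accidentally consume it.
#' The whole dataset is drawn from a single RNG stream seeded once, so a
#' fixed seed gives bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (falls back to `config$seed`, then 1).
#' @return An object of class `study_dataset`: a list with tibbles
#'   `standards`, `samples`, `metadata` (culture, treatment, level,
#'   water delta), `growth`, `truth`, and the `config`.
#' @export
generate_study <- function(config = synthetic_config(), seed = NULL) {
  validate_synthetic_config(config)
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  set.seed(seed)

  standards <- list()
  samples <- list()
  growth <- list()
  meta <- list()
  truth <- list()

  for (tr in seq_len(config$n_treatments)) {
    treatment <- sprintf("T%d", tr)
    level <- tr
    eps0 <- stats::rnorm(1, config$true_epsilon_mean, config$true_epsilon_sd)
    eps_moiety <- eps0 + config$ring_enrichment_per_ring * (0:3)
    for (rep in seq_len(config$replicates_per_treatment)) {
      culture <- sprintf("%s-r%d", treatment, rep)
      water <- stats::runif(1, config$water_delta_range[1],
                            config$water_delta_range[2])
      ab <- rdirichlet1(config$abundance_dirichlet)
      mu <- stats::runif(1, config$mu_range[1], config$mu_range[2])
      run <- sprintf("run-%s", culture)

      standards[[length(standards) + 1L]] <-
        generate_standards_run(config, run_id = run)
      for (inj in seq_len(config$n_injections)) {
        samples[[length(samples) + 1L]] <-
          generate_sample_run(eps_moiety, ab, water, config,
                              run_id = run, injection = inj,
                              culture_id = culture, treatment = treatment)
      }
      growth[[length(growth) + 1L]] <-
        generate_growth_curve(mu, config$od0, config$growth_times,
                              noise_sd = config$growth_noise_sd,
                              od_max = config$od_max, culture_id = culture)
      meta[[length(meta) + 1L]] <- tibble::tibble(
        culture_id = culture, experiment = "synthetic",
        treatment = treatment, level = level, d2h_water = water,
        d2h_water_sigma = 0.5
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        culture_id = culture, treatment = treatment, mu = mu,
        water_delta = water,
        eps_bp0 = eps_moiety[1], eps_bp1 = eps_moiety[2],
        eps_bp2 = eps_moiety[3], eps_bp3 = eps_moiety[4],
        ab_bp0 = ab[1], ab_bp1 = ab[2], ab_bp2 = ab[3], ab_bp3 = ab[4]
      )
    }
  }

  structure(
    list(
      standards = do.call(rbind, standards),
      samples = do.call(rbind, samples),
      metadata = do.call(rbind, meta),
      growth = do.call(rbind, growth),
      truth = do.call(rbind, truth),
      config = config,
      seed = seed
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>",
      nrow(x$metadata), "cultures,",
      nrow(x$samples), "sample peaks,",
      nrow(x$standards), "standard peaks (seed", x$seed, ")\n")
  invisible(x)
}

#' Write a synthetic study to delimited text files
#'
#' Emits `standards.tsv` and `samples.tsv` (peak tables with the
#' documented header `run_id`, `injection`, `compound`, `rt_s`,
#' `amplitude_mV`, `area_Vs`, `d2H_raw_permil`, plus sample labels),
#' `metadata.tsv` (`culture_id`, `experiment`, `level`,
#' `d2H_water_permil`), `growth.tsv` (`culture_id`, `time_h`, `od600`),
#' `standard_defs.tsv` (ladder accepted values), `truth.tsv` (hidden
#' truth, separate channel), and `config.yaml`.
#'
#' @param study a `study_dataset` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  peak_cols <- function(df) {
    out <- data.frame(
      run_id = df$run_id, injection = df$injection, compound = df$compound,
      rt_s = df$rt, amplitude_mV = df$amplitude, area_Vs = df$area,
      d2H_raw_permil = df$d2h_raw, check.names = FALSE
    )
    if (!is.null(df$culture_id)) {
      out$culture_id <- df$culture_id
      out$treatment <- df$treatment
    }
    out
  }
  files <- c(
    wt(peak_cols(study$standards), "standards.tsv"),
    wt(peak_cols(study$samples), "samples.tsv"),
    wt(data.frame(culture_id = study$metadata$culture_id,
                  experiment = study$metadata$experiment,
                  treatment = study$metadata$treatment,
                  level = study$metadata$level,
                  d2H_water_permil = study$metadata$d2h_water,
                  d2H_water_sigma_permil = study$metadata$d2h_water_sigma,
                  check.names = FALSE), "metadata.tsv"),
    wt(study$growth, "growth.tsv"),
    wt(data.frame(compound = a7_standard_ladder()$compound,
                  accepted_d2H_permil = a7_standard_ladder()$accepted_d2h,
                  accepted_sigma_permil = a7_standard_ladder()$accepted_sigma,
                  check.names = FALSE), "standard_defs.tsv"),
    wt(study$truth, "truth.tsv")
  )
  cfg <- study$config
  cfg$growth_times <- as.numeric(cfg$growth_times)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(c(files, file.path(dir, "config.yaml")))
}
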