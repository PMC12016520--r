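std_run <- function(cfg, seed = 1, n_runs = 1) {
  do.call(rbind, lapply(seq_len(n_runs), function(i) {
    generate_standards_run(cfg, seed = if (i == 1) seed else NULL,
                           run_id = sprintf("std-%d", i))
  }))
}

test_that("calibration recovers planted offset, scale, and size terms", {
  lad <- a7_standard_ladder()
  cfg <- make_noiseless_config(cal_offset = -10, cal_scale = 0.98,
                               cal_size_coeff = 0)
  fit <- fit_calibration(std_run(cfg), lad)
  expect_equal(unname(fit$coefficients["offset"]), -10, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["scale"]), 0.98, tolerance = 1e-9)

  idcfg <- make_noiseless_config(cal_offset = 0, cal_scale = 1,
                                 cal_size_coeff = 0)
  idfit <- fit_calibration(std_run(idcfg), lad)
  expect_equal(unname(idfit$coefficients["offset"]), 0, tolerance = 1e-9)
  expect_equal(unname(idfit$coefficients["scale"]), 1, tolerance = 1e-9)
  expect_equal(idfit$residual_rmse, 0, tolerance = 1e-9)

  szcfg <- make_noiseless_config(cal_size_coeff = 0.002)
  szfit <- fit_calibration(std_run(szcfg), lad)
  expect_equal(unname(szfit$coefficients["size"]), 0.002, tolerance = 1e-9)
})

test_that("degenerate standards designs are rejected", {
  lad <- a7_standard_ladder()
  cfg <- make_noiseless_config()
  run <- std_run(cfg)
  expect_error(fit_calibration(run[run$compound == "nC15", ], lad),
               "distinct")
  bad <- run
  bad$compound[1] <- "mystery"
  expect_error(fit_calibration(bad, lad), "mystery")
})

test_that("apply_calibration inverts the instrument on noiseless data", {
  lad <- a7_standard_ladder()
  cfg <- make_noiseless_config(cal_size_coeff = 0.0015)
  fit <- fit_calibration(std_run(cfg), lad)
  # fresh peaks simulated with the same instrument (no dilution), known truth
  cfg0 <- make_noiseless_config(cal_size_coeff = 0.0015, n_added = 0,
                                detection_limit = 0)
  truth <- ((1 - 210 / 1000) * (1000 - 55)) - 1000
  samp <- generate_sample_run(rep(-210, 4), rep(0.25, 4), -55, cfg0,
                              seed = 9)
  cal <- apply_calibration(fit, samp)
  expect_equal(cal$d2h_cal, rep(truth, 4), tolerance = 1e-9)
  expect_equal(cal$d2h_cal_sigma, rep(0, 4), tolerance = 1e-9)
})

test_that("identity fit returns raw values unchanged", {
  lad <- a7_standard_ladder()
  idcfg <- make_noiseless_config(cal_offset = 0, cal_scale = 1,
                                 cal_size_coeff = 0)
  fit <- fit_calibration(std_run(idcfg), lad)
  peaks <- tibble::tibble(compound = "BP-0", amplitude = c(1000, 4000),
                          d2h_raw = c(-250, -180))
  cal <- apply_calibration(fit, peaks)
  expect_equal(cal$d2h_cal, peaks$d2h_raw, tolerance = 1e-9)
})

test_that("calibrated sigma does not increase with peak amplitude", {
  lad <- a7_standard_ladder()
  cfg <- synthetic_config()
  set.seed(42)
  fit <- fit_calibration(std_run(cfg, n_runs = 30), lad)
  amps <- seq(800, 7000, length.out = 12)
  peaks <- tibble::tibble(compound = "BP-1", amplitude = amps,
                          d2h_raw = -240)
  sig <- apply_calibration(fit, peaks)$d2h_cal_sigma
  expect_true(all(diff(sig) <= 1e-9))
})

test_that("hydrogenation correction matches the pool mass balance", {
  # identity when nothing is added
  out0 <- hydrogenation_correct(iso_value(-250, 3), iso_value(-750, 50),
                                n_added = 0)
  expect_equal(out0$value, -250)
  expect_equal(attr(out0, "correction"), 0)
  # hand-computed: (82*-250 - 2*-750)/80 = -237.5, correction +12.5
  out <- hydrogenation_correct(iso_value(-250, 3), iso_value(-750, 50))
  expect_equal(out$value, -237.5, tolerance = 1e-12)
  expect_equal(attr(out, "correction"), 12.5, tolerance = 1e-12)
  # quadrature propagation: sqrt((82/80*3)^2 + (2/80*50)^2)
  expect_equal(out$sigma, sqrt((82 / 80 * 3)^2 + (2 / 80 * 50)^2),
               tolerance = 1e-12)
  expect_lt(out$sigma - 3, 1.9)
  expect_error(hydrogenation_correct(iso_value(-250), iso_value(-750),
                                     n_added = 82), "n_added")
})

test_that("hydrogenation correction exactly inverts the generator dilution", {
  set.seed(17)
  for (i in 1:20) {
    d_bio <- runif(1, -320, -150)
    d_add <- runif(1, -900, 0)
    n_add <- sample(1:4, 1)
    n_tot <- sample(60:100, 1)
    diluted <- ((n_tot - n_add) * d_bio + n_add * d_add) / n_tot
    rec <- hydrogenation_correct(iso_value(diluted), iso_value(d_add),
                                 n_added = n_add, n_total = n_tot)
    expect_equal(rec$value, d_bio, tolerance = 1e-10)
    # correction magnitude is linear in (measured - added) with slope
    # n_added/(n_total - n_added)
    expect_equal(attr(rec, "correction"),
                 (n_add / (n_tot - n_add)) * (diluted - d_add),
                 tolerance = 1e-10)
  }
})

test_that("diagnostics expose residual structure", {
  lad <- a7_standard_ladder()
  cfg <- make_noiseless_config()
  run <- std_run(cfg)
  fit <- fit_calibration(run, lad)
  di <- calibration_diagnostics(fit, run, lad)
  expect_true(all(abs(di$per_standard$residual) < 1e-9))
  expect_equal(di$residual_rmse, 0, tolerance = 1e-9)
  # a single perturbed standard carries the largest residual
  run2 <- run
  i <- which(run2$compound == "nC22")
  run2$d2h_raw[i] <- run2$d2h_raw[i] + 20
  fit2 <- fit_calibration(run2, lad)
  di2 <- calibration_diagnostics(fit2, run2, lad)
  worst <- di2$per_standard$compound[which.max(abs(di2$per_standard$residual))]
  expect_equal(worst, "nC22")
})

test_that("binned repeatability tracks the configured noise at scale", {
  cfg <- synthetic_config()
  set.seed(7)
  lad <- a7_standard_ladder()
  rmses <- replicate(200, {
    fit <- fit_calibration(std_run(cfg, n_runs = 2), lad)
    fit$residual_rmse
  })
  med_amp <- mean(cfg$amplitude_range)
  target <- cfg$noise_base_sigma + cfg$noise_amplitude_coeff / med_amp
  expect_equal(mean(rmses), target, tolerance = 0.25)
})
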