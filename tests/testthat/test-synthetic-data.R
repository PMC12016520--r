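test_that("identity instrument reproduces accepted standard values", {
  cfg <- make_noiseless_config(cal_offset = 0, cal_scale = 1,
                               cal_size_coeff = 0)
  run <- generate_standards_run(cfg, seed = 1)
  lad <- a7_standard_ladder()
  expect_equal(run$d2h_raw, lad$accepted_d2h[match(run$compound,
                                                   lad$compound)],
               tolerance = 1e-12)
  # ladder spans -9 to -263 permil and carries the C36 alkane
  expect_equal(range(lad$accepted_d2h), c(-263, -9))
  expect_equal(lad$accepted_d2h[lad$compound == "nC36"], -259.2)
})

test_that("pure offset shifts every standard by exactly the offset", {
  cfg <- make_noiseless_config(cal_offset = -10, cal_scale = 1,
                               cal_size_coeff = 0)
  run <- generate_standards_run(cfg, seed = 2)
  lad <- a7_standard_ladder()
  expect_equal(run$d2h_raw,
               lad$accepted_d2h[match(run$compound, lad$compound)] - 10,
               tolerance = 1e-12)
})

test_that("planted size effect appears linearly in amplitude", {
  cfg <- make_noiseless_config(cal_offset = 0, cal_scale = 1,
                               cal_size_coeff = 0.002)
  run <- generate_standards_run(cfg, seed = 3)
  lad <- a7_standard_ladder()
  acc <- lad$accepted_d2h[match(run$compound, lad$compound)]
  expect_equal(run$d2h_raw - acc, 0.002 * run$amplitude, tolerance = 1e-12)
})

test_that("noise follows the sigma(A) = a + b/A law", {
  # fixed amplitude so the law can be checked against an empirical SD
  cfg <- synthetic_config(noise_base_sigma = 2, noise_amplitude_coeff = 2000,
                          amplitude_range = c(3000, 3000))
  set.seed(99)
  lad <- a7_standard_ladder()
  resid <- replicate(1000, {
    run <- generate_standards_run(cfg)
    acc <- lad$accepted_d2h[match(run$compound, lad$compound)]
    expected <- cfg$cal_offset + cfg$cal_scale * acc +
      cfg$cal_size_coeff * run$amplitude
    (run$d2h_raw - expected)[1]
  })
  target <- 2 + 2000 / 3000
  expect_equal(sd(resid), target, tolerance = 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(noise_base_sigma = -1), "noise")
  expect_error(synthetic_config(cal_scale = 0.4), "cal_scale")
  expect_error(synthetic_config(abundance_dirichlet = c(1, 2, 3)),
               "dirichlet")
  expect_error(synthetic_config(amplitude_range = c(-5, 100)), "positive")
  expect_error(synthetic_config(n_added = 90), "n_added")
})

test_that("hydrogenation dilution in sample generation is exact mass balance", {
  base <- list(cal_offset = 0, cal_scale = 1, cal_size_coeff = 0,
               detection_limit = 0)
  # n_total 82, n_added 2, true -250, added -750: (80*-250 + 2*-750)/82
  cfg <- do.call(make_noiseless_config, c(base, list(delta_added_h = -750)))
  run <- generate_sample_run(rep(-250, 4), rep(0.25, 4), water_delta = 0,
                             cfg, seed = 4)
  expect_equal(run$d2h_raw, rep((80 * -250 + 2 * -750) / 82, 4),
               tolerance = 1e-12)
  # equal-pool mixing is a no-op
  cfg2 <- do.call(make_noiseless_config, c(base, list(delta_added_h = -650)))
  run2 <- generate_sample_run(rep(-650, 4), rep(0.25, 4), water_delta = 0,
                              cfg2, seed = 5)
  expect_equal(run2$d2h_raw, rep(-650, 4), tolerance = 1e-12)
})

test_that("sample generation inverts epsilon against growth water", {
  # printed worked example: eps -234, water -59.7 -> peak delta ~ -280
  cfg <- make_noiseless_config(cal_offset = 0, cal_scale = 1,
                               cal_size_coeff = 0, n_added = 0,
                               detection_limit = 0)
  run <- generate_sample_run(rep(-234, 4), rep(0.25, 4),
                             water_delta = -59.7, cfg, seed = 6)
  expect_equal(round(run$d2h_raw[1]), -280)
  # peak areas proportional to abundances
  ab <- c(0.5, 0.3, 0.15, 0.05)
  run2 <- generate_sample_run(rep(-200, 4), ab, -50, cfg, seed = 7)
  expect_equal(run2$amplitude / sum(run2$amplitude), ab, tolerance = 1e-12)
  expect_error(generate_sample_run(rep(-200, 4), c(0.5, 0.3, 0.1, 0.2),
                                   -50, cfg),
               "sum to 1")
})

test_that("growth curves behave at the trivial limits", {
  flat <- generate_growth_curve(0, 0.1, 0:5)
  expect_equal(flat$od600, rep(0.1, 6))
  one <- generate_growth_curve(log(2), 0.01, c(0, 1))
  expect_equal(one$od600[2], 0.02, tolerance = 1e-12)
  expect_error(generate_growth_curve(0.1, 0.01, c(-1, 0, 1)),
               "non-negative")
  capped <- generate_growth_curve(1, 0.5, 0:10, od_max = 1.2)
  expect_equal(max(capped$od600), 1.2)
})

test_that("study generation is deterministic and structurally complete", {
  cfg <- synthetic_config(n_treatments = 5, replicates_per_treatment = 3)
  a <- generate_study(cfg, seed = 123)
  b <- generate_study(cfg, seed = 123)
  expect_identical(a, b)
  c <- generate_study(cfg, seed = 124)
  # same design (cultures, runs, injections); noise draws differ, and
  # below-detection peaks may drop, so peak counts can vary slightly
  expect_identical(dim(c$metadata), dim(a$metadata))
  expect_identical(dim(c$growth), dim(a$growth))
  expect_identical(dim(c$standards), dim(a$standards))
  expect_identical(unique(c$samples$injection), unique(a$samples$injection))
  expect_false(isTRUE(all.equal(a$standards$d2h_raw, c$standards$d2h_raw)))
  # 5 x 3 design: 15 cultures, each with standards, water, growth, truth
  expect_equal(nrow(a$metadata), 15)
  expect_equal(nrow(a$truth), 15)
  expect_setequal(unique(a$growth$culture_id), a$metadata$culture_id)
  expect_setequal(unique(a$samples$culture_id), a$metadata$culture_id)
  expect_equal(length(unique(a$standards$run_id)), 15)
  # truth abundances sum to one
  tot <- with(a$truth, ab_bp0 + ab_bp1 + ab_bp2 + ab_bp3)
  expect_true(all(abs(tot - 1) < 1e-6))
})
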