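test_that("delta/ratio conversions satisfy closed forms and round-trip", {
  expect_equal(delta_from_ratio(1, 1), 0)
  expect_equal(ratio_from_delta(-500), 0.5)
  for (d in c(-999, -204, 0, 350)) {
    expect_equal(delta_from_ratio(ratio_from_delta(d), 1), d,
                 tolerance = 1e-12)
  }
  expect_error(delta_from_ratio(-0.1, 1), "positive")
  expect_error(ratio_from_delta(-1000), "non-positive")
})

test_that("epsilon_lw reproduces worked fractionation values", {
  # chemostat 7 h BP-0: printed delta pair gives -234 permil
  e1 <- epsilon_lw(iso_value(-280), iso_value(-59.7))
  expect_equal(e1$value, ((1000 - 280) / (1000 - 59.7) - 1) * 1000)
  expect_equal(round(e1$value), -234)
  # pH 2 BP-0 gives -211 permil
  e2 <- epsilon_lw(iso_value(-258), iso_value(-59.8))
  expect_equal(round(e2$value), -211)
})

test_that("epsilon_lw identity, monotonicity, and error propagation", {
  set.seed(11)
  for (x in runif(5, -300, 100)) {
    expect_equal(epsilon_lw(iso_value(x), iso_value(x))$value, 0,
                 tolerance = 1e-12)
  }
  # strictly increasing in delta_bp at fixed water
  d <- sort(runif(20, -400, 0))
  eps <- epsilon_lw(iso_value(d), iso_value(-50))$value
  expect_true(all(diff(eps) > 0))
  expect_error(epsilon_lw(iso_value(-100), iso_value(-1000)))
  # first-order sigma agrees with Monte-Carlo spread
  mc <- replicate(4000, {
    epsilon_lw(iso_value(-250 + rnorm(1, 0, 5)),
               iso_value(-50 + rnorm(1, 0, 2)))$value
  })
  prop <- epsilon_lw(iso_value(-250, 5), iso_value(-50, 2))$sigma
  expect_equal(sd(mc), prop, tolerance = 0.1)
})

test_that("weighted_mean implements 1/sigma^2 weights and the max error rule", {
  # single value passes through
  one <- weighted_mean(iso_value(-210, 3))
  expect_equal(one$value, -210)
  expect_equal(one$sigma, 3)
  # hand-computed oracle: weights 1 and 0.01
  wm <- weighted_mean(iso_value(c(-200, -100), sigma = c(1, 10)))
  expect_equal(wm$value, (-200 * 1 + -100 * 0.01) / 1.01, tolerance = 1e-12)
  expect_equal(wm$value, oracle_weighted_mean(c(-200, -100), c(1, 10)))
  # equal sigmas reduce to the arithmetic mean, error >= replicate SD
  eq <- weighted_mean(iso_value(c(-200, -210), sigma = 2))
  expect_equal(eq$value, -205)
  expect_gte(eq$sigma, sd(c(-200, -210)) - 1e-12)
  # reported sigma never below the propagated sigma of the weighted mean
  set.seed(21)
  for (i in 1:25) {
    v <- rnorm(sample(2:6, 1), -200, 10)
    s <- runif(length(v), 0.5, 8)
    out <- weighted_mean(iso_value(v, s))
    expect_gte(out$sigma, sqrt(1 / sum(1 / s^2)) - 1e-12)
    expect_equal(out$value, oracle_weighted_mean(v, s), tolerance = 1e-12)
  }
  expect_error(weighted_mean(iso_value(NA_real_)), "no non-missing")
})

test_that("abundance_weighted_mean applies the >5% rule and renormalises", {
  # 75 degree treatment: printed abundances and epsilons give -224
  wm <- abundance_weighted_mean(c(0.06, 0.13, 0.60, 0.21),
                                iso_value(c(-220, -214, -226, -227)))
  expect_equal(round(wm$value), -224)
  expect_equal(wm$value, sum(c(0.06, 0.13, 0.60, 0.21) *
                               c(-220, -214, -226, -227)),
               tolerance = 1e-12)
  # equal values are returned whatever the abundances
  expect_equal(abundance_weighted_mean(c(0.4, 0.1, 0.3, 0.2),
                                       iso_value(rep(-205, 4)))$value, -205)
  # a 3% moiety is excluded by the threshold
  wm2 <- abundance_weighted_mean(c(0.97, 0.03), iso_value(c(-200, -100)))
  expect_equal(wm2$value, -200)
  expect_equal(attr(wm2, "excluded"), 2L)
  # missing values are excluded and the rest renormalised
  wm3 <- abundance_weighted_mean(c(0.5, 0.25, 0.25),
                                 iso_value(c(-200, NA, -100)))
  expect_equal(wm3$value, (-200 * 2 / 3) + (-100 * 1 / 3), tolerance = 1e-12)
  expect_error(abundance_weighted_mean(c(0.04, 0.96),
                                       iso_value(c(-200, NA))),
               "threshold")
})

test_that("ring indices match worked values, endpoints, and scaling", {
  expect_equal(ring_index_bp(c(0.18, 0.31, 0.36, 0.15)), 1.48)
  expect_equal(ring_index_bp(c(0.31, 0.39, 0.28, 0.02)), 1.01)
  expect_equal(ring_index_bp(c(1, 0, 0, 0)), 0)
  expect_equal(ring_index_bp(c(0, 0, 0, 1)), 3)
  # invariant to positive rescaling
  set.seed(5)
  for (i in 1:10) {
    a <- runif(4)
    k <- runif(1, 0.1, 50)
    expect_equal(ring_index_bp(a * k), ring_index_bp(a), tolerance = 1e-12)
  }
  expect_error(ring_index_bp(c(0, 0, 0, 0)), "zero")
  expect_error(ring_index_bp(c(0.5, 0.5)), "expected 4")
  # iGDGT variant spans rings 0..8
  expect_equal(ring_index_gdgt(c(0, 0, 0, 0, 1, 0, 0, 0, 0)), 4)
  expect_equal(ring_index_gdgt(rep(1 / 9, 9)), 4)
  gg <- numeric(9); gg[2] <- 0.5; gg[4] <- 0.5
  expect_equal(ring_index_gdgt(gg), 2)
})

test_that("ring_difference matches worked rows and the brute-force oracle", {
  # 21 h chemostat: per-moiety means round to (0, 0, 3, 14)
  eps21 <- iso_value(c(-214, -214, -210, -189))
  rd <- ring_difference(eps21)
  expect_equal(round(rd$d_eps_ring), c(0, 0, 3, 14))
  expect_equal(rd$d_eps_ring[4], mean(c(25 / 3, 25 / 2, 21)),
               tolerance = 1e-12)
  # 7 h chemostat: (0, 4, 4, 14)
  eps7 <- iso_value(c(-234, -230, -226, -205))
  expect_equal(round(ring_difference(eps7)$d_eps_ring), c(0, 4, 4, 14))
  # agreement with brute-force enumeration on random epsilon maps
  set.seed(33)
  for (i in 1:20) {
    e <- runif(4, -260, -180)
    e[sample(4, sample(0:1, 1))] <- NA  # sometimes drop a moiety
    if (sum(!is.na(e)) < 2) next
    rd <- ring_difference(iso_value(e))
    for (r in rd$ring[rd$ring > min(rd$ring)]) {
      expect_equal(rd$d_eps_ring[rd$ring == r],
                   oracle_ring_diff_moiety(e, 0:3, r), tolerance = 1e-12)
    }
    expect_equal(mean_ring_difference(iso_value(e))$value,
                 oracle_mean_ring_diff(e, 0:3), tolerance = 1e-12)
  }
  # all-equal epsilons give zero everywhere
  expect_true(all(ring_difference(iso_value(rep(-200, 4)))$d_eps_ring == 0))
  # single moiety: warning and empty result
  expect_warning(out <- ring_difference(iso_value(c(-200, NA, NA, NA))),
                 "fewer than two")
  expect_equal(nrow(out), 0)
})

test_that("pooled mean ring difference reproduces chemostat treatment cells", {
  eps <- list(`7` = c(-234, -230, -226, -205),
              `21` = c(-214, -214, -210, -189),
              `44` = c(-214, -207, -202, -199))
  pooled <- vapply(eps, function(e) mean_ring_difference(iso_value(e))$value, 1)
  expect_equal(round(pooled), c(`7` = 9, `21` = 8, `44` = 5))
  expect_lte(abs(mean(pooled) - 7.4), 0.02)
})

test_that("iso_value container validates, indexes, and concatenates", {
  expect_error(iso_value(-200, sigma = -1), "non-negative")
  x <- c(iso_value(-200, 2), iso_value(c(-210, -220), c(3, 4), n = 2))
  expect_length(x, 3)
  expect_equal(x[2]$sigma, 3)
  expect_equal(as.data.frame(x)$n, c(1L, 2L, 2L))
})
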