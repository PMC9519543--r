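test_that("binding rates are least-squares slopes in events per hour", {
  r <- estimate_rate(c(0, 1800, 3600), c(0, 5, 10))
  expect_equal(r$rate, 10, tolerance = 1e-12)
  expect_equal(r$rate_se, 0, tolerance = 1e-9)

  flat <- estimate_rate((0:9) * 60, rep(0, 10))
  expect_equal(flat$rate, 0)
  expect_true(is.finite(flat$rate_se))

  expect_error(estimate_rate(c(0, 10), c(0, 1)), "3 time points")

  # Monte-Carlo: Poisson stream at 20/h is recovered without bias
  set.seed(41)
  cfg <- simulation_config(rate_constant = 20, duration = 3600,
                           frame_interval = 30)
  spot <- spot_region(0, 0, 5)
  times <- (0:119) * 30
  ests <- replicate(100, {
    ev <- sample_events(cfg, spot, cfg$c_ref)
    counts <- vapply(times, function(t) sum(ev$t_bind <= t), numeric(1))
    estimate_rate(times, counts)$rate
  })
  expect_lt(abs(mean(ests) - 20), 3 * stats::sd(ests) / sqrt(100))
  expect_gte(mean(abs(ests - 20) < 3 * stats::sd(ests)), 0.95)
})

test_that("power-law calibration fits recover exponents", {
  conc <- 10^seq(-16, -12)
  exact <- 3e14 * conc^0.8
  fit <- fit_calibration(conc, exact)
  expect_equal(fit$slope, 0.8, tolerance = 1e-9)

  # two points: exact interpolating line
  f2 <- fit_calibration(c(1e-15, 1e-13), c(10, 40))
  expect_equal(f2$slope, log10(4) / 2, tolerance = 1e-12)
  expect_true(all(is.na(f2$slope_ci)))

  # model-exact data with the theoretical slope has zero residual
  r23 <- 50 * (conc / 1e-15)^(2 / 3)
  f23 <- fit_calibration(conc, r23)
  resid <- f23$points$log10_r -
    (f23$theoretical_intercept + (2 / 3) * f23$points$log10_c)
  expect_lt(max(abs(resid)), 1e-9)

  # noisy b = 0.8 over 100 seeds: mean fitted exponent within 0.05
  set.seed(42)
  slopes <- replicate(100, {
    noisy <- exact * 10^stats::rnorm(5, 0, 0.15)
    fit_calibration(conc, noisy)$slope
  })
  expect_lt(abs(mean(slopes) - 0.8), 0.05)

  expect_warning(fit_calibration(conc, c(0, exact[-1])), "excluded")
})

test_that("endpoint LOD follows 3.3 sigma / slope with linear-scale slope", {
  # linear response 10 counts/fM: power-law with b = 1, a = 10^16 counts/M
  conc <- c(1e-15, 1e-14, 1e-13)
  fit <- fit_calibration(conc, 1e16 * conc)
  blank <- blank_stats(c(0, 3, 6))          # sd = 3 counts, n = 3
  lod <- lod_endpoint(blank, fit)
  expect_equal(lod$lod, 3.3 * 3 / 1e16, tolerance = 1e-9)  # 0.99 fM

  blank0 <- blank_stats(c(2, 2, 2))         # sd = 0
  expect_equal(lod_endpoint(blank0, fit)$lod, 0)

  # linear in sigma, inverse in slope
  lod2 <- lod_endpoint(blank_stats(c(0, 6, 12)), fit)
  expect_equal(lod2$lod, 2 * lod$lod, tolerance = 1e-12)
  fit2 <- fit_calibration(conc, 2e16 * conc)
  expect_equal(lod_endpoint(blank, fit2)$lod, lod$lod / 2, tolerance = 1e-12)

  # the global-linear alternative agrees for an exactly linear response
  expect_equal(lod_endpoint(blank, fit, method = "global_linear")$lod,
               lod$lod, tolerance = 1e-6)
})

test_that("kinetic LOD inverts model-exact data to numerical precision", {
  c0 <- 1e-15; r0 <- 50
  conc <- 10^seq(-16, -12)
  rates <- r0 * (conc / c0)^(2 / 3)
  c_star <- 3e-17
  thr <- r0 * (c_star / c0)^(2 / 3)
  blank <- blank_stats(c(thr / 2 - thr / 6, thr / 2, thr / 2 + thr / 6))
  # mean + 3 sd = thr/2 + 3*(thr/6) = thr exactly
  lod <- lod_kinetic(conc, rates, blank)
  expect_equal(lod$lod / c_star, 1, tolerance = 1e-9)
  expect_true(lod$extrapolated)  # below the fitted range, as designed

  # scale equivariance: scaling all concentrations scales the LOD
  lod_k <- lod_kinetic(conc * 37, rates, blank)
  expect_equal(lod_k$lod / (37 * c_star), 1, tolerance = 1e-9)

  # degenerate blanks: all-zero threshold errors, a floor rescues it
  zero_blank <- blank_stats(c(0, 0, 0))
  expect_error(lod_kinetic(conc, rates, zero_blank), "threshold")
  lod_f <- lod_kinetic(conc, rates, zero_blank, floor = thr)
  expect_equal(lod_f$lod / c_star, 1, tolerance = 1e-9)

  # threshold above all responses: flagged as extrapolated above the range
  hi_blank <- blank_stats(c(1e5, 1.1e5, 1.2e5))
  lod_hi <- lod_kinetic(conc, rates, hi_blank)
  expect_true(lod_hi$extrapolated)
  expect_gt(lod_hi$lod, max(conc))
})

test_that("the LOD interval brackets the theoretical-slope estimate", {
  # measured-like data: a slightly soft exponent whose confidence interval
  # still covers the theoretical 2/3 (the well-posed regime)
  set.seed(1)
  c0 <- 1e-15
  conc <- 10^seq(-16, -12)
  rates <- 50 * (conc / c0)^0.63 * 10^stats::rnorm(5, 0, 0.04)
  blank <- blank_stats(c(0.5, 1.0, 1.5))
  lod <- lod_kinetic(conc, rates, blank)
  fit <- lod$fit
  expect_lt(fit$slope, 2 / 3)
  expect_gt(fit$slope_ci[2], 2 / 3)
  expect_lte(lod$interval[1], lod$lod)
  expect_lte(lod$lod, lod$interval[2])
})

test_that("molarity/copies conversions use Avogadro's number", {
  expect_equal(molarity_copies(0, 1), 0)
  expect_equal(molarity_copies(1, 1), 6.02214076e23)
  expect_equal(copies_molarity(molarity_copies(3e-17, 2e-4), 2e-4), 3e-17)
  expect_error(molarity_copies(-1, 1))
})

test_that("molarity strings parse and format case-sensitively", {
  expect_equal(parse_molarity(c("100aM", "1fM", "1pM")),
               c(1e-16, 1e-15, 1e-12))
  expect_equal(parse_molarity("2.5 nM"), 2.5e-9)
  expect_error(parse_molarity("100am"), "parse")
  expect_error(parse_molarity("fM"), "parse")
  expect_equal(format_molarity(1e-16), "100 aM")
  expect_equal(format_molarity(2.5e-9), "2.5 nM")
})
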