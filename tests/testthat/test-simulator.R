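test_that("event sampling follows the c^(2/3) Poisson rate law", {
  cfg <- simulation_config(rate_constant = 10, duration = 3600)
  spot <- spot_region(64, 64, 40)

  expect_equal(nrow(sample_events(cfg, spot, 0)), 0)
  expect_error(sample_events(cfg, spot, -1e-15), "non-negative")

  # mean count at c_ref matches k * duration (Monte-Carlo, 3 SE band)
  set.seed(101)
  n <- replicate(1000, nrow(sample_events(cfg, spot, cfg$c_ref)))
  se <- sqrt(10 / 1000)
  expect_lt(abs(mean(n) - 10), 3 * se)

  # 8x the concentration quadruples the rate: (8)^(2/3) = 4
  expect_equal(binding_rate_law(cfg, 8 * cfg$c_ref),
               4 * binding_rate_law(cfg, cfg$c_ref))
  set.seed(102)
  n8 <- replicate(1000, nrow(sample_events(cfg, spot, 8 * cfg$c_ref)))
  se8 <- sqrt(40 / 1000)
  expect_lt(abs(mean(n8) - 40), 3 * se8)
})

test_that("arrival counts are Poisson (variance/mean near 1) and events lie in the spot", {
  cfg <- simulation_config(rate_constant = 50, duration = 2100)
  spot <- spot_region(48, 52, 30)
  set.seed(103)
  counts <- replicate(500, nrow(sample_events(cfg, spot, cfg$c_ref)))
  fano <- stats::var(counts) / mean(counts)
  expect_gt(fano, 0.8)
  expect_lt(fano, 1.2)

  set.seed(104)
  ev <- sample_events(cfg, spot, 10 * cfg$c_ref)
  expect_true(all((ev$x - spot$x)^2 + (ev$y - spot$y)^2 <= spot$radius^2))
  expect_true(all(ev$t_unbind > ev$t_bind))
  expect_true(all(ev$t_bind >= 0 & ev$t_bind <= cfg$duration))
})

test_that("same seed gives bit-identical events and frames", {
  cfg <- simulation_config(image_shape = c(48, 48), duration = 600)
  spot <- spot_region(23.5, 23.5, 15)
  run <- function() {
    set.seed(77)
    ev <- sample_events(cfg, spot, cfg$c_ref)
    list(ev = ev, movie = render_timelapse(cfg, ev))
  }
  a <- run(); b <- run()
  expect_identical(a$ev, b$ev)
  expect_identical(a$movie$frames, b$movie$frames)
})

test_that("rendered time-lapse places bumps at the right times and places", {
  cfg <- simulation_config(image_shape = c(48, 48), frame_interval = 10,
                           duration = 200, shot_noise_scale = 0)
  # blank, noiseless: constant background
  blank <- render_timelapse(cfg, empty_events(), noise = FALSE)
  expect_true(all(blank$frames == cfg$background_level))

  # permanent event appearing at frame 5
  ev <- events_from_positions(data.frame(x = 20, y = 24), t_bind = 50)
  movie <- render_timelapse(cfg, ev, noise = FALSE)
  px <- movie$frames[25, 21, ]  # row = y+1, col = x+1
  expect_true(all(px[1:5] == cfg$background_level))
  expect_true(all(px[6:20] > cfg$background_level + 0.9 *
                    cfg$particle_contrast * cfg$background_level))

  # two events 10 px apart: local maxima at the planted coordinates
  ev2 <- events_from_positions(data.frame(x = c(15, 25), y = c(30, 30)),
                               t_bind = 0)
  m2 <- render_timelapse(cfg, ev2, noise = FALSE)
  f <- m2$frames[, , 10]
  for (i in 1:2) {
    win <- f[(31 - 3):(31 + 3), (ev2$x[i] + 1 - 3):(ev2$x[i] + 1 + 3)]
    pk <- which(win == max(win), arr.ind = TRUE)
    expect_lte(abs(pk[1] - 4), 0.5)  # centre of the 7x7 window
    expect_lte(abs(pk[2] - 4), 0.5)
  }
  expect_error(render_timelapse(cfg, events_from_positions(
    data.frame(x = 100, y = 10), t_bind = 0)), "bounds")
})

test_that("z-stack rendering follows the odd defocus curve", {
  cfg <- simulation_config(image_shape = c(48, 48), shot_noise_scale = 0)
  z <- (seq_len(cfg$n_z) - (cfg$n_z + 1) / 2) * cfg$z_step
  a <- defocus_amplitude(cfg, z)

  # odd in z: sign flips through focus
  delta <- cfg$z_step / 2
  expect_lt(defocus_amplitude(cfg, -delta) * defocus_amplitude(cfg, delta), 0)

  # no particles: max-min is exactly zero without noise
  zs0 <- render_zstack(cfg, data.frame(x = numeric(), y = numeric()),
                       noise = FALSE)
  expect_true(all(differential_image(zs0) == 0))

  # one particle at a pixel centre: differential equals the a(z) excursion
  zs1 <- render_zstack(cfg, data.frame(x = 24, y = 24), noise = FALSE)
  d <- differential_image(normalize_stack(zs1))
  expect_equal(d[25, 25], max(a) - min(a), tolerance = 1e-9)
})

test_that("calibration datasets reproduce the generating rate law", {
  cfg <- simulation_config(duration = 2100)
  expect_equal(cfg$concentrations, 10^seq(-16, -12))

  cfg0 <- simulation_config(nonspecific_rate = 0, duration = 2100)
  cal0 <- make_calibration_dataset(cfg0, replicates = 2L, seed = 5)
  expect_true(all(cal0$blanks$rate == 0))

  cfg2 <- simulation_config(rate_constant = 20, duration = 3600,
                            frame_interval = 30)
  cal <- make_calibration_dataset(cfg2, concentrations = 10^seq(-16, -13),
                                  replicates = 200L, seed = 6)
  agg <- stats::aggregate(rate ~ concentration, cal$points, mean)
  for (i in seq_len(nrow(agg))) {
    lam <- binding_rate_law(cfg2, agg$concentration[i])
    sub <- cal$points$rate[cal$points$concentration == agg$concentration[i]]
    se <- stats::sd(sub) / sqrt(length(sub))
    expect_lt(abs(agg$rate[i] - lam), 3 * se + 1e-9)
  }
})

test_that("simulation_config rejects non-physical parameters", {
  expect_error(simulation_config(particle_contrast = -0.1), "positive")
  expect_error(simulation_config(permanent_fraction = 1.5), "0, 1")
  expect_error(simulation_config(mean_dwell_time = 0), "positive")
  expect_equal(simulation_config()$scaling_exponent, 2 / 3)
})
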