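#' Simulation configuration
#'
#' Parameters of the synthetic scene generator. The generator draws
#' binding-event streams as a homogeneous Poisson process whose rate scales
#' with volumetric target concentration as `c^(2/3)` (the diffusion-limited
#' sheet-density regime that holds at low concentration), assigns each event
#' an exponential dwell time with a configurable permanently-bound fraction,
#' and renders the events as diffraction-limited Gaussian intensity bumps on
#' a uniform background with per-pixel Gaussian shot noise.
#'
#' @param image_shape integer length-2, frame size in pixels (rows, cols).
#' @param pixel_pitch physical pixel size, micrometres per pixel.
#' @param frame_interval time between frames, seconds (kinetic mode).
#' @param z_step focus step between frames, micrometres (endpoint mode).
#' @param n_z number of focus positions in a rendered z-stack.
#' @param defocus_period,defocus_width micrometres; period and Gaussian
#'   envelope width of the defocus contrast curve
#'   `a(z) = particle_contrast * sin(2*pi*z/period) * exp(-z^2/(2*width^2))`.
#' @param psf_sigma standard deviation of the rendered particle image, pixels.
#' @param particle_contrast peak particle amplitude relative to a background
#'   level of 1.0 (dimensionless).
#' @param background_level mean background grayscale level.
#' @param shot_noise_scale per-pixel Gaussian noise SD as a fraction of the
#'   background level.
#' @param rate_constant binding events per hour per spot at the reference
#'   concentration `c_ref`.
#' @param c_ref reference concentration, molar. Fixed at 1 fM by default so
#'   rate constants are human-scale numbers.
#' @param scaling_exponent exponent of the rate law
#'   `lambda(c) = rate_constant * (c / c_ref)^scaling_exponent`; the
#'   diffusion-limited theoretical value is 2/3.
#' @param mean_dwell_time mean dwell time of transient binders, seconds.
#' @param permanent_fraction probability that an event never debinds.
#' @param nonspecific_rate events per hour per spot on blank (no-target)
#'   spots, independent of concentration.
#' @param duration movie duration, seconds.
#' @param concentrations default calibration grid, molar. The default spans
#'   100 aM to 1 pM in decade steps.
#' @param flow_rate_ul_min sample flow rate, microlitres per minute. Recorded
#'   as metadata only; transport physics is not simulated.
#' @param rng_seed optional integer seed applied by pipeline-level drivers.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(image_shape = c(128L, 128L),
                              pixel_pitch = 0.5,
                              frame_interval = 10,
                              z_step = 0.25,
                              n_z = 17L,
                              defocus_period = 4,
                              defocus_width = 1.5,
                              psf_sigma = 1.5,
                              particle_contrast = 0.1,
                              background_level = 1.0,
                              shot_noise_scale = 0.01,
                              rate_constant = 50,
                              c_ref = 1e-15,
                              scaling_exponent = 2 / 3,
                              mean_dwell_time = 600,
                              permanent_fraction = 0.1,
                              nonspecific_rate = 1,
                              duration = 2100,
                              concentrations = 10^seq(-16, -12),
                              flow_rate_ul_min = 5,
                              rng_seed = NULL) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_pitch = pixel_pitch,
    frame_interval = frame_interval,
    z_step = z_step,
    n_z = as.integer(n_z),
    defocus_period = defocus_period,
    defocus_width = defocus_width,
    psf_sigma = psf_sigma,
    particle_contrast = particle_contrast,
    background_level = background_level,
    shot_noise_scale = shot_noise_scale,
    rate_constant = rate_constant,
    c_ref = c_ref,
    scaling_exponent = scaling_exponent,
    mean_dwell_time = mean_dwell_time,
    permanent_fraction = permanent_fraction,
    nonspecific_rate = nonspecific_rate,
    duration = duration,
    concentrations = concentrations,
    flow_rate_ul_min = flow_rate_ul_min,
    rng_seed = rng_seed
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  pos <- c("pixel_pitch", "frame_interval", "z_step", "defocus_period",
           "defocus_width", "psf_sigma", "particle_contrast",
           "background_level", "rate_constant", "c_ref", "scaling_exponent",
           "mean_dwell_time", "duration")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("simulation_config: '", f, "' must be a single positive number")
    }
  }
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L)) {
    stop("simulation_config: image_shape must be two integers >= 8")
  }
  if (cfg$shot_noise_scale < 0) {
    stop("simulation_config: shot_noise_scale must be >= 0")
  }
  if (cfg$nonspecific_rate < 0) {
    stop("simulation_config: nonspecific_rate must be >= 0")
  }
  if (cfg$permanent_fraction < 0 || cfg$permanent_fraction > 1) {
    stop("simulation_config: permanent_fraction must lie in [0, 1]")
  }
  if (cfg$n_z < 3L) stop("simulation_config: n_z must be >= 3")
  if (any(cfg$concentrations < 0)) {
    stop("simulation_config: concentrations must be non-negative")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation_config: %dx%d px @ %g um/px\n",
    "  rate law: %g events/h/spot at c_ref = %s, exponent %.4g\n",
    "  dwell: exp(mean %g s), permanent fraction %g; duration %g s\n"),
    x$image_shape[1L], x$image_shape[2L], x$pixel_pitch,
    x$rate_constant, format_molarity(x$c_ref), x$scaling_exponent,
    x$mean_dwell_time, x$permanent_fraction, x$duration))
  invisible(x)
}

#' Circular spot region in pixel coordinates
#'
#' @param x,y centre, pixels (0-based, pixel-centre convention).
#' @param radius radius in pixels.
#' @param spot_id identifier carried into the events it owns.
#' @return An object of class `spot_region`.
#' @export
spot_region <- function(x, y, radius, spot_id = "S01") {
  stopifnot(radius > 0)
  structure(list(x = x, y = y, radius = radius, spot_id = as.character(spot_id)),
            class = "spot_region")
}

#' Sample a ground-truth binding/debinding event stream for one spot
#'
#' Arrival times follow a homogeneous Poisson process with rate
#' `lambda(c) = rate_constant * (c / c_ref)^scaling_exponent` events per
#' hour over `config$duration`. Each event is permanently bound with
#' probability `permanent_fraction`, otherwise its dwell time is
#' exponential with mean `mean_dwell_time`. Positions are uniform within
#' the spot disc. Uses the ambient RNG stream; seed with [set.seed()] (or a
#' pipeline driver) for reproducibility.
#'
#' @param config a [simulation_config()].
#' @param spot a [spot_region()].
#' @param concentration molar target concentration (>= 0).
#' @param rate_per_hour optional explicit event rate overriding the rate
#'   law, events per hour (used for nonspecific/blank streams).
#' @return data frame with columns `event_id`, `spot_id`, `x`, `y`,
#'   `t_bind`, `t_unbind` (seconds; `Inf` when permanently bound).
#' @export
sample_events <- function(config, spot, concentration, rate_per_hour = NULL) {
  stopifnot(inherits(config, "simulation_config"), inherits(spot, "spot_region"))
  if (is.null(rate_per_hour)) {
    if (!is.numeric(concentration) || length(concentration) != 1L ||
        is.na(concentration) || concentration < 0) {
      stop("concentration must be a single non-negative molar value")
    }
    rate_per_hour <- binding_rate_law(config, concentration)
  }
  lambda <- rate_per_hour * config$duration / 3600
  n <- stats::rpois(1L, lambda)
  if (n == 0L) {
    return(data.frame(event_id = integer(), spot_id = character(),
                      x = numeric(), y = numeric(),
                      t_bind = numeric(), t_unbind = numeric()))
  }
  t_bind <- sort(stats::runif(n, 0, config$duration))
  perm <- stats::runif(n) < config$permanent_fraction
  dwell <- stats::rexp(n, rate = 1 / config$mean_dwell_time)
  t_unbind <- ifelse(perm, Inf, t_bind + dwell)
  r <- spot$radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(
    event_id = seq_len(n),
    spot_id = spot$spot_id,
    x = spot$x + r * cos(th),
    y = spot$y + r * sin(th),
    t_bind = t_bind,
    t_unbind = t_unbind
  )
}

#' Event rate implied by the concentration scaling law
#'
#' @param config a [simulation_config()].
#' @param concentration molar.
#' @return events per hour per spot.
#' @export
binding_rate_law <- function(config, concentration) {
  config$rate_constant * (concentration / config$c_ref)^config$scaling_exponent
}

# Add an isotropic Gaussian bump (amplitude `amp`, sd `sigma` px) centred at
# 0-based pixel coordinates (x, y); only a +-4 sigma window is touched.
add_bump <- function(frame, x, y, amp, sigma) {
  nr <- nrow(frame); nc <- ncol(frame)
  half <- ceiling(4 * sigma)
  r0 <- max(1L, floor(y + 1 - half)); r1 <- min(nr, ceiling(y + 1 + half))
  c0 <- max(1L, floor(x + 1 - half)); c1 <- min(nc, ceiling(x + 1 + half))
  if (r0 > r1 || c0 > c1) return(frame)
  ry <- (r0:r1) - 1; cx <- (c0:c1) - 1
  gy <- exp(-((ry - y)^2) / (2 * sigma^2))
  gx <- exp(-((cx - x)^2) / (2 * sigma^2))
  frame[r0:r1, c0:c1] <- frame[r0:r1, c0:c1] + amp * outer(gy, gx)
  frame
}

#' Render a ground-truth event stream as a time-lapse movie
#'
#' Frame `n` images the scene at `t = n * frame_interval` (n = 0, 1, ...):
#' every event with `t_bind <= t < t_unbind` contributes an isotropic
#' Gaussian bump of amplitude `particle_contrast * background_level` and sd
#' `psf_sigma`, added to the uniform background; i.i.d. Gaussian noise of sd
#' `shot_noise_scale * background_level` is added per pixel. An empty event
#' list yields a blank movie.
#'
#' @param config a [simulation_config()].
#' @param events data frame as returned by [sample_events()].
#' @param noise logical; set `FALSE` for a noiseless render.
#' @return A [frame_stack()] with a time axis.
#' @export
render_timelapse <- function(config, events, noise = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  nf <- max(1L, floor(config$duration / config$frame_interval))
  times <- (seq_len(nf) - 1) * config$frame_interval
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
  bg <- config$background_level
  amp <- config$particle_contrast * bg
  frames <- array(bg, dim = c(nr, nc, nf))
  if (nrow(events) > 0L) {
    if (any(events$x < 0 | events$x > nc - 1 | events$y < 0 | events$y > nr - 1)) {
      stop("events fall outside the image bounds")
    }
    for (i in seq_len(nf)) {
      live <- which(events$t_bind <= times[i] & times[i] < events$t_unbind)
      f <- frames[, , i]
      for (j in live) {
        f <- add_bump(f, events$x[j], events$y[j], amp, config$psf_sigma)
      }
      frames[, , i] <- f
    }
  }
  if (noise && config$shot_noise_scale > 0) {
    frames <- frames + stats::rnorm(length(frames),
                                    sd = config$shot_noise_scale * bg)
  }
  frame_stack(frames, axis_kind = "time", axis_values = times,
              pixel_pitch = config$pixel_pitch)
}

#' Defocus contrast curve
#'
#' Relative particle amplitude as a function of defocus `z` (micrometres
#' from best focus): `particle_contrast * sin(2*pi*z/period) *
#' exp(-z^2 / (2*width^2))`. The curve is odd in `z`, so the interferometric
#' signature flips sign through focus and the per-pixel max-min across a
#' z-stack is large at particle sites.
#'
#' @param config a [simulation_config()].
#' @param z numeric vector of defocus values, micrometres.
#' @return numeric vector of amplitudes (relative to background level 1.0).
#' @export
defocus_amplitude <- function(config, z) {
  config$particle_contrast * sin(2 * pi * z / config$defocus_period) *
    exp(-z^2 / (2 * config$defocus_width^2))
}

#' Render immobilized particles as a focus series (z-stack)
#'
#' The stack holds `n_z` frames at focus positions symmetric about best
#' focus in steps of `z_step`; each particle's bump amplitude follows
#' [defocus_amplitude()] times the background level.
#'
#' @param config a [simulation_config()].
#' @param particles data frame (or 2-column matrix) with `x`, `y` pixel
#'   coordinates; zero rows give a blank stack.
#' @param noise logical; set `FALSE` for a noiseless render.
#' @return A [frame_stack()] with a z axis.
#' @export
render_zstack <- function(config, particles, noise = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  particles <- as.data.frame(particles)
  if (nrow(particles) > 0L) {
    if (is.null(particles$x)) names(particles)[1:2] <- c("x", "y")
  }
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
  if (nrow(particles) > 0L &&
      any(particles$x < 0 | particles$x > nc - 1 |
          particles$y < 0 | particles$y > nr - 1)) {
    stop("particles fall outside the image bounds")
  }
  nz <- config$n_z
  z <- (seq_len(nz) - (nz + 1) / 2) * config$z_step
  bg <- config$background_level
  a <- defocus_amplitude(config, z) * bg
  frames <- array(bg, dim = c(nr, nc, nz))
  for (i in seq_len(nz)) {
    f <- frames[, , i]
    for (j in seq_len(nrow(particles))) {
      f <- add_bump(f, particles$x[j], particles$y[j], a[i], config$psf_sigma)
    }
    frames[, , i] <- f
  }
  if (noise && config$shot_noise_scale > 0) {
    frames <- frames + stats::rnorm(length(frames),
                                    sd = config$shot_noise_scale * bg)
  }
  frame_stack(frames, axis_kind = "z", axis_values = z,
              pixel_pitch = config$pixel_pitch)
}

#' Generate a kinetic calibration data set at the event level
#'
#' For each concentration and replicate, draws a binding-event stream from
#' the configured rate law, forms the cumulative binding curve on the frame
#' grid, and extracts a binding rate by least squares ([estimate_rate()]).
#' Blank replicates are drawn at the configured `nonspecific_rate`
#' (concentration-independent). The rendering and detection stages are
#' bypassed, making this the fast ground-truth route for calibration
#' studies; run the imaging pipeline for end-to-end validation.
#'
#' @param config a [simulation_config()].
#' @param concentrations molar grid; defaults to `config$concentrations`.
#' @param replicates replicates per concentration.
#' @param blank_replicates number of blank (no-target) replicates.
#' @param seed optional integer seed.
#' @return An object of class `calibration_set`: list with `points`
#'   (data frame: concentration, replicate, n_events, rate, rate_se),
#'   `blanks` (same columns, concentration 0), `blank_stats`
#'   ([blank_stats()]), and `truth` (the generating rate law).
#' @export
make_calibration_dataset <- function(config,
                                     concentrations = NULL,
                                     replicates = 8L,
                                     blank_replicates = 3L,
                                     seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(concentrations)) concentrations <- config$concentrations
  if (length(concentrations) < 2L) {
    stop("need at least two concentrations plus blanks")
  }
  if (!is.null(seed)) set.seed(seed)
  spot <- spot_region(config$image_shape[2L] / 2, config$image_shape[1L] / 2,
                      radius = 0.4 * min(config$image_shape))
  times <- (seq_len(max(1L, floor(config$duration / config$frame_interval))) - 1) *
    config$frame_interval
  one <- function(conc, rep_i, rate = NULL) {
    ev <- sample_events(config, spot, conc, rate_per_hour = rate)
    counts <- vapply(times, function(t) sum(ev$t_bind <= t), numeric(1L))
    r <- estimate_rate(times, counts)
    data.frame(concentration = conc, replicate = rep_i,
               n_events = nrow(ev), rate = r$rate, rate_se = r$rate_se)
  }
  points <- do.call(rbind, lapply(concentrations, function(conc) {
    do.call(rbind, lapply(seq_len(replicates), function(i) one(conc, i)))
  }))
  blanks <- do.call(rbind, lapply(seq_len(blank_replicates), function(i) {
    one(0, i, rate = config$nonspecific_rate)
  }))
  structure(
    list(points = points, blanks = blanks,
         blank_stats = blank_stats(blanks$rate),
         truth = list(rate_constant = config$rate_constant,
                      c_ref = config$c_ref,
                      scaling_exponent = config$scaling_exponent,
                      nonspecific_rate = config$nonspecific_rate)),
    class = "calibration_set"
  )
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("calibration_set: %d concentrations x %d replicates, %d blanks\n",
              length(unique(x$points$concentration)),
              max(x$points$replicate), nrow(x$blanks)))
  invisible(x)
}
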