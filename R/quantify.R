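# Muffle lm's "essentially perfect fit" warning, which is routine for
# model-exact synthetic inputs.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Binding rate from a cumulative curve
#'
#' Ordinary least-squares slope of cumulative binding count versus time
#' (converted to hours), with its standard error. Because cumulative
#' counts are non-decreasing the estimated rate is never negative.
#'
#' @param time time points, seconds.
#' @param count cumulative binding counts at `time`.
#' @param window optional numeric length-2 `(t0, t1)` in seconds
#'   restricting the fit; default uses all points after `burn_in`.
#' @param burn_in seconds discarded from the start of the curve.
#' @return list of class `binding_rate`: `rate` (events/hour), `rate_se`,
#'   `window` (seconds actually used), `n` points.
#' @export
estimate_rate <- function(time, count, window = NULL, burn_in = 0) {
  stopifnot(length(time) == length(count))
  keep <- time >= burn_in
  if (!is.null(window)) keep <- keep & time >= window[1L] & time <= window[2L]
  t <- time[keep]; y <- count[keep]
  if (length(t) < 3L) stop("need at least 3 time points in the fit window")
  th <- t / 3600
  fit <- stats::lm(y ~ th)
  se <- quiet_perfect_fit(summary(fit)$coefficients["th", "Std. Error"])
  structure(list(rate = unname(stats::coef(fit)["th"]),
                 rate_se = unname(se),
                 window = range(t), n = length(t)),
            class = "binding_rate")
}

#' Blank statistics
#'
#' Mean and standard deviation of blank measurements (buffer-only chips or
#' non-complementary control spots), the basis of detection thresholds.
#'
#' @param values blank responses (rates in events/hour, or endpoint
#'   counts); at least 2 for a standard deviation.
#' @return list of class `blank_stats`: `mean`, `sd`, `n`.
#' @export
blank_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 blank replicates")
  structure(list(mean = mean(values), sd = stats::sd(values),
                 n = length(values)),
            class = "blank_stats")
}

#' Power-law calibration fit on double-logarithmic axes
#'
#' Fits `log10(response) = intercept + slope * log10(concentration)` by
#' ordinary least squares (the free fit), and additionally the
#' theoretical-slope line with the slope fixed at 2/3 (intercept by least
#' squares), which is the diffusion-limited expectation for kinetic
#' binding rates at low concentration. Non-positive responses cannot be
#' log-transformed and are excluded with a warning; nothing is ever added
#' to the data silently.
#'
#' @param concentration molar values (> 0).
#' @param response endpoint counts or binding rates (events/hour).
#' @param theoretical_slope slope of the constrained line; default 2/3.
#' @param conf confidence level for the slope interval.
#' @return object of class `calibration_fit`: `slope`, `intercept`,
#'   `slope_ci`, `theoretical_slope`, `theoretical_intercept`, `points`
#'   (data frame `log10_c`, `log10_r`), `n_dropped`.
#' @export
fit_calibration <- function(concentration, response,
                            theoretical_slope = 2 / 3, conf = 0.95) {
  stopifnot(length(concentration) == length(response))
  ok <- is.finite(concentration) & is.finite(response) &
    concentration > 0 & response > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warning(n_dropped, " point(s) with non-positive response/concentration ",
            "excluded from the log-log fit")
  }
  x <- log10(concentration[ok]); y <- log10(response[ok])
  if (length(x) < 2L) stop("need at least 2 positive points for a log-log fit")
  fit <- stats::lm(y ~ x)
  ci <- if (length(x) > 2L) {
    quiet_perfect_fit(stats::confint(fit, "x", level = conf))
  } else {
    matrix(c(NA_real_, NA_real_), 1L)
  }
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 slope_ci = unname(ci[1L, ]),
                 theoretical_slope = theoretical_slope,
                 theoretical_intercept = mean(y - theoretical_slope * x),
                 points = data.frame(log10_c = x, log10_r = y),
                 conf = conf,
                 n_dropped = n_dropped),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(paste0("calibration_fit: slope %.4f (CI %.4f..%.4f), ",
                     "intercept %.4f; slope-%.3g line intercept %.4f\n"),
              x$slope, x$slope_ci[1L], x$slope_ci[2L], x$intercept,
              x$theoretical_slope, x$theoretical_intercept))
  invisible(x)
}

#' Endpoint limit of detection: 3.3 sigma / slope
#'
#' The classical endpoint LOD, `3.3 * sd(blank) / slope`, with the slope
#' expressed on the linear response scale (counts per molar). Since the
#' calibration is a power law, the linear slope is taken as the local
#' derivative `a * b * c^(b-1)` of the fitted response `a * c^b` at the
#' lowest fitted concentration (`method = "local_derivative"`, default), or
#' from a straight-line fit of response against concentration
#' (`method = "global_linear"`).
#'
#' @param blank a [blank_stats()] of blank endpoint counts.
#' @param fit a [fit_calibration()] of endpoint counts against molarity.
#' @param method slope convention, see above.
#' @return object of class `lod_estimate` with `lod` (molar), `method`,
#'   `interval` (`NA` for the endpoint form), `extrapolated`.
#' @export
lod_endpoint <- function(blank, fit, method = c("local_derivative",
                                                "global_linear")) {
  method <- match.arg(method)
  stopifnot(inherits(blank, "blank_stats"), inherits(fit, "calibration_fit"))
  if (method == "local_derivative") {
    a <- 10^fit$intercept
    b <- fit$slope
    c_min <- 10^min(fit$points$log10_c)
    slope_lin <- a * b * c_min^(b - 1)
  } else {
    conc <- 10^fit$points$log10_c
    resp <- 10^fit$points$log10_r
    slope_lin <- unname(stats::coef(stats::lm(resp ~ conc))["conc"])
  }
  if (!is.finite(slope_lin) || slope_lin <= 0) {
    stop("calibration slope is not positive: no sensitivity")
  }
  lod <- 3.3 * blank$sd / slope_lin
  structure(list(lod = lod, method = paste0("endpoint_3.3sigma_", method),
                 interval = c(NA_real_, NA_real_),
                 threshold = NA_real_,
                 extrapolated = lod < 10^min(fit$points$log10_c)),
            class = "lod_estimate")
}

#' Kinetic limit of detection: threshold crossing of the c^(2/3) trend
#'
#' Computes the concentration at which the theoretical-slope (2/3) line
#' through the double-log calibration points crosses the decision
#' threshold `mean(blank) + 3 * sd(blank)` (rates in events/hour). An
#' interval accompanies the estimate: the lower bound is the crossing of
#' the free best-fit line, the upper bound the crossing of the steepest
#' plausible line - operationalized as the upper end of the free slope's
#' confidence interval, pivoted through the centroid of the points.
#'
#' @param concentration molar values of the calibration points (> 0).
#' @param rate binding rates, events/hour.
#' @param blank a [blank_stats()] of blank rates.
#' @param floor minimum admissible threshold (events/hour) guarding the
#'   degenerate all-zero-blank case; the threshold used is
#'   `max(mean + 3 sd, floor)` and must be positive.
#' @param conf confidence level defining the steepest slope.
#' @return object of class `lod_estimate`: `lod` (molar), `interval`
#'   (lower, upper, molar), `threshold` (events/hour), `extrapolated`
#'   (`TRUE` when the LOD lies outside the fitted concentration range),
#'   plus the underlying `fit`.
#' @export
lod_kinetic <- function(concentration, rate, blank, floor = 0, conf = 0.95) {
  stopifnot(inherits(blank, "blank_stats"))
  threshold <- max(blank$mean + 3 * blank$sd, floor)
  if (!is.finite(threshold) || threshold <= 0) {
    stop("decision threshold is not positive; supply a positive floor ",
         "or non-degenerate blanks")
  }
  fit <- fit_calibration(concentration, rate, conf = conf)
  lt <- log10(threshold)
  # theoretical-slope crossing (the conservative estimate)
  lod <- 10^((lt - fit$theoretical_intercept) / fit$theoretical_slope)
  # free best fit crossing
  lower <- if (is.finite(fit$slope) && fit$slope > 0) {
    10^((lt - fit$intercept) / fit$slope)
  } else NA_real_
  # steepest-slope crossing: upper CI slope through the centroid
  xbar <- mean(fit$points$log10_c); ybar <- mean(fit$points$log10_r)
  s_up <- fit$slope_ci[2L]
  upper <- if (is.finite(s_up) && s_up > 0) {
    10^(xbar + (lt - ybar) / s_up)
  } else NA_real_
  rng <- range(10^fit$points$log10_c)
  structure(list(lod = lod, method = "kinetic_intersection",
                 interval = c(lower, upper), threshold = threshold,
                 extrapolated = lod < rng[1L] || lod > rng[2L],
                 fit = fit),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf("lod_estimate (%s): LOD = %s", x$method, format_molarity(x$lod)))
  if (all(is.finite(x$interval))) {
    cat(sprintf(" [%s, %s]", format_molarity(x$interval[1L]),
                format_molarity(x$interval[2L])))
  }
  if (isTRUE(x$extrapolated)) cat(" (extrapolated)")
  cat("\n")
  invisible(x)
}
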