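PIPELINE_VERSION <- "0.1.0"

RUN_CONFIG_FIELDS <- c("seed", "out_dir", "grid", "target_probe",
                       "concentrations", "simulator", "detection",
                       "tracking", "log_level")

#' Reproducible run configuration
#'
#' Bundles every knob of a simulate-detect-track-quantify run. The object
#' serializes losslessly to JSON ([write_run_config()] /
#' [read_run_config()]); unknown keys in a config file are rejected.
#'
#' @param seed integer seed applied to all randomness in the run.
#' @param out_dir output directory for run artifacts.
#' @param grid list of [build_grid()] arguments (probes, replicates,
#'   pitch_um, diameter_um). The default is a deliberately small array -
#'   three probes (target, off-target, non-complementary control) with two
#'   replicate spots each - so a full run stays desk-scale.
#' @param target_probe probe label receiving concentration-dependent
#'   binding; all spots additionally receive nonspecific events.
#' @param concentrations molar values (numeric, or SI strings such as
#'   `"100aM"`, `"1fM"`, `"1pM"`) - one movie is simulated per value.
#' @param simulator list of [simulation_config()] overrides.
#' @param detection list of [detection_params()] overrides.
#' @param tracking list of [tracking_params()] overrides.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       out_dir = tempfile("spiris_run_"),
                       grid = list(probes = c("target", "offtarget", "control"),
                                   replicates = 2L, pitch_um = 40,
                                   diameter_um = 24),
                       target_probe = NULL,
                       concentrations = c("100aM", "1fM"),
                       simulator = list(pixel_pitch = 1, frame_interval = 15,
                                        duration = 900),
                       detection = list(),
                       tracking = list(),
                       log_level = "info") {
  if (is.character(concentrations)) {
    concentrations <- parse_molarity(concentrations)
  }
  if (is.null(target_probe)) target_probe <- grid$probes[[1L]]
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, grid = grid,
              target_probe = target_probe, concentrations = concentrations,
              simulator = simulator, detection = detection,
              tracking = tracking, log_level = log_level)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_FIELDS)
  if (length(unknown) > 0L) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(RUN_CONFIG_FIELDS, names(cfg))
  if (length(missing) > 0L) {
    stop("missing run_config key(s): ", paste(missing, collapse = ", "))
  }
  if (!cfg$target_probe %in% cfg$grid$probes) {
    stop("target_probe must be one of the grid probes")
  }
  if (any(cfg$concentrations < 0)) stop("concentrations must be >= 0")
  invisible(cfg)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$grid <- as.list(x$grid)
  for (f in c("simulator", "detection", "tracking")) {
    x[[f]] <- as.list(x[[f]])
  }
  validate_run_config(x)
  do.call(run_config, x)
}

pipeline_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) {
    message("[spiris] ", sprintf(...))
  }
}

write_csv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spiris %s | config %s | seed %d",
                     prov$version, prov$config_hash, prov$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV artifact (skipping the provenance header)
#'
#' @param path CSV written by [run_pipeline()].
#' @return data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full simulate-detect-track-quantify pipeline
#'
#' For each configured concentration, simulates binding events on every
#' spot of the grid (rate-law events on the target probe's spots,
#' nonspecific events everywhere), renders one time-lapse movie of the
#' field of view, detects and links particles, assigns tracks to spots,
#' and accumulates per-probe binding curves. Target binding rates are then
#' fitted per concentration, blanked against the non-target spot rates,
#' and turned into a kinetic limit of detection when at least two positive
#' concentrations are available. All artifacts (TIFF movies, CSV tables,
#' JSON report) are written under `config$out_dir` and embed the config
#' hash and seed; identical config and seed reproduce identical outputs.
#'
#' Later stages can be re-run on the artifacts of earlier ones by passing a
#' subset of `stages`: a stage that is skipped is read back from
#' `config$out_dir` instead of recomputed.
#'
#' @param config a [run_config()].
#' @param stages character subset of `c("simulate", "detect", "track",
#'   "quantify")`; earlier stages not listed are loaded from disk.
#' @return invisibly, a list with `report` (also written as
#'   `report.json`; `NULL` unless quantify runs), `curves`, `rates`,
#'   `grid` and artifact `paths`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "detect", "track", "quantify")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- do.call(build_grid, config$grid)
  sim_args <- config$simulator
  # size the field of view to cover the grid with a margin
  margin <- grid$diameter_um
  pitch_px <- if (is.null(sim_args$pixel_pitch)) 0.5 else sim_args$pixel_pitch
  x_rng <- range(grid$spots$x_um) + c(-margin, margin)
  y_rng <- range(grid$spots$y_um) + c(-margin, margin)
  offset_um <- c(x_rng[1L], y_rng[1L])
  sim_args$image_shape <- c(ceiling(diff(y_rng) / pitch_px),
                            ceiling(diff(x_rng) / pitch_px))
  scfg <- do.call(simulation_config, sim_args)
  dpar <- do.call(detection_params, config$detection)
  tpar <- do.call(tracking_params, config$tracking)
  config_path <- file.path(config$out_dir, "config.json")
  write_run_config(config, config_path)
  prov <- list(version = PIPELINE_VERSION,
               config_hash = unname(tools::md5sum(config_path)),
               seed = config$seed)
  paths <- list(config = config_path)

  regions <- lapply(seq_len(nrow(grid$spots)), function(i) {
    s <- grid$spots[i, ]
    spot_region((s$x_um - offset_um[1L]) / scfg$pixel_pitch,
                (s$y_um - offset_um[2L]) / scfg$pixel_pitch,
                s$radius_um / scfg$pixel_pitch, s$spot_id)
  })
  target_ids <- grid$spots$spot_id[grid$spots$probe == config$target_probe]
  frame_times <- (seq_len(max(1L, floor(scfg$duration / scfg$frame_interval))) - 1) *
    scfg$frame_interval

  rates <- list(); curves <- list(); blank_rates <- numeric()
  for (ci in seq_along(config$concentrations)) {
    conc <- config$concentrations[ci]
    tag <- gsub(" ", "", format_molarity(conc))
    stack_path <- file.path(config$out_dir, sprintf("movie_%s.tif", tag))
    det_path <- file.path(config$out_dir, sprintf("detections_%s.csv", tag))
    trk_path <- file.path(config$out_dir, sprintf("tracks_%s.csv", tag))
    log_path <- file.path(config$out_dir, sprintf("eventlog_%s.csv", tag))
    if ("simulate" %in% stages) {
      pipeline_log(config, "simulating %s movie", tag)
      events <- do.call(rbind, lapply(regions, function(rg) {
        spec <- if (rg$spot_id %in% target_ids) {
          sample_events(scfg, rg, conc)
        } else NULL
        nonspec <- sample_events(scfg, rg, 0,
                                 rate_per_hour = scfg$nonspecific_rate)
        rbind(spec, nonspec)
      }))
      movie <- render_timelapse(scfg, events)
      write_stack(movie, stack_path)
      write_csv_prov(events, file.path(config$out_dir,
                                       sprintf("events_%s.csv", tag)), prov)
    }
    if (!any(c("detect", "track", "quantify") %in% stages)) next
    if ("detect" %in% stages) {
      if (!exists("movie", inherits = FALSE)) movie <- read_stack(stack_path)
      pipeline_log(config, "detecting (%d frames)", n_frames(movie))
      dets <- detect_stack(movie, params = dpar, mode = "kinetic")
      write_csv_prov(dets, det_path, prov)
    } else {
      dets <- read_pipeline_csv(det_path)
    }
    if (!any(c("track", "quantify") %in% stages)) next
    tracks <- link_tracks(dets, tpar)
    assignment <- assign_spots(tracks, grid, scfg$pixel_pitch, offset_um)
    elog <- cumulative_binding(tracks, frame_times, assignment,
                               spot_ids = grid$spots$spot_id)
    write_csv_prov(as.data.frame(tracks), trk_path, prov)
    write_csv_prov(elog$log, log_path, prov)
    pc <- per_probe_curves(elog, grid)
    pc$concentration <- conc
    curves[[ci]] <- pc
    # per-spot rates: target spots feed the calibration, all other spots
    # serve as the blank population
    for (sid in grid$spots$spot_id) {
      sub <- elog$log[elog$log$spot_id == sid, ]
      r <- estimate_rate(sub$time, sub$cumulative_count)
      if (sid %in% target_ids) {
        rates[[length(rates) + 1L]] <- data.frame(
          concentration = conc, spot_id = sid,
          probe = config$target_probe, rate = r$rate, rate_se = r$rate_se)
      } else {
        blank_rates <- c(blank_rates, r$rate)
      }
    }
    if (exists("movie", inherits = FALSE)) rm(movie)
  }
  if (!any(c("track", "quantify") %in% stages)) {
    return(invisible(list(report = NULL, curves = NULL, rates = NULL,
                          grid = grid, paths = paths)))
  }
  rates <- do.call(rbind, rates)
  curves <- do.call(rbind, curves)
  write_csv_prov(curves, file.path(config$out_dir, "curves.csv"), prov)
  write_csv_prov(rates, file.path(config$out_dir, "rates.csv"), prov)
  if (!"quantify" %in% stages) {
    return(invisible(list(report = NULL, curves = curves, rates = rates,
                          grid = grid, paths = paths)))
  }
  mean_rates <- stats::aggregate(rate ~ concentration, rates, mean)
  report <- list(provenance = prov,
                 concentrations = config$concentrations,
                 mean_target_rates = mean_rates$rate,
                 blank = NULL, lod = NULL)
  if (length(blank_rates) >= 2L) {
    bs <- blank_stats(blank_rates)
    report$blank <- list(mean = bs$mean, sd = bs$sd, n = bs$n)
    pos <- mean_rates$rate > 0
    if (sum(pos) >= 2L) {
      lod <- tryCatch(
        lod_kinetic(mean_rates$concentration[pos], mean_rates$rate[pos], bs),
        error = function(e) NULL)
      if (!is.null(lod)) {
        report$lod <- list(lod_molar = lod$lod,
                           interval_molar = lod$interval,
                           threshold_per_hour = lod$threshold,
                           extrapolated = lod$extrapolated)
      }
    }
  }
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths$report <- report_path
  pipeline_log(config, "report written to %s", report_path)
  invisible(list(report = report, curves = curves, rates = rates,
                 grid = grid, paths = paths))
}
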