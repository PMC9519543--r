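#' Build a microarray spot grid
#'
#' Lays out replicate probe spots on a regular rectangular lattice with the
#' given centre-to-centre pitch. Each probe occupies a contiguous row-major
#' block of `replicates` spots (`block_cols` columns wide); probe blocks
#' are stacked vertically in the order given. The defaults mirror a
#' spotter layout of sixteen replicate spots per probe at 200 um pitch.
#'
#' @param probes character vector of probe labels (e.g. target, off-target
#'   and non-complementary control sequences).
#' @param replicates spots per probe.
#' @param pitch_um centre-to-centre spacing, micrometres; must exceed the
#'   spot diameter so discs never overlap.
#' @param diameter_um spot diameter, micrometres (printed spots of 65, 90
#'   or 130 um are typical).
#' @param block_cols columns per probe block; default `ceiling(sqrt(replicates))`.
#' @param origin numeric length-2, centre of the first spot in micrometres.
#' @return An object of class `spot_grid`: list with `spots` (data frame
#'   `spot_id`, `x_um`, `y_um`, `radius_um`, `probe`), `pitch_um`,
#'   `diameter_um`.
#' @export
build_grid <- function(probes, replicates = 16L, pitch_um = 200,
                       diameter_um = 90, block_cols = NULL,
                       origin = c(0, 0)) {
  probes <- as.character(probes)
  stopifnot(length(probes) >= 1L, replicates >= 1L, pitch_um > 0,
            diameter_um > 0)
  if (pitch_um <= diameter_um) {
    stop("pitch must exceed the spot diameter (non-overlapping discs)")
  }
  if (is.null(block_cols)) block_cols <- ceiling(sqrt(replicates))
  block_rows <- ceiling(replicates / block_cols)
  rows <- list()
  row_offset <- 0L
  sid <- 0L
  for (p in probes) {
    for (i in seq_len(replicates)) {
      r <- (i - 1L) %/% block_cols
      cc <- (i - 1L) %% block_cols
      sid <- sid + 1L
      rows[[sid]] <- data.frame(
        spot_id = sprintf("S%03d", sid),
        x_um = origin[1L] + cc * pitch_um,
        y_um = origin[2L] + (row_offset + r) * pitch_um,
        radius_um = diameter_um / 2,
        probe = p
      )
    }
    row_offset <- row_offset + block_rows
  }
  spots <- do.call(rbind, rows)
  structure(list(spots = spots, pitch_um = pitch_um,
                 diameter_um = diameter_um),
            class = "spot_grid")
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d spots (%d probes), pitch %g um, diameter %g um\n",
              nrow(x$spots), length(unique(x$spots$probe)),
              x$pitch_um, x$diameter_um))
  invisible(x)
}

#' Serialize / read a spot grid as JSON
#'
#' The JSON round-trips the grid bit-exactly (numbers are written at full
#' precision).
#'
#' @param grid a [build_grid()] object.
#' @param path JSON file path.
#' @return `write_grid`: `path` invisibly; `read_grid`: a `spot_grid`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "spot_grid"))
  jsonlite::write_json(list(spots = grid$spots, pitch_um = grid$pitch_um,
                            diameter_um = grid$diameter_um),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spots <- as.data.frame(x$spots)
  for (cn in c("x_um", "y_um", "radius_um")) spots[[cn]] <- as.numeric(spots[[cn]])
  structure(list(spots = spots, pitch_um = as.numeric(x$pitch_um),
                 diameter_um = as.numeric(x$diameter_um)),
            class = "spot_grid")
}

#' Assign tracks to probe spots
#'
#' Converts track centroids from pixels to micrometres
#' (`um = px * pixel_pitch + offset`) and assigns each track to the spot
#' whose disc contains it, or to `"background"` when no disc does. Spot
#' discs never overlap, so the assignment is unique.
#'
#' @param tracks a `track_set` or its [as.data.frame.track_set()] summary.
#' @param grid a [build_grid()] object.
#' @param pixel_pitch micrometres per pixel.
#' @param offset_um numeric length-2 added after scaling, micrometres
#'   (position of pixel (0,0) in grid coordinates).
#' @return data frame `track_id`, `spot_id` (`"background"` for
#'   unassigned tracks).
#' @export
assign_spots <- function(tracks, grid, pixel_pitch, offset_um = c(0, 0)) {
  stopifnot(inherits(grid, "spot_grid"), pixel_pitch > 0)
  tab <- if (inherits(tracks, "track_set")) as.data.frame(tracks) else tracks
  if (nrow(tab) == 0L) {
    return(data.frame(track_id = integer(), spot_id = character()))
  }
  x_um <- tab$x * pixel_pitch + offset_um[1L]
  y_um <- tab$y * pixel_pitch + offset_um[2L]
  sp <- grid$spots
  spot_id <- vapply(seq_along(x_um), function(i) {
    d2 <- (sp$x_um - x_um[i])^2 + (sp$y_um - y_um[i])^2
    j <- which.min(d2)
    if (d2[j] <= sp$radius_um[j]^2) sp$spot_id[j] else "background"
  }, character(1L))
  data.frame(track_id = tab$track_id, spot_id = spot_id)
}

#' Aggregate replicate spot curves into per-probe curves
#'
#' Averages the cumulative binding curves of all replicate spots of each
#' probe pointwise in time and reports the across-replicate standard
#' deviation (`mode = "mean"`, the default, which keeps error bars and
#' blank statistics available), or sums them (`mode = "sum"`). Spots
#' without any event contribute flat zero curves.
#'
#' @param event_log an [cumulative_binding()] `event_log`.
#' @param grid a [build_grid()] object.
#' @param mode `"mean"` or `"sum"`.
#' @return data frame `probe`, `time`, `count` (mean or sum), `sd`
#'   (across replicates; `NA` under `"sum"`), `n_spots`.
#' @export
per_probe_curves <- function(event_log, grid, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(event_log, "event_log"), inherits(grid, "spot_grid"))
  times <- event_log$frame_times
  sp <- grid$spots
  out <- lapply(unique(sp$probe), function(p) {
    ids <- sp$spot_id[sp$probe == p]
    curves <- vapply(ids, function(s) {
      sub <- event_log$log[event_log$log$spot_id == s, , drop = FALSE]
      if (nrow(sub) == 0L) rep(0, length(times)) else sub$cumulative_count
    }, numeric(length(times)))
    curves <- matrix(curves, nrow = length(times))
    if (mode == "mean") {
      data.frame(probe = p, time = times,
                 count = rowMeans(curves),
                 sd = apply(curves, 1L, stats::sd),
                 n_spots = length(ids))
    } else {
      data.frame(probe = p, time = times,
                 count = rowSums(curves), sd = NA_real_,
                 n_spots = length(ids))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
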