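#' Tracking parameters
#'
#' @param association_radius maximum centroid displacement (pixels) for a
#'   detection to continue an existing track. Particles are immobile once
#'   bound, so this only absorbs localization jitter.
#' @param max_gap maximum number of consecutive missed frames that gap
#'   repair will bridge between two co-located track fragments. The default
#'   of 2 frames reflects a dwell-time prior: true binders persist for many
#'   frames, so short dropouts are detector false negatives.
#' @param min_duration minimum supported duration (frames) for a track to
#'   count as a binding event; the default of 2 removes single-frame
#'   positives.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(association_radius = 2.0,
                            max_gap = 2L,
                            min_duration = 2L) {
  stopifnot(association_radius > 0, max_gap >= 0, min_duration >= 1)
  structure(list(association_radius = association_radius,
                 max_gap = as.integer(max_gap),
                 min_duration = as.integer(min_duration)),
            class = "tracking_params")
}

new_track_set <- function(tracks) {
  structure(list(tracks = tracks), class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks\n", length(x$tracks)))
  invisible(x)
}

#' @export
length.track_set <- function(x) length(x$tracks)

#' Summarize a track set as a data frame
#'
#' @param x a `track_set` from [associate()], [repair_gaps()] or
#'   [remove_single_frame()].
#' @param row.names,optional,... ignored (base generic signature).
#' @return data frame: `track_id`, `x`, `y` (representative position, mean
#'   of supporting detections), `first_frame`, `last_frame`, `n_support`,
#'   `repaired_gaps`.
#' @export
as.data.frame.track_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (length(x$tracks) == 0L) {
    return(data.frame(track_id = integer(), x = numeric(), y = numeric(),
                      first_frame = integer(), last_frame = integer(),
                      n_support = integer(), repaired_gaps = integer()))
  }
  do.call(rbind, lapply(x$tracks, function(tr) {
    data.frame(track_id = tr$track_id, x = mean(tr$xs), y = mean(tr$ys),
               first_frame = min(tr$frames), last_frame = max(tr$frames),
               n_support = length(tr$frames),
               repaired_gaps = tr$repaired_gaps)
  }))
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour association: for every frame, candidate
#' (active track, detection) pairs within `association_radius` are matched
#' in order of increasing distance (ties broken by lowest track id);
#' unmatched detections open new tracks and unmatched active tracks end
#' immediately. Dropouts are handled afterwards by [repair_gaps()], so a
#' track's support is always a contiguous frame interval here.
#'
#' @param detections data frame from [detect_stack()] (kinetic mode):
#'   columns `frame_index`, `x`, `y`.
#' @param params a [tracking_params()].
#' @return A `track_set`.
#' @export
associate <- function(detections, params = tracking_params()) {
  stopifnot(inherits(params, "tracking_params"))
  if (nrow(detections) == 0L) return(new_track_set(list()))
  detections <- detections[order(detections$frame_index), , drop = FALSE]
  frames <- min(detections$frame_index):max(detections$frame_index)
  tracks <- list()       # finished + active
  active <- integer()    # indices into `tracks`
  next_id <- 1L
  for (f in frames) {
    det <- detections[detections$frame_index == f, , drop = FALSE]
    nd <- nrow(det)
    matched_det <- rep(FALSE, nd)
    matched_trk <- rep(FALSE, length(active))
    if (nd > 0L && length(active) > 0L) {
      ax <- vapply(tracks[active], function(t) t$last_x, numeric(1L))
      ay <- vapply(tracks[active], function(t) t$last_y, numeric(1L))
      ids <- vapply(tracks[active], function(t) t$track_id, integer(1L))
      dist <- sqrt(outer(ax, det$x, "-")^2 + outer(ay, det$y, "-")^2)
      cand <- which(dist <= params$association_radius, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(dist[cand], ids[cand[, 1L]])
        for (k in ord) {
          ti <- cand[k, 1L]; di <- cand[k, 2L]
          if (matched_trk[ti] || matched_det[di]) next
          matched_trk[ti] <- TRUE
          matched_det[di] <- TRUE
          tr <- tracks[[active[ti]]]
          tr$frames <- c(tr$frames, f)
          tr$xs <- c(tr$xs, det$x[di]); tr$ys <- c(tr$ys, det$y[di])
          tr$last_x <- det$x[di]; tr$last_y <- det$y[di]
          tracks[[active[ti]]] <- tr
        }
      }
    }
    # unmatched active tracks end; unmatched detections open new tracks
    active <- active[matched_trk]
    for (di in which(!matched_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        track_id = next_id,
        frames = f, xs = det$x[di], ys = det$y[di],
        last_x = det$x[di], last_y = det$y[di],
        repaired_gaps = 0L)
      active <- c(active, length(tracks))
      next_id <- next_id + 1L
    }
  }
  new_track_set(tracks)
}

#' Repair dropout gaps between co-located track fragments
#'
#' Two tracks whose representative positions lie within
#' `association_radius` and whose temporal gap (frames missing between the
#' end of one and the start of the other) is at most `max_gap` are merged
#' into a single track; the missing frames are counted in
#' `repaired_gaps`. Merging repeats to a fixed point, so the operation is
#' idempotent. A reappearance after a gap longer than `max_gap` remains a
#' separate track - i.e. a new binding event.
#'
#' @param tracks a `track_set` from [associate()].
#' @param params a [tracking_params()].
#' @return A `track_set`.
#' @export
repair_gaps <- function(tracks, params = tracking_params()) {
  stopifnot(inherits(tracks, "track_set"), inherits(params, "tracking_params"))
  trs <- tracks$tracks
  repeat {
    n <- length(trs)
    if (n < 2L) break
    first <- vapply(trs, function(t) min(t$frames), numeric(1L))
    last <- vapply(trs, function(t) max(t$frames), numeric(1L))
    mx <- vapply(trs, function(t) mean(t$xs), numeric(1L))
    my <- vapply(trs, function(t) mean(t$ys), numeric(1L))
    merged <- FALSE
    ord <- order(first)
    for (a in ord) {
      gaps <- first - last[a] - 1
      d <- sqrt((mx - mx[a])^2 + (my - my[a])^2)
      cand <- which(gaps >= 0 & gaps <= params$max_gap &
                    d <= params$association_radius)
      cand <- setdiff(cand, a)
      if (length(cand) == 0L) next
      b <- cand[order(gaps[cand], d[cand])][1L]
      ta <- trs[[a]]; tb <- trs[[b]]
      ta$frames <- c(ta$frames, tb$frames)
      ta$xs <- c(ta$xs, tb$xs); ta$ys <- c(ta$ys, tb$ys)
      ta$last_x <- tb$last_x; ta$last_y <- tb$last_y
      ta$repaired_gaps <- ta$repaired_gaps + tb$repaired_gaps + as.integer(gaps[b])
      trs[[a]] <- ta
      trs[[b]] <- NULL
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  new_track_set(trs)
}

#' Remove single-frame (short-lived) artifact tracks
#'
#' Discards tracks whose supported duration (number of frames with a
#' detection) is below `min_duration`. With the default of 2 this removes
#' single-frame positives.
#'
#' @param tracks a `track_set`, normally after [repair_gaps()].
#' @param params a [tracking_params()].
#' @return A `track_set`.
#' @export
remove_single_frame <- function(tracks, params = tracking_params()) {
  stopifnot(inherits(tracks, "track_set"), inherits(params, "tracking_params"))
  keep <- vapply(tracks$tracks,
                 function(t) length(t$frames) >= params$min_duration,
                 logical(1L))
  new_track_set(tracks$tracks[keep])
}

#' Full linking pipeline: associate, repair gaps, drop artifacts
#'
#' @inheritParams associate
#' @return A `track_set` of surviving binding events.
#' @export
link_tracks <- function(detections, params = tracking_params()) {
  remove_single_frame(repair_gaps(associate(detections, params), params), params)
}

#' Cumulative binding-event log
#'
#' Each surviving track is one binding event contributing +1 to its spot's
#' cumulative count at the time of its first supporting frame. Debinding
#' never decrements the count (total-binding convention): a complex that
#' binds and later debinds is still counted, which is what makes the
#' kinetic read-out more sensitive than surface-bound particle counts.
#'
#' @param tracks a `track_set` of surviving tracks.
#' @param frame_times numeric vector mapping frame index 0, 1, ... to
#'   acquisition time (seconds).
#' @param assignment optional data frame (`track_id`, `spot_id`) from
#'   [assign_spots()]; tracks default to spot `"S01"`. Tracks assigned to
#'   `"background"` are logged under that label.
#' @param spot_ids spot identifiers to include in the log even when no
#'   track was assigned to them (their curves are zero).
#' @return An object of class `event_log`: list with `log` (data frame
#'   `spot_id`, `time`, `cumulative_count`, evaluated at every frame time)
#'   and `events` (data frame `track_id`, `spot_id`, `t_bind`, `t_end`;
#'   `t_end` is `NA` for tracks alive in the final frame).
#' @export
cumulative_binding <- function(tracks, frame_times, assignment = NULL,
                               spot_ids = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  tab <- as.data.frame(tracks)
  if (nrow(tab) > 0L && max(tab$last_frame) + 1L > length(frame_times)) {
    stop("frame_times shorter than the track frame range")
  }
  if (is.null(assignment)) {
    assignment <- data.frame(track_id = tab$track_id,
                             spot_id = rep("S01", nrow(tab)))
  }
  tab <- merge(tab, assignment, by = "track_id", all.x = TRUE)
  if (nrow(tab) > 0L && anyNA(tab$spot_id)) {
    stop("every track must be assigned to a spot or background")
  }
  if (is.null(spot_ids)) spot_ids <- sort(unique(tab$spot_id))
  if (length(spot_ids) == 0L) spot_ids <- "S01"
  last_time <- frame_times[length(frame_times)]
  events <- data.frame(
    track_id = tab$track_id,
    spot_id = if (nrow(tab)) tab$spot_id else character(),
    t_bind = frame_times[tab$first_frame + 1L],
    t_end = ifelse(tab$last_frame + 1L == length(frame_times), NA_real_,
                   frame_times[tab$last_frame + 1L])
  )
  log <- do.call(rbind, lapply(spot_ids, function(s) {
    tb <- sort(events$t_bind[events$spot_id == s])
    data.frame(spot_id = s, time = frame_times,
               cumulative_count = vapply(frame_times,
                                         function(t) sum(tb <= t), numeric(1L)))
  }))
  rownames(log) <- NULL
  structure(list(log = log, events = events, frame_times = frame_times),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("event_log: %d binding events on %d spot(s), %d time points\n",
              nrow(x$events), length(unique(x$log$spot_id)),
              length(x$frame_times)))
  invisible(x)
}
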