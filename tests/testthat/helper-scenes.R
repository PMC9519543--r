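# Shared fixtures: planted scenes, synthetic detection streams, and the
# independent interval-reconstruction oracle used to validate the tracker.

empty_events <- function() {
  data.frame(event_id = integer(), spot_id = character(),
             x = numeric(), y = numeric(),
             t_bind = numeric(), t_unbind = numeric())
}

# n particle positions on a jittered square grid with a border margin,
# guaranteeing a minimum pairwise separation.
planted_positions <- function(n, image_side, margin = 12, jitter = 2) {
  side <- ceiling(sqrt(n))
  g <- seq(margin, image_side - 1 - margin, length.out = side)
  pts <- expand.grid(x = g, y = g)[seq_len(n), ]
  pts$x <- pts$x + stats::runif(n, -jitter, jitter)
  pts$y <- pts$y + stats::runif(n, -jitter, jitter)
  pts
}

events_from_positions <- function(pts, t_bind, t_unbind = Inf, spot_id = "S01") {
  data.frame(event_id = seq_len(nrow(pts)), spot_id = spot_id,
             x = pts$x, y = pts$y, t_bind = t_bind, t_unbind = t_unbind)
}

# Detection stream for one immobile emitter: one detection per frame in
# `frames`, jittered by at most `jitter` around (x, y).
detections_at <- function(x, y, frames, jitter = 0) {
  n <- length(frames)
  data.frame(frame_index = as.integer(frames),
             x = x + stats::runif(n, -jitter, jitter),
             y = y + stats::runif(n, -jitter, jitter),
             score = 0.9, area = 9, perimeter = 8, ratio = 1.125)
}

# Brute-force reconstruction of binding events from a detection table,
# independent of the associate/repair/filter implementation: cluster
# detections by single-linkage distance <= radius, then per cluster split
# the sorted support frames wherever the dropout exceeds max_gap, and keep
# segments with at least min_duration supporting frames. Valid whenever
# distinct emitters are separated by more than the association radius.
oracle_events <- function(det, params) {
  if (nrow(det) == 0L) {
    return(list(count = 0L, first_frames = integer()))
  }
  d <- as.matrix(stats::dist(det[, c("x", "y")]))
  adj <- d <= params$association_radius
  comp <- rep(0L, nrow(det))
  cur <- 0L
  for (i in seq_len(nrow(det))) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[j, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  firsts <- integer()
  for (s in seq_len(cur)) {
    fr <- sort(unique(det$frame_index[comp == s]))
    seg_id <- cumsum(c(0L, as.integer(diff(fr) - 1L > params$max_gap)))
    for (seg in split(fr, seg_id)) {
      if (length(seg) >= params$min_duration) firsts <- c(firsts, seg[1L])
    }
  }
  list(count = length(firsts), first_frames = sort(firsts))
}

# Random tracking instance with <= max_det detections: well-separated
# sites (> 4 radius apart), 1-3 presence intervals per site with gaps on
# both sides of max_gap, localization jitter < radius/3, plus optional
# single-frame artifacts far from every site.
random_tracking_instance <- function(params, max_det = 20L) {
  r <- params$association_radius
  n_sites <- sample(1:4, 1L)
  centers <- data.frame(x = (seq_len(n_sites) - 1) * 6 * r + 10,
                        y = sample(seq(10, 50, by = 6 * r), n_sites,
                                   replace = TRUE))
  det <- NULL
  budget <- max_det
  for (i in seq_len(n_sites)) {
    f <- 0L
    for (k in seq_len(sample(1:3, 1L))) {
      len <- sample(1:4, 1L)
      if (budget - len < 0) break
      frames <- f + seq_len(len) - 1L
      det <- rbind(det, detections_at(centers$x[i], centers$y[i], frames,
                                      jitter = r / 3.01))
      budget <- budget - len
      f <- frames[length(frames)] + 1L + sample(1:(params$max_gap + 3L), 1L)
    }
  }
  if (budget > 0 && stats::runif(1) < 0.5) {
    det <- rbind(det, detections_at(200, 200, sample(0:10, 1L)))
  }
  det
}

# Build a track_set by pushing synthetic per-emitter detection streams
# through the associator (used where tests need an event_log input).
tracks_from_streams <- function(streams, params = tracking_params()) {
  link_tracks(do.call(rbind, streams), params)
}
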