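#' Detection parameters
#'
#' Tuning parameters of the particle-detection stage. Defaults were
#' calibrated once on the synthetic scene generator and frozen.
#'
#' @param psf_sigma expected particle image sd, pixels; sets the default
#'   correlation kernel and pseudomedian kernel sizes.
#' @param temporal_average_n frames per non-overlapping averaging block
#'   applied before kinetic detection (1 = off).
#' @param pseudomedian_kernel side of the background-smoothing pseudomedian
#'   window, pixels; odd, and slightly larger than the point spread
#'   function. Default: `ceil(3 * psf_sigma)` rounded up to odd.
#' @param global_threshold correlation-score threshold in (0, 1) used to
#'   binarize the zero-normalized cross-correlation map.
#' @param area_range keypoint blob area bounds, px^2 (inclusive).
#' @param ratio_range keypoint area-to-perimeter ratio bounds (inclusive);
#'   rejects elongated blobs, keeping diffraction-limited (round) spots.
#' @param smooth_background subtract the pseudomedian background estimate
#'   before correlation. Off by default: per-pixel median normalization
#'   already flattens fixed-pattern structure and the correlation score is
#'   locally zero-normalized, so subtraction only helps when large-scale
#'   background undulation survives normalization - enable it then and use
#'   a `pseudomedian_kernel` at least twice the particle footprint so the
#'   estimate does not absorb the particles themselves.
#' @param baseline kinetic per-pixel baseline: `"min"` (default, the
#'   minimum across frames - robust for binders that dwell for a large
#'   fraction of the movie, since one particle-free frame suffices; the
#'   small downward noise bias is a constant factor the correlation score
#'   is invariant to) or `"median"` (the z-median analogue; only valid
#'   when every pixel is particle-free more than half the time).
#' @param median_window odd window (frames) for a rolling temporal-median
#'   baseline in kinetic mode; `NULL` uses the global per-pixel median.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(psf_sigma = 1.5,
                             temporal_average_n = 1L,
                             pseudomedian_kernel = NULL,
                             global_threshold = 0.55,
                             area_range = c(5, 200),
                             ratio_range = c(1.05, 5),
                             smooth_background = FALSE,
                             baseline = c("min", "median"),
                             median_window = NULL) {
  baseline <- match.arg(baseline)
  if (is.null(pseudomedian_kernel)) {
    k <- ceiling(3 * psf_sigma)
    pseudomedian_kernel <- if (k %% 2 == 1) k else k + 1
  }
  pseudomedian_kernel <- as.integer(pseudomedian_kernel)
  if (pseudomedian_kernel < 3L || pseudomedian_kernel %% 2L == 0L) {
    stop("pseudomedian_kernel must be odd and >= 3")
  }
  if (!(global_threshold > 0 && global_threshold < 1)) {
    stop("global_threshold must lie in (0, 1)")
  }
  stopifnot(temporal_average_n >= 1L, length(area_range) == 2L,
            length(ratio_range) == 2L, area_range[1L] > 0)
  structure(list(psf_sigma = psf_sigma,
                 temporal_average_n = as.integer(temporal_average_n),
                 pseudomedian_kernel = pseudomedian_kernel,
                 global_threshold = global_threshold,
                 area_range = area_range,
                 ratio_range = ratio_range,
                 smooth_background = smooth_background,
                 baseline = baseline,
                 median_window = median_window),
            class = "detection_params")
}

#' Detection kernel (correlation template)
#'
#' A small odd-sized template image the detector cross-correlates against.
#' In production use this is a measured particle image; for synthetic work
#' [gaussian_kernel()] builds one from the expected point spread function.
#' The template is mean-centred and unit-normalized inside [correlate()],
#' so only its shape matters.
#'
#' @param template square numeric matrix with odd side length >= 3.
#' @param provenance `"measured"` or `"synthetic-gaussian"`.
#' @return An object of class `detection_kernel`.
#' @export
detection_kernel <- function(template, provenance = "measured") {
  template <- as.matrix(template)
  if (nrow(template) < 3L || nrow(template) %% 2L == 0L ||
      ncol(template) %% 2L == 0L) {
    stop("kernel template must have odd side length >= 3")
  }
  if (stats::sd(template) == 0) stop("kernel template is constant")
  structure(list(template = template, provenance = provenance),
            class = "detection_kernel")
}

#' @rdname detection_kernel
#' @param psf_sigma Gaussian sd in pixels.
#' @param size odd side length; default `2*ceil(3*psf_sigma) + 1`.
#' @export
gaussian_kernel <- function(psf_sigma, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(3 * psf_sigma) + 1L
  half <- (size - 1L) / 2L
  g <- exp(-((-half):half)^2 / (2 * psf_sigma^2))
  detection_kernel(outer(g, g), provenance = "synthetic-gaussian")
}

#' Block-average frames in time
#'
#' Averages non-overlapping blocks of `n` consecutive frames; an incomplete
#' tail block is dropped. On a static scene with i.i.d. noise this reduces
#' the noise sd by `1/sqrt(n)`. Axis values become block means.
#'
#' @param stack a [frame_stack()].
#' @param n block size; `1` is the identity.
#' @return A [frame_stack()] with `floor(n_frames / n)` frames.
#' @export
temporal_average <- function(stack, n) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- as.integer(n)
  nf <- n_frames(stack)
  if (n < 1L || n > nf) stop("n must be in 1..", nf)
  if (n == 1L) return(stack)
  nb <- nf %/% n
  d <- dim(stack$frames)
  flat <- matrix(stack$frames[, , seq_len(nb * n)], nrow = d[1L] * d[2L])
  out <- array(0, dim = c(d[1L], d[2L], nb))
  av <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * n + 1L):(b * n)
    out[, , b] <- rowMeans(flat[, idx, drop = FALSE])
    av[b] <- mean(stack$axis_values[idx])
  }
  frame_stack(out, axis_kind = stack$axis_kind, axis_values = av,
              pixel_pitch = stack$pixel_pitch)
}

# Pseudomedian of one clamped window: mean of the max and min of the
# per-row medians (the separable pseudomedian construction).
window_pseudomedian <- function(image, i, j, h) {
  ri <- max(1L, i - h):min(nrow(image), i + h)
  cj <- max(1L, j - h):min(ncol(image), j + h)
  rm <- apply(image[ri, cj, drop = FALSE], 1L, stats::median)
  (max(rm) + min(rm)) / 2
}

#' Sparse pseudomedian background estimate
#'
#' Separable pseudomedian (mean of max-of-row-medians and
#' min-of-row-medians over a `kernel_px` square window) evaluated on a
#' sparse grid with stride `kernel_px %/% 2` and bilinearly interpolated
#' back to full resolution. Structures smaller than the kernel - such as
#' diffraction-limited particles - are suppressed, so the result is a
#' smooth background estimate.
#'
#' @param image numeric matrix.
#' @param kernel_px odd window side >= 3, chosen slightly larger than the
#'   point spread function.
#' @param dense evaluate at every pixel instead of the sparse grid (slow;
#'   reference for validation).
#' @return numeric matrix, same shape as `image`.
#' @export
pseudomedian_smooth <- function(image, kernel_px, dense = FALSE) {
  image <- as.matrix(image)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px %% 2L == 0L || kernel_px < 3L) stop("kernel must be odd and >= 3")
  if (kernel_px > min(dim(image))) stop("kernel larger than image")
  h <- kernel_px %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  if (dense) {
    out <- image
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) out[i, j] <- window_pseudomedian(image, i, j, h)
    }
    return(out)
  }
  stride <- max(1L, h)
  gi <- unique(c(seq(1L, nr, by = stride), nr))
  gj <- unique(c(seq(1L, nc, by = stride), nc))
  grid <- matrix(0, length(gi), length(gj))
  for (a in seq_along(gi)) {
    for (b in seq_along(gj)) {
      grid[a, b] <- window_pseudomedian(image, gi[a], gj[b], h)
    }
  }
  if (length(gi) == 1L && length(gj) == 1L) {
    return(matrix(grid[1L, 1L], nr, nc))
  }
  xp <- rep(seq_len(nc), each = nr)
  yp <- rep(seq_len(nr), times = nc)
  vals <- pracma::interp2(x = gj, y = gi, Z = grid, xp = xp, yp = yp,
                          method = "linear")
  matrix(vals, nr, nc)
}

#' Normalize a stack by the per-pixel median across frames
#'
#' Divides every pixel time/z series by its own median, removing fixed-
#' pattern illumination and reflectivity structure; the median frame of the
#' output is 1.0 everywhere (exactly so for odd frame counts).
#'
#' @param stack a [frame_stack()] with >= 3 frames.
#' @return A normalized [frame_stack()].
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (n_frames(stack) < 3L) stop("need at least 3 frames to normalize")
  med <- pixel_median(stack$frames)
  if (any(med <= 0)) stop("per-pixel median <= 0: corrupt or non-intensity input")
  frames <- stack$frames / as.vector(med)
  frame_stack(frames, axis_kind = stack$axis_kind,
              axis_values = stack$axis_values, pixel_pitch = stack$pixel_pitch)
}

# Per-pixel median across the frame axis of a [row, col, frame] array.
pixel_median <- function(arr) {
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1L] * d[2L])
  matrix(row_medians(flat), d[1L], d[2L])
}

# Row medians without extra dependencies; sorts each row once.
row_medians <- function(m) {
  apply(m, 1L, stats::median)
}

#' Max-min differential image of a stack
#'
#' Per-pixel difference between the maximum and minimum value across
#' frames. On a normalized z-stack the defocus curve of each particle
#' swings its pixels above and below 1.0, so the differential image shows
#' particles as bright bumps on a near-zero background.
#'
#' @param stack a [frame_stack()] (normalize first with [normalize_stack()]).
#' @return numeric matrix, non-negative.
#' @export
differential_image <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, nrow = d[1L] * d[2L])
  rng <- row_range(flat)
  matrix(rng[, 2L] - rng[, 1L], d[1L], d[2L])
}

row_range <- function(m) {
  cbind(do.call(pmin, as.data.frame(m)), do.call(pmax, as.data.frame(m)))
}

#' Zero-normalized cross-correlation with a detection kernel
#'
#' Scores every pixel by the Pearson correlation between the kernel
#' template and the image patch centred there. Near the image border the
#' score is computed over the valid overlap only (both the patch and the
#' kernel restricted to in-bounds offsets). Scores lie in \\[-1, 1\\];
#' patches with (numerically) zero variance score 0. Computed with
#' zero-padded FFTs, which reproduce the direct windowed sums exactly up
#' to floating-point rounding.
#'
#' @param image numeric matrix, or a `[row, col, frame]` array / `frame_stack`
#'   to score every frame at once.
#' @param kernel a [detection_kernel()].
#' @return score map with the same spatial shape as the input.
#' @export
correlate <- function(image, kernel) {
  stopifnot(inherits(kernel, "detection_kernel"))
  arr <- if (inherits(image, "frame_stack")) image$frames else image
  if (length(dim(arr)) == 2L || is.null(dim(arr))) {
    arr <- array(as.matrix(arr), dim = c(dim(as.matrix(arr)), 1L))
    squeeze <- TRUE
  } else squeeze <- FALSE
  k <- kernel$template
  kh <- (nrow(k) - 1L) %/% 2L
  kw <- (ncol(k) - 1L) %/% 2L
  d <- dim(arr)
  nr <- d[1L]; nc <- d[2L]; nf <- d[3L]
  if (nrow(k) > nr || ncol(k) > nc) stop("kernel larger than image")
  P <- nr + 2L * kh; Q <- nc + 2L * kw
  ri <- (kh + 1L):(kh + nr); cj <- (kw + 1L):(kw + nc)
  fpad <- function(m, rows, cols) {
    z <- matrix(0, P, Q)
    z[rows, cols] <- m
    stats::fft(z)
  }
  xcorr <- function(fa, fb_conj) {
    Re(stats::fft(fa * fb_conj, inverse = TRUE))[seq_len(nr), seq_len(nc)] / (P * Q)
  }
  f_k <- Conj(fpad(k, seq_len(nrow(k)), seq_len(ncol(k))))
  f_k2 <- Conj(fpad(k^2, seq_len(nrow(k)), seq_len(ncol(k))))
  f_1 <- Conj(fpad(matrix(1, nrow(k), ncol(k)), seq_len(nrow(k)), seq_len(ncol(k))))
  # frame-independent border terms from the validity mask
  f_mask <- fpad(matrix(1, nr, nc), ri, cj)
  N <- xcorr(f_mask, f_1)
  SK <- xcorr(f_mask, f_k)
  SK2 <- xcorr(f_mask, f_k2)
  vark <- pmax(SK2 - SK * SK / N, 0)
  score <- array(0, dim = d)
  for (f in seq_len(nf)) {
    img <- arr[, , f]
    f_img <- fpad(img, ri, cj)
    f_img2 <- fpad(img * img, ri, cj)
    SPK <- xcorr(f_img, f_k)
    S1 <- xcorr(f_img, f_1)
    S2 <- xcorr(f_img2, f_1)
    num <- SPK - S1 * SK / N
    varp <- pmax(S2 - S1 * S1 / N, 0)
    den <- sqrt(varp * vark)
    sc <- ifelse(den > 1e-12, num / den, 0)
    score[, , f] <- pmin(pmax(sc, -1), 1)
  }
  if (squeeze) score <- score[, , 1L]
  score
}

# Direct tap-loop ZNCC; O(kernel_area) passes over the stack. Retained as
# the slow reference implementation for validating the FFT route.
correlate_direct <- function(image, kernel) {
  stopifnot(inherits(kernel, "detection_kernel"))
  arr <- if (inherits(image, "frame_stack")) image$frames else image
  if (length(dim(arr)) == 2L || is.null(dim(arr))) {
    arr <- array(as.matrix(arr), dim = c(dim(as.matrix(arr)), 1L))
    squeeze <- TRUE
  } else squeeze <- FALSE
  k <- kernel$template
  kh <- (nrow(k) - 1L) %/% 2L
  kw <- (ncol(k) - 1L) %/% 2L
  d <- dim(arr)
  nr <- d[1L]; nc <- d[2L]; nf <- d[3L]
  if (nrow(k) > nr || ncol(k) > nc) stop("kernel larger than image")
  pad <- array(0, dim = c(nr + 2L * kh, nc + 2L * kw, nf))
  pad[kh + seq_len(nr), kw + seq_len(nc), ] <- arr
  valid <- array(0, dim = dim(pad))
  valid[kh + seq_len(nr), kw + seq_len(nc), ] <- 1
  zero <- array(0, dim = d)
  N <- zero; S1 <- zero; S2 <- zero; SK <- zero; SK2 <- zero; SPK <- zero
  for (di in (-kh):kh) {
    ri <- kh + di + seq_len(nr)
    for (dj in (-kw):kw) {
      w <- k[di + kh + 1L, dj + kw + 1L]
      cj <- kw + dj + seq_len(nc)
      p <- pad[ri, cj, , drop = FALSE]
      v <- valid[ri, cj, , drop = FALSE]
      N <- N + v
      S1 <- S1 + p
      S2 <- S2 + p * p
      SK <- SK + v * w
      SK2 <- SK2 + v * w * w
      SPK <- SPK + p * w
    }
  }
  num <- SPK - S1 * SK / N
  varp <- pmax(S2 - S1 * S1 / N, 0)
  vark <- pmax(SK2 - SK * SK / N, 0)
  den <- sqrt(varp * vark)
  score <- ifelse(den > 1e-12, num / den, 0)
  score <- pmin(pmax(score, -1), 1)
  if (squeeze) score <- score[, , 1L]
  score
}

#' Threshold a correlation score map
#'
#' @param score_map numeric matrix or array of correlation scores.
#' @param threshold scalar in (0, 1); pixels with `score >= threshold` are
#'   kept.
#' @return logical mask congruent with `score_map`.
#' @export
binarize <- function(score_map, threshold) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must lie in (0, 1]")
  score_map >= threshold
}

# 8-connected component labels of a logical mask; returns an integer matrix
# (0 = background). Flood fill over the (sparse) foreground pixel set.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  current <- 0L
  offs_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offs_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (px in fg) {
    if (lab[px] != 0L) next
    current <- current + 1L
    queue <- px
    lab[px] <- current
    while (length(queue) > 0L) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      nbr_r <- r + offs_r
      nbr_c <- cc + offs_c
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nidx <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      if (length(nidx) > 0L) {
        lab[nidx] <- current
        queue <- c(queue, nidx)
      }
    }
  }
  lab
}

#' Extract and filter keypoints from a binarized score map
#'
#' Labels 8-connected components of the mask, measures each component's
#' area (pixel count), perimeter (count of component pixels with a
#' 4-neighbour outside the component or outside the image), peak score and
#' score-weighted sub-pixel centroid, then keeps components whose area and
#' area-to-perimeter ratio fall inside the configured ranges. The ratio
#' filter passes compact (round) blobs and rejects elongated artifacts.
#'
#' @param mask logical matrix from [binarize()].
#' @param score_map congruent score matrix used for centroid weighting.
#' @param params a [detection_params()].
#' @param frame_index frame index recorded on each detection (`-1` for
#'   endpoint detections).
#' @return data frame of detections: `frame_index`, `x`, `y` (0-based
#'   pixel-centre coordinates), `score`, `area`, `perimeter`, `ratio`.
#' @export
extract_and_filter_keypoints <- function(mask, score_map, params,
                                         frame_index = -1L) {
  stopifnot(identical(dim(mask), dim(score_map)))
  empty <- data.frame(frame_index = integer(), x = numeric(), y = numeric(),
                      score = numeric(), area = numeric(),
                      perimeter = numeric(), ratio = numeric())
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0L) return(empty)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- vector("list", ncomp)
  idx <- which(lab > 0L)
  comp_of <- lab[idx]
  for (comp in seq_len(ncomp)) {
    px <- idx[comp_of == comp]
    r <- ((px - 1L) %% nr) + 1L
    cc <- ((px - 1L) %/% nr) + 1L
    area <- length(px)
    inside <- function(rr, ccc) {
      ok <- rr >= 1L & rr <= nr & ccc >= 1L & ccc <= nc
      res <- logical(length(rr))
      res[ok] <- lab[(ccc[ok] - 1L) * nr + rr[ok]] == comp
      res
    }
    border <- !(inside(r - 1L, cc) & inside(r + 1L, cc) &
                inside(r, cc - 1L) & inside(r, cc + 1L))
    perimeter <- sum(border)
    w <- score_map[px]
    w <- pmax(w, 1e-9)
    rows[[comp]] <- data.frame(
      frame_index = as.integer(frame_index),
      x = sum(w * (cc - 1)) / sum(w),
      y = sum(w * (r - 1)) / sum(w),
      score = max(score_map[px]),
      area = area,
      perimeter = perimeter,
      ratio = area / perimeter
    )
  }
  out <- do.call(rbind, rows)
  keep <- out$area >= params$area_range[1L] & out$area <= params$area_range[2L] &
    out$ratio >= params$ratio_range[1L] & out$ratio <= params$ratio_range[2L]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-pixel baseline for kinetic mode: "min" across frames, or the
# temporal median (global, or rolling over a centred odd window).
temporal_baseline <- function(arr, method = "min", window = NULL) {
  d <- dim(arr)
  if (method == "min") {
    flat <- matrix(arr, nrow = d[1L] * d[2L])
    mn <- do.call(pmin, as.data.frame(flat))
    return(array(rep(mn, d[3L]), dim = d))
  }
  if (is.null(window)) {
    med <- pixel_median(arr)
    return(array(rep(med, d[3L]), dim = d))
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("median_window must be odd")
  h <- window %/% 2L
  out <- array(0, dim = d)
  flat <- matrix(arr, nrow = d[1L] * d[2L])
  for (f in seq_len(d[3L])) {
    sel <- max(1L, f - h):min(d[3L], f + h)
    out[, , f] <- row_medians(flat[, sel, drop = FALSE])
  }
  out
}

#' Detect particles in a stack
#'
#' End-to-end detection operator. In `endpoint` mode the stack is a focus
#' series: it is normalized by the per-pixel z-median, collapsed to a
#' max-min differential image, background-smoothed (pseudomedian
#' subtraction), cross-correlated with the kernel, binarized at the global
#' threshold and keypoint-filtered; all detections carry
#' `frame_index = -1`. In `kinetic` mode the stack is a time-lapse movie:
#' frames are optionally block-averaged, each pixel is normalized by its
#' temporal median baseline, and every frame is correlated, binarized and
#' keypoint-filtered independently.
#'
#' @param stack a [frame_stack()].
#' @param kernel a [detection_kernel()]; default is a Gaussian template
#'   built from `params$psf_sigma`.
#' @param params a [detection_params()].
#' @param mode `"endpoint"` or `"kinetic"`; defaults to the stack's axis
#'   kind (`z` -> endpoint, `time` -> kinetic).
#' @return data frame of detections (see
#'   [extract_and_filter_keypoints()]) keyed by `frame_index`.
#' @export
detect_stack <- function(stack, kernel = NULL, params = detection_params(),
                         mode = NULL) {
  stopifnot(inherits(stack, "frame_stack"), inherits(params, "detection_params"))
  if (is.null(mode)) mode <- if (stack$axis_kind == "z") "endpoint" else "kinetic"
  mode <- match.arg(mode, c("endpoint", "kinetic"))
  if (is.null(kernel)) kernel <- gaussian_kernel(params$psf_sigma)
  smooth_bg <- isTRUE(params$smooth_background)
  if (mode == "endpoint") {
    norm <- normalize_stack(stack)
    img <- differential_image(norm)
    if (smooth_bg) {
      img <- img - pseudomedian_smooth(img, params$pseudomedian_kernel)
    }
    sm <- correlate(img, kernel)
    mask <- binarize(sm, params$global_threshold)
    return(extract_and_filter_keypoints(mask, sm, params, frame_index = -1L))
  }
  if (params$temporal_average_n > 1L) {
    stack <- temporal_average(stack, params$temporal_average_n)
  }
  arr <- stack$frames
  base <- temporal_baseline(arr, params$baseline, params$median_window)
  if (any(base <= 0)) stop("per-pixel median <= 0: corrupt or non-intensity input")
  norm <- arr / base
  scores <- correlate(norm, kernel)
  dets <- vector("list", dim(arr)[3L])
  for (f in seq_len(dim(arr)[3L])) {
    sm <- scores[, , f]
    if (smooth_bg) {
      sm_img <- norm[, , f] - pseudomedian_smooth(norm[, , f],
                                                  params$pseudomedian_kernel)
      sm <- correlate(sm_img, kernel)
    }
    mask <- binarize(sm, params$global_threshold)
    dets[[f]] <- extract_and_filter_keypoints(mask, sm, params,
                                              frame_index = f - 1L)
  }
  out <- do.call(rbind, dets)
  rownames(out) <- NULL
  out
}
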