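#' Frame stack container
#'
#' An ordered stack of grayscale image frames, either a focus series
#' (`axis_kind = "z"`, axis values in micrometres) or a time-lapse movie
#' (`axis_kind = "time"`, axis values in seconds). Frames are stored as a
#' numeric array indexed `[row, column, frame]`. Pixel coordinates used
#' throughout the package are 0-based at pixel centres with `x` along
#' columns and `y` along rows, so pixel `(x = 0, y = 0)` is the centre of
#' the top-left pixel.
#'
#' @param frames numeric array `[row, col, frame]`, or a list of equal-sized
#'   matrices.
#' @param axis_kind `"z"` or `"time"`.
#' @param axis_values numeric vector, one value per frame, strictly monotone
#'   (micrometres for `"z"`, seconds for `"time"`).
#' @param pixel_pitch physical pixel size in micrometres per pixel.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, axis_kind = c("time", "z"), axis_values = NULL,
                        pixel_pitch = 1) {
  axis_kind <- match.arg(axis_kind)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must have identical dimensions")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (length(dim(frames)) == 2L) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  stopifnot(length(dim(frames)) == 3L, is.numeric(frames))
  nf <- dim(frames)[3L]
  if (is.null(axis_values)) {
    axis_values <- seq_len(nf) - 1
  }
  if (length(axis_values) != nf) {
    stop("axis_values must have one entry per frame")
  }
  d <- diff(axis_values)
  if (nf > 1L && !(all(d > 0) || all(d < 0))) {
    stop("axis_values must be strictly monotone")
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0) {
    stop("pixel_pitch must be a single positive number")
  }
  structure(
    list(frames = frames, axis_kind = axis_kind,
         axis_values = as.numeric(axis_values),
         pixel_pitch = as.numeric(pixel_pitch)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  unit <- if (x$axis_kind == "z") "um" else "s"
  cat(sprintf("frame_stack: %d frames of %d x %d px (%s axis, %g..%g %s, %g um/px)\n",
              d[3L], d[1L], d[2L], x$axis_kind,
              min(x$axis_values), max(x$axis_values), unit, x$pixel_pitch))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3L]

#' Write a frame stack as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are quantized to 16-bit using an affine map recorded in the
#' sidecar (`<path>.json`), which also stores the axis metadata and pixel
#' pitch, so [read_stack()] reconstructs the quantized physical values.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @param intensity_range numeric length-2 giving the physical values mapped
#'   to 0 and 65535; defaults to the data range (expanded slightly when
#'   degenerate).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, intensity_range = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(intensity_range)) {
    intensity_range <- range(stack$frames)
    if (diff(intensity_range) == 0) {
      intensity_range <- intensity_range + c(-0.5, 0.5)
    }
  }
  lo <- intensity_range[1L]
  span <- intensity_range[2L] - intensity_range[1L]
  stopifnot(span > 0)
  # quantize to 16-bit here (writeTIFF truncates): adding half a level
  # before the writer's floor makes read-write-read a fixed point
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    q <- round(pmin(pmax((stack$frames[, , i] - lo) / span, 0), 1) * 65535)
    pmin((q + 0.5) / 65535, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    axis_kind = stack$axis_kind,
    axis_values = stack$axis_values,
    pixel_pitch = stack$pixel_pitch,
    intensity_offset = lo,
    intensity_scale = span
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' Expects 8- or 16-bit grayscale pages of identical shape. Axis metadata is
#' taken from the JSON sidecar written by [write_stack()]; when the sidecar
#' is absent the stack is treated as a time-lapse at 1 s per frame and a
#' warning is emitted.
#'
#' @param path TIFF path.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (is.array(pages) && !is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L) {
      stop("page ", i, " is not single-channel grayscale")
    }
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) {
    bad <- which(vapply(pages, function(p) !identical(dim(p), dims[[1L]]),
                        logical(1L)))[1L]
    stop("page ", bad, " has a different shape from page 1")
  }
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    frames <- lapply(pages, function(p) p * sc$intensity_scale + sc$intensity_offset)
    frame_stack(frames, axis_kind = sc$axis_kind,
                axis_values = sc$axis_values, pixel_pitch = sc$pixel_pitch)
  } else {
    warning("no sidecar '", sidecar_path,
            "'; assuming time axis with 1 s frame interval")
    frame_stack(pages, axis_kind = "time",
                axis_values = seq_along(pages) - 1, pixel_pitch = 1)
  }
}
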