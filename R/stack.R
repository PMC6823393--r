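#' Calibrated image stack
#'
#' Container for a time-lapse fluorescence stack: a numeric array with
#' dimensions (y, x, channel, frame) plus the physical calibration needed to
#' convert pixel measurements to micrometers and seconds.
#'
#' @param data numeric array; either (y, x, c, t), (y, x, t) for a
#'   single-channel movie, or (y, x) for a single frame.
#' @param pixel_size pixel size in um/px (> 0).
#' @param frame_interval frame interval in s (> 0).
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, pixel_size, frame_interval) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) {
    d <- dim(data)
    dim(data) <- c(d[1L], d[2L], 1L, d[3L])
  }
  stopifnot(length(dim(data)) == 4L,
            is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_interval), frame_interval > 0)
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d px, %d channel(s), %d frame(s)\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  calibration: %g um/px, %g s/frame\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @rdname image_stack
#' @param stack an `image_stack`.
#' @export
n_frames <- function(stack) dim(stack$data)[4L]

#' @rdname image_stack
#' @export
n_channels <- function(stack) dim(stack$data)[3L]

#' @rdname image_stack
#' @param frame frame index (1-based).
#' @param channel channel index (1-based).
#' @return `get_frame()` returns the (y, x) intensity matrix of one frame.
#' @export
get_frame <- function(stack, frame, channel = 1L) {
  d <- dim(stack$data)
  if (channel < 1L || channel > d[3L])
    stop("channel ", channel, " not present (stack has ", d[3L], ")")
  if (frame < 1L || frame > d[4L])
    stop("frame ", frame, " out of range 1..", d[4L])
  stack$data[, , channel, frame]
}

# Apply a per-frame, per-channel image transform, keeping calibration.
map_frames <- function(stack, f) {
  out <- stack$data
  for (tt in seq_len(dim(out)[4L]))
    for (cc in seq_len(dim(out)[3L]))
      out[, , cc, tt] <- f(stack$data[, , cc, tt])
  stack$data <- out
  stack
}

#' Write / read a calibrated TIFF stack
#'
#' Stacks are written as multi-page TIFF in TCYX page order (channel fastest)
#' with 16-bit integer samples; intensities are clamped to \[0, 65535\] and
#' rounded, so a written stack reads back bit-exactly at that quantization.
#' Calibration (and optionally ground-truth annotations) go to a JSON sidecar
#' `<path>.json`, which `read_stack()` uses to restore the calibration.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @param truth optional list of ground-truth annotations stored in the
#'   sidecar (numeric vectors only; pixel masks are not serialized).
#' @return `write_stack()` invisibly returns the quantized stack as written;
#'   `read_stack()` returns an [image_stack].
#' @export
write_stack <- function(stack, path, truth = NULL) {
  d <- dim(stack$data)
  q <- round(clamp(stack$data, 0, 65535))
  pages <- vector("list", d[3L] * d[4L])
  i <- 1L
  for (tt in seq_len(d[4L])) for (cc in seq_len(d[3L])) {
    pages[[i]] <- q[, , cc, tt] / 65535
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               n_channels = d[3L], n_frames = d[4L],
               height = d[1L], width = d[2L])
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  stack$data <- q
  invisible(stack)
}

#' @rdname write_stack
#' @param pixel_size,frame_interval calibration overrides; required when no
#'   sidecar is present.
#' @param n_channels number of channels (sidecar value used when `NULL`).
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       n_channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% side$pixel_size
    frame_interval <- frame_interval %||% side$frame_interval
    n_channels <- n_channels %||% side$n_channels
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("missing calibration: supply pixel_size and frame_interval ",
         "or provide the JSON sidecar")
  n_channels <- as.integer(n_channels %||% 1L)
  np <- length(pages)
  if (np %% n_channels != 0L)
    stop("page count ", np, " not divisible by n_channels ", n_channels)
  nt <- np %/% n_channels
  d <- dim(pages[[1L]])
  arr <- array(0, c(d[1L], d[2L], n_channels, nt))
  i <- 1L
  for (tt in seq_len(nt)) for (cc in seq_len(n_channels)) {
    arr[, , cc, tt] <- round(pages[[i]] * 65535)
    i <- i + 1L
  }
  image_stack(arr, pixel_size, frame_interval)
}
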