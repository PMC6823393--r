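#' Smooth a reporter frame
#'
#' Gaussian smoothing applied to reporter (GFP) images before kymograph
#' extraction and membrane/lumen trace measurement: nominal support 10 px
#' (realized as the nearest odd size, 11x11) with SD 1.2 px. The kernel is
#' normalized, so total intensity is preserved up to boundary handling.
#'
#' @param frame 2-D intensity matrix.
#' @param size nominal kernel support in px.
#' @param sigma Gaussian SD in px.
#' @return Smoothed matrix.
#' @export
smooth_reporter <- function(frame, size = 10L, sigma = 1.2) {
  convolve2d(frame, gaussian_kernel(size, sigma))
}

#' Ordered perimeter path of a mask
#'
#' Traces the closed 8-connected boundary of a single-component mask by
#' Moore-neighbor tracing, starting at the topmost-then-leftmost boundary
#' pixel and proceeding clockwise (in image orientation, y down). Pixels on
#' one-pixel-wide protrusions appear twice, keeping the path closed.
#'
#' @param mask logical/binary matrix with one connected component.
#' @return Integer matrix with columns `y`, `x`, one row per path step.
#' @export
perimeter_path <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 1L)
    return(matrix(pts[1L, ], 1L, 2L, dimnames = list(NULL, c("y", "x"))))
  start <- pts[order(pts[, 1L], pts[, 2L])[1L], ]
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(y, x) y >= 1L && y <= nr && x >= 1L && x <= nc && mask[y, x]
  # clockwise neighbor offsets (y down): up, up-right, right, down-right,
  # down, down-left, left, up-left
  dy <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dx <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  # initial backtrack: the pixel above the start (outside by construction)
  p <- start; bdir <- 1L   # direction from p towards the backtrack pixel
  path <- matrix(0L, 8L * nrow(pts) + 2L, 2L)
  path[1L, ] <- p; np <- 1L
  second <- NULL
  finish <- function() {
    # drop a trailing duplicate of the start so the trace is closed but
    # the start pixel appears once
    if (np > 1L && all(path[np, ] == start)) np <- np - 1L
    structure(path[seq_len(np), , drop = FALSE],
              dimnames = list(NULL, c("y", "x")))
  }
  repeat {
    found <- FALSE
    for (k in seq_len(8L)) {
      dir <- ((bdir - 1L + k - 1L) %% 8L) + 1L
      yy <- p[1L] + dy[dir]; xx <- p[2L] + dx[dir]
      if (inside(yy, xx)) {
        # stop when the traversal state repeats: back at the start pixel
        # and about to move to the same second pixel as the first step
        if (!is.null(second) && all(p == start) &&
            yy == second[1L] && xx == second[2L])
          return(finish())
        if (is.null(second)) second <- c(yy, xx)
        pold <- p
        p <- c(yy, xx)
        np <- np + 1L
        path[np, ] <- p
        # new backtrack: the neighbor checked just before this hit
        prev <- ((dir - 2L) %% 8L) + 1L
        py <- pold[1L] + dy[prev] - yy
        px <- pold[2L] + dx[prev] - xx
        bdir <- which(dy == py & dx == px)
        found <- TRUE
        break
      }
    }
    if (!found || np >= nrow(path) - 1L) return(finish())
  }
}

#' Perimeter kymograph of a tracked liposome
#'
#' Row `t` of the kymograph is the smoothed reporter intensity sampled along
#' that frame's perimeter path. Because the circumference changes when the
#' liposome deforms, every row is resampled by linear interpolation to the
#' length of the longest path in the movie, so all rows align. The column
#' origin is each frame's topmost-then-leftmost boundary pixel and columns
#' advance clockwise.
#'
#' @param paths list of perimeter paths (one per frame, see
#'   [perimeter_path()]).
#' @param frames list of smoothed reporter matrices (one per frame).
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @return A `kymograph` object: list with `data` (rows = time, columns =
#'   normalized perimeter position), calibration, and `origin` note.
#' @export
build_kymograph <- function(paths, frames, pixel_size, frame_interval) {
  stopifnot(length(paths) >= 1L, length(paths) == length(frames))
  lens <- vapply(paths, nrow, 0L)
  if (any(lens == 0L)) stop("empty perimeter path")
  L <- max(lens)
  rows <- vapply(seq_along(paths), function(i) {
    vals <- frames[[i]][paths[[i]]]
    resample_linear(vals, L)
  }, numeric(L))
  structure(list(data = t(rows), pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 origin = "topmost-leftmost boundary pixel, clockwise"),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions (%g um/px, %g s/frame)\n",
              nrow(x$data), ncol(x$data), x$pixel_size, x$frame_interval))
  invisible(x)
}

# Linear interpolation of a profile to `n` samples spanning the same range.
resample_linear <- function(vals, n) {
  m <- length(vals)
  if (m == 1L) return(rep(vals, n))
  if (m == n) return(vals)
  approx(seq_len(m), vals, xout = seq(1, m, length.out = n))$y
}

#' Membrane and lumen intensity traces
#'
#' For each frame, the membrane region is the band of pixels within
#' `band_width` px inside the mask boundary (mask minus its erosion by a
#' disk of that radius) and the lumen region is the mask eroded by
#' `band_width + 2` px, leaving a buffer between the two. Mean smoothed
#' reporter intensity over each region is reported per frame; frames whose
#' lumen region is empty (liposome too small for the band) yield `NA` and
#' are flagged.
#'
#' @param masks list of logical masks (one per frame).
#' @param frames list of smoothed reporter matrices.
#' @param band_width membrane band width in px.
#' @return data.frame with columns `frame`, `membrane_mean`, `lumen_mean`,
#'   `lumen_empty`.
#' @export
membrane_lumen_traces <- function(masks, frames, band_width = 3) {
  stopifnot(length(masks) == length(frames))
  k_in <- disk_kernel(band_width)
  k_lum <- disk_kernel(band_width + 2)
  out <- data.frame(frame = seq_along(masks), membrane_mean = NA_real_,
                    lumen_mean = NA_real_, lumen_empty = FALSE)
  for (i in seq_along(masks)) {
    m <- masks[[i]] > 0
    er <- EBImage::erode(m * 1, k_in) > 0
    band <- m & !er
    lum <- EBImage::erode(m * 1, k_lum) > 0
    f <- frames[[i]]
    out$membrane_mean[i] <- if (any(band)) mean(f[band]) else NA_real_
    if (any(lum)) out$lumen_mean[i] <- mean(f[lum])
    else out$lumen_empty[i] <- TRUE
  }
  out
}

#' Liposome elongation
#'
#' Ratio of major to minor axis of the ellipse with the same normalized
#' second central moments as the mask: the square root of the ratio of the
#' eigenvalues of the pixel-coordinate covariance matrix, with a +1/12 px^2
#' correction on the diagonal accounting for the finite pixel area (and
#' keeping the minor eigenvalue positive for one-pixel-thick masks).
#'
#' @param mask logical/binary matrix, area >= 4 px.
#' @return Dimensionless elongation >= 1.
#' @export
elongation <- function(mask) {
  pts <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(pts)
  if (n < 4L) stop("mask area < 4 px: elongation undefined")
  ctr <- colMeans(pts)
  z <- sweep(pts, 2L, ctr)
  # population (normalized) second central moments + pixel-area term
  C <- crossprod(z) / n + diag(1 / 12, 2L)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[1L] / ev[2L])
}

#' Normalized perimeter
#'
#' Circumference of the circle with the same area as the mask:
#' `pi * sqrt(4 * A / pi)`, with `A` the calibrated area in um^2. By the
#' isoperimetric inequality this is a lower bound on the true perimeter of
#' any non-circular shape.
#'
#' @param mask logical/binary matrix.
#' @param pixel_size um/px.
#' @return Normalized perimeter in um.
#' @export
normalized_perimeter <- function(mask, pixel_size = 1) {
  a_px <- sum(mask > 0)
  if (a_px == 0) stop("empty mask")
  a <- a_px * pixel_size^2
  pi * sqrt(4 * a / pi)
}

#' Phase lag between elongation and lumen signal
#'
#' Lag (in seconds) at the maximum of the circular cross-correlation of the
#' mean-subtracted elongation and lumen-intensity series. Positive values
#' mean the elongation cycle leads the lumen signal; the result is wrapped
#' to (-T/2, T/2] with T the series duration.
#'
#' @param elong per-frame elongation series.
#' @param lumen per-frame lumen intensity series (same length).
#' @param frame_interval s/frame.
#' @return Lag in seconds.
#' @export
elongation_phase_lag <- function(elong, lumen, frame_interval) {
  stopifnot(length(elong) == length(lumen), length(elong) >= 3L)
  if (sd(elong) == 0 || sd(lumen) == 0)
    stop("constant series: phase undefined")
  e <- elong - mean(elong)
  l <- lumen - mean(lumen)
  n <- length(e)
  shifts <- 0:(n - 1L)
  cc <- vapply(shifts, function(s) {
    idx <- ((seq_len(n) - 1L + s) %% n) + 1L
    sum(e * l[idx])
  }, 0)
  best <- shifts[which.max(cc)]
  if (best > n / 2) best <- best - n
  best * frame_interval
}
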