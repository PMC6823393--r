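#' Background correction by white top-hat
#'
#' Removes broad background while retaining features thinner than the
#' structuring element: the grayscale opening with a disk of the given radius
#' is subtracted from the frame (white top-hat). The membrane ring of a
#' liposome is thinner than the default 4-px disk, so it survives while
#' smooth background and large filled structures are suppressed. The result
#' is non-negative everywhere.
#'
#' @param frame 2-D intensity matrix.
#' @param radius disk radius in px (>= 1).
#' @return Corrected matrix of the same size.
#' @export
background_correct <- function(frame, radius = 4) {
  stopifnot(is.matrix(frame), radius >= 1)
  if (2 * radius + 1 > min(dim(frame)))
    stop("structuring element larger than the image")
  frame - gray_opening(frame, disk_kernel(radius))
}

# Bank of rotated elongated Laplacian-of-Gaussian kernels. Each kernel is the
# analytic LoG of an anisotropic Gaussian (SD `sigma_along` along the filter
# axis, `sigma_across` across it), sampled on an odd grid of nominal support
# `size`, sign-flipped so bright ridges score positive, and mean-subtracted
# so uniform regions score zero.
log_kernel_bank <- function(n_orientations = 12L, size = 10L,
                            sigma_along = 3, sigma_across = 0.1) {
  stopifnot(n_orientations >= 1)
  n <- as.integer(size)
  if (n %% 2L == 0L) n <- n + 1L
  h <- (n - 1L) %/% 2L
  u <- matrix(rep(-h:h, n), n, n)   # row offset (y)
  v <- t(u)                         # col offset (x)
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  lapply(thetas, function(th) {
    a <- v * cos(th) + u * sin(th)   # along the filter axis
    c <- -v * sin(th) + u * cos(th)  # across
    g <- exp(-a^2 / (2 * sigma_along^2) - c^2 / (2 * sigma_across^2))
    log_ <- g * ((a^2 / sigma_along^4 - 1 / sigma_along^2) +
                 (c^2 / sigma_across^4 - 1 / sigma_across^2))
    k <- -log_                      # ridges positive
    k - mean(k)
  })
}

#' Membrane ridge enhancement
#'
#' Convolves the frame with a bank of rotated elongated Laplacian-of-Gaussian
#' kernels (orientations uniformly spanning 0..180 degrees) and returns the
#' per-pixel maximum response. Thin bright ridges such as a liposome membrane
#' in cross-section respond strongly at the orientation matching their local
#' direction; isotropic blobs and uniform regions score near zero.
#'
#' @param frame 2-D intensity matrix (at least twice the kernel support).
#' @param n_orientations number of filter orientations over 180 degrees.
#' @param size nominal kernel support in px (rounded up to odd).
#' @param sigma_along,sigma_across Gaussian SDs along/across the filter axis.
#' @return Ridge-response matrix of the same size.
#' @export
membrane_enhance <- function(frame, n_orientations = 12L, size = 10L,
                             sigma_along = 3, sigma_across = 0.1) {
  if (n_orientations < 1) stop("n_orientations must be positive")
  bank <- log_kernel_bank(n_orientations, size, sigma_along, sigma_across)
  if (min(dim(frame)) < 2 * nrow(bank[[1L]]))
    stop("frame smaller than twice the kernel support")
  res <- convolve2d(frame, bank[[1L]])
  for (k in bank[-1L]) res <- pmax(res, convolve2d(frame, k))
  res
}

#' Seeded watershed segmentation of one liposome
#'
#' Floods the ridge-response landscape from two markers -- the user seed and
#' the image border -- using Meyer's marker-controlled watershed, so the two
#' fronts meet on the membrane ridge crest. The seed's catchment basin,
#' hole-filled and reduced to the single connected component containing the
#' seed, is returned as the liposome mask.
#'
#' @param response ridge-response matrix from [membrane_enhance()].
#' @param seed logical/binary seed matrix, non-empty, not touching the
#'   image border.
#' @return list with `mask` (logical matrix), `area` (px^2) and
#'   `centroid` c(y, x).
#' @export
watershed_segment <- function(response, seed) {
  stopifnot(is.matrix(response))
  seed <- seed > 0
  if (!any(seed)) stop("empty seed")
  if (!all(dim(seed) == dim(response))) stop("seed/response size mismatch")
  nr <- nrow(seed); nc <- ncol(seed)
  border <- matrix(FALSE, nr, nc)
  border[c(1L, nr), ] <- TRUE; border[, c(1L, nc)] <- TRUE
  if (any(seed & border)) stop("seed touches the image border")
  markers <- matrix(0L, nr, nc)
  markers[seed] <- 1L
  markers[border] <- 2L
  lab <- meyer_watershed(response, markers)
  mask <- lab == 1L
  mask <- EBImage::fillHull(mask * 1) > 0
  comp <- EBImage::bwlabel(mask * 1)
  keep <- unique(comp[seed & mask])
  keep <- keep[keep > 0]
  if (length(keep) == 0) stop("watershed failure: seed basin vanished")
  mask <- comp == keep[1L]
  inner <- matrix(FALSE, nr, nc)
  inner[c(2L, nr - 1L), ] <- TRUE; inner[, c(2L, nc - 1L)] <- TRUE
  if (any(mask & inner))
    stop("watershed failure: basin reaches the image border")
  pts <- which(mask, arr.ind = TRUE)
  list(mask = mask, area = nrow(pts),
       centroid = c(mean(pts[, 1L]), mean(pts[, 2L])))
}

#' Derive the next frame's seed from a segmented mask
#'
#' Erodes the mask with a disk whose radius scales with the liposome size:
#' `max(1, round(shrink_factor * D_eq))`, where `D_eq = 2 * sqrt(area / pi)`
#' is the equivalent diameter. If the erosion empties the mask (very small
#' liposomes), a 3x3 square centered on the centroid is used instead, so the
#' returned seed is always non-empty.
#'
#' @param mask logical mask of the previous frame's segmentation.
#' @param shrink_factor erosion radius as a fraction of equivalent diameter.
#' @return logical seed matrix.
#' @export
propagate_seed <- function(mask, shrink_factor = 0.15) {
  mask <- mask > 0
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  d_eq <- 2 * sqrt(area / pi)
  r <- max(1, round(shrink_factor * d_eq))
  seed <- EBImage::erode(mask * 1, disk_kernel(r)) > 0
  if (!any(seed)) {
    pts <- which(mask, arr.ind = TRUE)
    cy <- round(mean(pts[, 1L])); cx <- round(mean(pts[, 2L]))
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    ys <- clamp((cy - 1L):(cy + 1L), 1L, nrow(mask))
    xs <- clamp((cx - 1L):(cx + 1L), 1L, ncol(mask))
    seed[ys, xs] <- TRUE
  }
  seed
}

#' Track one liposome through a time-lapse stack
#'
#' Runs the full per-frame segmentation chain -- background correction,
#' ridge enhancement, seeded watershed -- on the membrane-dye channel, using
#' the supplied seed for frame 1 and a seed propagated from each segmented
#' frame (erosion by a size-dependent disk) for all later frames. Tracking is
#' declared lost if consecutive masks stop overlapping.
#'
#' @param stack an [image_stack].
#' @param initial_seed logical seed matrix for frame 1.
#' @param channel membrane-dye channel index.
#' @param bg_radius disk radius for [background_correct()].
#' @param n_orientations orientations for [membrane_enhance()].
#' @param shrink_factor see [propagate_seed()].
#' @return list with `masks` (list of logical matrices, one per frame) and
#'   `stats` (data.frame: frame, area_px2, centroid_y, centroid_x).
#' @export
track_liposome <- function(stack, initial_seed, channel = 1L, bg_radius = 4,
                           n_orientations = 12L, shrink_factor = 0.15) {
  nt <- n_frames(stack)
  masks <- vector("list", nt)
  stats <- data.frame(frame = seq_len(nt), area_px2 = NA_real_,
                      centroid_y = NA_real_, centroid_x = NA_real_)
  seed <- initial_seed > 0
  for (i in seq_len(nt)) {
    frame <- get_frame(stack, i, channel)
    resp <- membrane_enhance(background_correct(frame, bg_radius),
                             n_orientations)
    seg <- tryCatch(watershed_segment(resp, seed),
                    error = function(e)
                      stop("frame ", i, ": ", conditionMessage(e)))
    if (i > 1L && iou(seg$mask, masks[[i - 1L]]) == 0)
      stop("tracking loss at frame ", i,
           ": no overlap with the previous mask")
    masks[[i]] <- seg$mask
    stats$area_px2[i] <- seg$area
    stats$centroid_y[i] <- seg$centroid[1L]
    stats$centroid_x[i] <- seg$centroid[2L]
    seed <- propagate_seed(seg$mask, shrink_factor)
  }
  list(masks = masks, stats = stats)
}
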