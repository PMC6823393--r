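#' Standing-wave oscillation period by per-pixel autocorrelation
#'
#' Computes, for every pixel, the normalized temporal autocorrelation of its
#' mean-subtracted intensity trace and locates the first local maximum at
#' positive lag whose prominence (height above the lowest preceding value of
#' the autocorrelation) reaches `min_prominence`. The reported period is the
#' median of the qualifying lags, in seconds; with an even number of
#' qualifying pixels the median is the midpoint of the two central values.
#'
#' The prominence gate is what excludes pixels that carry no oscillation:
#' the autocorrelation of a pure-noise trace fluctuates with SD of roughly
#' `1/sqrt(n_frames)`, so the default of 0.3 rejects such pixels for any
#' realistic movie length while keeping every pixel whose oscillatory
#' component contributes more than about 15% of its temporal variance.
#'
#' @param stack single-channel [image_stack] (or the channel selected with
#'   `channel`).
#' @param min_prominence minimum autocorrelation peak prominence (fraction,
#'   on the normalized autocorrelation scale).
#' @param channel channel index.
#' @return Period in seconds.
#' @export
standing_wave_period <- function(stack, min_prominence = 0.3, channel = 1L) {
  d <- dim(stack$data)
  nt <- d[4L]
  if (nt < 3L) stop("too few frames")
  X <- matrix(stack$data[, , channel, ], d[1L] * d[2L], nt)
  X <- X - rowMeans(X)
  v <- rowSums(X^2)
  keep <- v > 0
  if (!any(keep)) stop("no pixel has temporal variance")
  X <- X[keep, , drop = FALSE]
  # unbiased autocorrelation via FFT: dividing the lag-l autocovariance sum
  # by (n - l) removes the triangular taper of the biased estimator, which
  # would otherwise pull every first peak systematically towards smaller
  # lags. Peaks are searched up to lag n/2, where the unbiased estimate is
  # still well conditioned (the movie is required to span several periods).
  nfft <- nextn(2L * nt, 2L)
  F <- mvfft(t(cbind(X, matrix(0, nrow(X), nfft - nt))))
  ac <- Re(mvfft(F * Conj(F), inverse = TRUE))[seq_len(nt), , drop = FALSE]
  ac <- ac / (nt - (seq_len(nt) - 1L))
  ac <- sweep(ac, 2L, ac[1L, ], "/")   # lag 0..nt-1 in rows, pixels in cols
  ac <- ac[seq_len(floor(nt / 2) + 1L), , drop = FALSE]
  lags <- first_prominent_peak(ac, min_prominence)
  lags <- lags[!is.na(lags)]
  if (length(lags) == 0)
    stop("no pixel has a qualifying autocorrelation peak: period undefined")
  median(lags) * stack$frame_interval
}

# For each column of `ac` (rows = lag 0..n-1), return the first positive lag
# that is a local maximum with prominence >= min_prom, or NA. Prominence is
# measured against the lowest autocorrelation value at or before the peak.
first_prominent_peak <- function(ac, min_prom) {
  n <- nrow(ac)
  if (n < 3L) return(rep(NA_integer_, ncol(ac)))
  mid <- ac[2:(n - 1L), , drop = FALSE]
  locmax <- mid >= ac[1:(n - 2L), , drop = FALSE] &
    mid > ac[3:n, , drop = FALSE]
  runmin <- apply(ac, 2L, cummin)[2:(n - 1L), , drop = FALSE]
  ok <- locmax & (mid - runmin >= min_prom)
  idx <- apply(ok, 2L, function(z) which(z)[1L])
  idx   # local-max index i corresponds to lag i (rows start at lag 1)
}

#' Kymograph along a line
#'
#' Samples the stack every 1 px along the segment from `p0` to `p1` (pixel
#' coordinates `c(y, x)`, bilinear interpolation) in every frame, giving a
#' kymograph with rows = time and columns = position along the line. Used to
#' measure traveling-wave geometry: with the line along the propagation
#' direction, wave crests appear as tilted stripes.
#'
#' @param stack an [image_stack].
#' @param p0,p1 segment end points, `c(y, x)` in px.
#' @param channel channel index.
#' @return A `kymograph` object.
#' @export
line_kymograph <- function(stack, p0, p1, channel = 1L) {
  if (all(p0 == p1)) stop("degenerate segment: p0 == p1")
  len <- sqrt(sum((p1 - p0)^2))
  n <- ceiling(len) + 1L
  ys <- seq(p0[1L], p1[1L], length.out = n)
  xs <- seq(p0[2L], p1[2L], length.out = n)
  nt <- n_frames(stack)
  out <- matrix(0, nt, n)
  for (i in seq_len(nt))
    out[i, ] <- bilinear_sample(get_frame(stack, i, channel), ys, xs)
  structure(list(data = out, pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval,
                 origin = sprintf("line (%g,%g)-(%g,%g)", p0[1L], p0[2L],
                                  p1[1L], p1[2L])),
            class = "kymograph")
}

# Bilinear interpolation of a matrix at fractional (y, x) positions.
bilinear_sample <- function(m, ys, xs) {
  nr <- nrow(m); nc <- ncol(m)
  y0 <- clamp(floor(ys), 1, nr - 1); x0 <- clamp(floor(xs), 1, nc - 1)
  fy <- clamp(ys, 1, nr) - y0; fx <- clamp(xs, 1, nc) - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fy) * (1 - fx) + m[i10] * fy * (1 - fx) +
    m[i01] * (1 - fy) * fx + m[i11] * fy * fx
}

#' Pre-blur a stack before kymograph extraction
#'
#' Per-frame Gaussian blur with SD equal to `radius` px, used to suppress
#' small-scale features (e.g. short cytoskeletal filaments) before measuring
#' large-scale wave geometry. `radius = 0` returns the stack unchanged.
#'
#' @param stack an [image_stack].
#' @param radius blur SD in px (>= 0).
#' @return Blurred [image_stack].
#' @export
preblur <- function(stack, radius = 8) {
  stopifnot(radius >= 0)
  if (radius == 0) return(stack)
  d <- dim(stack$data)
  # kernel support: ~6 SD, capped to the frame size (filter2 requirement)
  size <- min(max(7, ceiling(6 * radius)), min(d[1L], d[2L]))
  if (size %% 2L == 0L) size <- size - 1L
  k <- gaussian_kernel(size, radius)
  map_frames(stack, function(f) convolve2d(f, k))
}

#' Traveling-wave wavelength and velocity from a kymograph
#'
#' Wave crests in a space-time kymograph form parallel stripes. The
#' estimator binarizes the kymograph by Sobel edge detection -- gradient
#' magnitude thresholded by Otsu's method, thinned to per-row local maxima
#' along the space axis, keeping rising (dark-to-bright along space)
#' crossings only so that consecutive lines are one full wavelength apart --
#' and detects lines with a linear Hough transform (angle resolution 0.5
#' degrees, rho resolution 1 px). The stripe angle is seeded from the
#' kymograph's 2-D power spectrum and refined by maximizing the sharpness
#' of the edge projection within the window allowed by spectral
#' quantization (never narrower than `angle_window`); line candidates are
#' non-maximum suppressed with a minimum rho separation of 3 px. The stripe
#' slope gives the velocity (median `|dx/dt|` over accepted lines,
#' converted with the calibration) and the median spacing between
#' consecutive parallel lines along the space axis at fixed time gives the
#' wavelength.
#'
#' @param kymo a `kymograph` (rows = time, columns = space).
#' @param angle_res Hough angle resolution, degrees.
#' @param rho_sep minimum rho separation between accepted lines, px.
#' @param angle_window half-width of the dominant-angle gate, degrees.
#' @param min_votes_frac accept Hough peaks with at least this fraction of
#'   the strongest peak's votes.
#' @param smooth_sigma Gaussian SD (px) of the kymograph pre-smoothing
#'   applied before edge detection; suppresses pixel noise while leaving
#'   wave-scale stripes essentially untouched (0 = none).
#' @param exclude_stationary when the field of view also contains a static
#'   texture (e.g. a stable cytoskeletal network under a propagating wave),
#'   that texture appears in the kymograph as a family of stationary
#'   stripes, i.e. spectral power at zero temporal frequency. Set `TRUE`
#'   to drop the zero-frequency row from the spectral angle seed so the
#'   moving wave is measured; leave `FALSE` to measure stationary stripe
#'   patterns.
#' @return list with `wavelength_um`, `velocity_um_s`, `period_s`
#'   (`wavelength / velocity`), `n_lines`, `theta_deg`, and `flags`.
#' @export
estimate_traveling_wave <- function(kymo, angle_res = 0.5, rho_sep = 3,
                                    angle_window = 5, min_votes_frac = 0.5,
                                    smooth_sigma = 2,
                                    exclude_stationary = FALSE) {
  stopifnot(inherits(kymo, "kymograph"))
  K <- kymo$data
  if (max(K) == min(K)) stop("blank kymograph")
  if (smooth_sigma > 0)
    K <- convolve2d(K, gaussian_kernel(max(7, ceiling(6 * smooth_sigma)),
                                       smooth_sigma))
  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)
  gx <- convolve2d(K, sob)        # gradient along space (columns)
  gy <- convolve2d(K, t(sob))     # gradient along time (rows)
  mag <- sqrt(gx^2 + gy^2)
  rng <- range(mag)
  thr <- EBImage::otsu(EBImage::Image((mag - rng[1L]) / diff(rng))) *
    diff(rng) + rng[1L]
  # thin to per-row local maxima of gradient magnitude along space, keep
  # rising crossings only: one line per wavelength
  nr <- nrow(mag); ncl <- ncol(mag)
  locmax <- matrix(FALSE, nr, ncl)
  if (ncl >= 3L)
    locmax[, 2:(ncl - 1L)] <- mag[, 2:(ncl - 1L), drop = FALSE] >=
      mag[, 1:(ncl - 2L), drop = FALSE] &
      mag[, 2:(ncl - 1L), drop = FALSE] > mag[, 3:ncl, drop = FALSE]
  edges <- locmax & mag >= thr & gx > 0
  if (sum(edges) < 2L) stop("no edges detected in kymograph")

  seed <- spectral_seed(K, exclude_stationary, angle_window)
  pk <- hough_lines(edges, angle_res, rho_sep, min_votes_frac,
                    seed$theta, seed$half_window_deg, seed$rho_spacing)
  if (nrow(pk) < 2L)
    stop("fewer than two lines detected: estimate undefined")
  flags <- character(0)
  if (sd(pk$theta_deg) > 2) flags <- c(flags, "non_parallel_lines")
  v_px <- median(abs(tan(pk$theta_deg * pi / 180)))
  velocity <- v_px * kymo$pixel_size / kymo$frame_interval
  # spacing between consecutive parallel lines along the space axis at
  # fixed time: differences of the mid-row crossing positions
  wavelength <- median(diff(sort(pk$x0))) * kymo$pixel_size
  list(wavelength_um = wavelength, velocity_um_s = velocity,
       period_s = if (velocity > 0) wavelength / velocity else NA_real_,
       n_lines = nrow(pk), theta_deg = pk$theta_deg[1L], flags = flags)
}

# Seed the stripe angle from the kymograph's 2-D power spectrum. A plane
# wave is a single spatiotemporal frequency peak at (omega, kx), whose
# ratio gives the stripe slope s = dx/dt in px/frame (and hence the Hough
# angle, tan(theta) = -s); a static texture sits in the omega = 0 row and a
# spatially uniform flicker in the kx = 0 column, so both are separated
# from the wave by construction. The spectral estimate is quantized to
# whole periods per movie, so alongside the central angle the +/- half-bin
# uncertainty is propagated into the angle window that the Hough refinement
# is allowed to search.
spectral_seed <- function(M, exclude_stationary, angle_window) {
  nt <- nrow(M); nx <- ncol(M)
  P <- Mod(stats::fft(M - mean(M)))^2
  nw <- floor(nt / 2); nk <- floor(nx / 2)
  w_min <- if (exclude_stationary) 1L else 0L
  ws <- w_min:nw
  kx <- 1:nk
  # negative-slope cells (omega, kx) and positive-slope cells (omega, -kx)
  Pneg <- P[ws + 1L, kx + 1L, drop = FALSE]
  Ppos <- P[ws + 1L, nx - kx + 1L, drop = FALSE]
  if (w_min == 0L) Ppos[1L, ] <- -Inf   # omega = 0: one copy is enough
  if (max(Pneg) >= max(Ppos)) {
    ij <- which(Pneg == max(Pneg), arr.ind = TRUE)[1L, ]
    sgn <- -1
  } else {
    ij <- which(Ppos == max(Ppos), arr.ind = TRUE)[1L, ]
    sgn <- 1
  }
  w <- ws[ij[1L]]; k <- kx[ij[2L]]
  slope <- function(wv, kv) sgn * wv * nx / (kv * nt)   # px per frame
  th_of <- function(s) { th <- atan(-s); if (th < 0) th + pi else th }
  th_mid <- th_of(slope(w, k))
  # propagate the +/- half-bin spectral quantization into an angle window
  corners <- c(th_of(slope(max(w - 0.5, 0), k + 0.5)),
               th_of(slope(w + 0.5, max(k - 0.5, 0.5))))
  dist <- function(a, b) { d <- abs(a - b); min(d, pi - d) }
  half <- max(angle_window * pi / 180,
              max(vapply(corners, dist, 0, b = th_mid)) + 0.5 * pi / 180)
  list(theta = th_mid, half_window_deg = half * 180 / pi,
       rho_spacing = (nx / k) * abs(cos(th_mid)))
}

# Linear Hough transform on a logical edge map (rows = y, cols = x; both
# 0-based in the parameterization rho = x cos(theta) + y sin(theta)),
# restricted to theta_seed +/- half_window_deg (from the spectral seed).
#
# The exact angle is found by maximizing a sharpness criterion -- the sum
# of squares of the Gaussian-smoothed (SD rho_sep) 1-px projection
# histogram of all edge points -- which is largest when the projection
# direction matches the stripes: first on an angle_res grid over the
# allowed window, then on two zoom levels five / five-hundred times finer.
# Without the last zoom a residual angle error of a few hundredths of a
# degree still drifts a steep line's projection across several 1-px bins
# over the height of the kymograph, and a coarse-grid angle error would be
# amplified by 1/cos(theta) in the spacing conversion. Lines are then the
# local maxima of the smoothed projection histogram at the final angle,
# subject to a minimum rho separation of rho_sep px and at least
# min_votes_frac of the strongest line's (smoothed) count.
hough_lines <- function(edges, angle_res, rho_sep, min_votes_frac,
                        theta_seed, half_window_deg, rho_spacing = Inf) {
  pts <- which(edges, arr.ind = TRUE)
  y <- pts[, 1L] - 1; x <- pts[, 2L] - 1
  diag_len <- ceiling(sqrt((nrow(edges) - 1)^2 + (ncol(edges) - 1)^2))
  rho_off <- diag_len + 2L
  nrho <- 2L * (diag_len + 2L) + 1L
  proj_counts <- function(th) {
    tabulate(round(x * cos(th) + y * sin(th)) + rho_off, nbins = nrho)
  }
  # histogram smoothing absorbs edge-position jitter within one stripe; its
  # SD is capped well below the expected stripe spacing (known from the
  # spectral seed) so that closely spaced stripes are not merged
  sd_h <- clamp(rho_spacing / 6, 0.8, rho_sep)
  gw <- ceiling(2 * sd_h)
  g <- exp(-((-gw):gw)^2 / (2 * sd_h^2))
  g <- g / sum(g)
  smooth_hist <- function(h) {
    hs <- as.numeric(stats::filter(h, g, sides = 2))
    hs[is.na(hs)] <- 0
    hs
  }
  sharpness <- function(th) sum(smooth_hist(proj_counts(th))^2)
  th_star <- theta_seed
  for (pass in 1:3) {
    half <- switch(pass, half_window_deg, angle_res, angle_res / 5)
    step <- switch(pass, angle_res, angle_res / 5, angle_res / 100)
    fine <- seq(th_star - half * pi / 180, th_star + half * pi / 180,
                by = step * pi / 180)
    th_star <- fine[which.max(vapply(fine, sharpness, 0))]
  }
  if (abs(th_star - pi / 2) < 1 * pi / 180)
    stop("stripes parallel to the time axis: spacing undefined")

  # aggregate jittered edge positions belonging to one stripe: Gaussian
  # smoothing with SD = rho_sep, matching the scale below which two
  # candidate lines are considered the same stripe
  hs <- smooth_hist(proj_counts(th_star))
  # candidate lines are local maxima of the smoothed projection histogram
  nb <- length(hs)
  ismax <- c(FALSE, hs[2:(nb - 1L)] >= hs[1:(nb - 2L)] &
               hs[2:(nb - 1L)] > hs[3:nb], FALSE)
  ord <- order(hs, decreasing = TRUE)
  ord <- ord[ismax[ord] & hs[ord] >= min_votes_frac * max(hs) & hs[ord] > 0]
  rho_pk <- numeric(0); votes <- numeric(0)
  for (i in ord) {
    r <- i - rho_off
    if (length(rho_pk) > 0 && any(abs(rho_pk - r) < rho_sep)) next
    rho_pk <- c(rho_pk, r); votes <- c(votes, hs[i])
  }
  m <- merge_close_lines(rho_pk, votes)
  y_mid <- (nrow(edges) - 1) / 2
  data.frame(rho = m$rho, theta_deg = th_star * 180 / pi, votes = m$votes,
             x0 = (m$rho - y_mid * sin(th_star)) / cos(th_star))
}

# Edge-position jitter can split one stripe's projection into nearby peaks.
# Iteratively merge (vote-weighted) any pair of lines whose separation is
# far below the median line spacing; genuine consecutive stripes are left
# untouched.
merge_close_lines <- function(rho, votes, frac = 0.4) {
  repeat {
    if (length(rho) < 3L) break
    o <- order(rho)
    rho <- rho[o]; votes <- votes[o]
    d <- diff(rho)
    if (min(d) >= frac * median(d)) break
    i <- which.min(d)
    w <- votes[i] + votes[i + 1L]
    rho[i] <- (rho[i] * votes[i] + rho[i + 1L] * votes[i + 1L]) / w
    votes[i] <- w
    rho <- rho[-(i + 1L)]; votes <- votes[-(i + 1L)]
  }
  list(rho = rho, votes = votes)
}

#' Classify the oscillation mode of a perimeter kymograph
#'
#' Extracts the phase of the shared dominant temporal frequency at every
#' perimeter position and classifies the phase profile:
#' \describe{
#'   \item{pulsing}{phases coherent around the whole perimeter (circular SD
#'     below 30 degrees);}
#'   \item{pole_to_pole}{bimodal phase profile with modes ~180 degrees apart
#'     (strong doubled-angle concentration despite weak first-order
#'     concentration);}
#'   \item{circling}{unwrapped phase advancing monotonically through 2*pi
#'     around the perimeter (Spearman |rho| > 0.9 against position);}
#'   \item{undetermined}{no dominant spectral peak, or none of the above.}
#' }
#'
#' @param kymo a perimeter `kymograph` (rows = time, columns = perimeter
#'   position).
#' @param min_power_frac minimum fraction of total non-DC temporal power in
#'   the dominant frequency for classification to proceed.
#' @return list with `label`, `period_s` (dominant period), `phase_profile`
#'   (radians per column) and, for circling, `direction` (+1 = phase
#'   advances clockwise with the perimeter path, -1 = counterclockwise).
#' @export
classify_oscillation_mode <- function(kymo, min_power_frac = 0.2) {
  stopifnot(inherits(kymo, "kymograph"))
  M <- kymo$data
  nt <- nrow(M); np <- ncol(M)
  if (nt < 6L) stop("too few frames for classification")
  M <- sweep(M, 2L, colMeans(M))
  F <- mvfft(M)
  kmax <- floor(nt / 2)
  pw <- rowSums(Matrix_mod2(F[2:(kmax + 1L), , drop = FALSE]))
  kstar <- which.max(pw)
  undet <- list(label = "undetermined", period_s = NA_real_,
                phase_profile = rep(NA_real_, np), direction = NA_integer_)
  if (sum(pw) == 0 || pw[kstar] / sum(pw) < min_power_frac) return(undet)
  period <- nt * kymo$frame_interval / kstar
  phase <- Arg(F[kstar + 1L, ])
  r1 <- Mod(mean(exp(1i * phase)))
  circ_sd_deg <- sqrt(-2 * log(max(r1, 1e-12))) * 180 / pi
  r2 <- Mod(mean(exp(2i * phase)))
  out <- list(label = "undetermined", period_s = period,
              phase_profile = phase, direction = NA_integer_)
  if (circ_sd_deg < 30) {
    out$label <- "pulsing"
  } else if (r2 > 0.7 && r1 < 0.5) {
    out$label <- "pole_to_pole"
  } else {
    uw <- unwrap_phase(phase)
    span <- uw[np] - uw[1L]
    rho_s <- cor(uw, seq_len(np), method = "spearman")
    if (abs(rho_s) > 0.9 && abs(span) > 1.5 * pi && abs(span) < 2.5 * pi) {
      out$label <- "circling"
      out$direction <- if (span < 0) 1L else -1L
    }
  }
  out
}

Matrix_mod2 <- function(z) Re(z)^2 + Im(z)^2

# Standard 1-D phase unwrapping: successive differences folded into
# (-pi, pi].
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}
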