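#' Specification of a synthetic liposome scene
#'
#' Describes a single liposome cross-section imaged at (or near) its
#' equatorial plane: a thin bright membrane ring in the dye channel and a
#' reporter that redistributes between the membrane and the lumen in one of
#' several oscillation modes, optionally coupled to an area-preserving shape
#' elongation. Rendered movies come with full ground truth so downstream
#' segmentation, kymograph and mode-classification code can be validated.
#'
#' Modes:
#' \describe{
#'   \item{`none`}{reporter entirely in the lumen, constant in time.}
#'   \item{`static_membrane`}{reporter entirely on the membrane, constant.}
#'   \item{`pulsing`}{membrane-bound fraction oscillates uniformly around the
#'     whole perimeter with period `period`.}
#'   \item{`pole_to_pole`}{two antiphase membrane domains at opposite poles;
#'     each pole peaks once per `period`.}
#'   \item{`circling`}{a membrane hotspot whose angular position advances by
#'     2*pi per `period`.}
#' }
#'
#' @param image_size c(ny, nx) image size in px.
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @param n_frames number of frames.
#' @param center c(y, x) center in px; defaults to the image center.
#' @param radius liposome radius in um.
#' @param membrane_width membrane ring width in px (Gaussian radial SD is
#'   `membrane_width / 2`).
#' @param mode oscillation mode (see Details).
#' @param period oscillation period in s; must exceed `2 * frame_interval`.
#' @param reporter_amplitude mean reporter intensity scale (counts).
#' @param membrane_dye_level peak membrane-dye intensity (counts).
#' @param elongation_amplitude peak major/minor axis ratio (>= 1; 1 = none).
#' @param elongation_phase_lag temporal shift of the elongation cycle, s.
#' @param psf_sigma Gaussian PSF SD in px (0 = none).
#' @param gaussian_sd Gaussian read-noise SD (counts).
#' @param poisson_scale photon-count scaling for Poisson shot noise
#'   (0 = none; counts per intensity unit).
#' @param seed integer seed for the per-call noise generator.
#' @return A `liposome_scene_spec` list.
#' @export
liposome_scene_spec <- function(image_size = c(96L, 96L), pixel_size = 0.13,
                                frame_interval = 2, n_frames = 75L,
                                center = NULL, radius = 3.2,
                                membrane_width = 3, mode = "pulsing",
                                period = 50, reporter_amplitude = 200,
                                membrane_dye_level = 400,
                                elongation_amplitude = 1,
                                elongation_phase_lag = 0, psf_sigma = 1,
                                gaussian_sd = 0, poisson_scale = 0,
                                seed = 1L) {
  mode <- match.arg(mode, c("none", "static_membrane", "pulsing",
                            "pole_to_pole", "circling"))
  center <- center %||% (image_size + 1) / 2
  r_px <- radius / pixel_size
  if (2 * r_px >= min(image_size))
    stop("liposome diameter (", round(2 * r_px), " px) does not fit in the image")
  if (mode %in% c("pulsing", "pole_to_pole", "circling") &&
      period <= 2 * frame_interval)
    stop("period must exceed twice the frame interval (Nyquist)")
  if (elongation_amplitude < 1)
    stop("elongation_amplitude must be >= 1")
  if (membrane_width >= r_px)
    stop("membrane ring thicker than the liposome radius")
  spec <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
               frame_interval = frame_interval, n_frames = as.integer(n_frames),
               center = center, radius = radius,
               membrane_width = membrane_width, mode = mode, period = period,
               reporter_amplitude = reporter_amplitude,
               membrane_dye_level = membrane_dye_level,
               elongation_amplitude = elongation_amplitude,
               elongation_phase_lag = elongation_phase_lag,
               psf_sigma = psf_sigma, gaussian_sd = gaussian_sd,
               poisson_scale = poisson_scale, seed = as.integer(seed))
  class(spec) <- "liposome_scene_spec"
  spec
}

# Apply PSF blur then mixed Poisson/Gaussian noise to one frame.
apply_noise <- function(frame, psf_sigma, gaussian_sd, poisson_scale) {
  if (psf_sigma > 0)
    frame <- convolve2d(frame, gaussian_kernel(max(7, ceiling(6 * psf_sigma)),
                                               psf_sigma))
  if (poisson_scale > 0)
    frame <- matrix(rpois(length(frame), pmax(frame, 0) * poisson_scale),
                    nrow(frame)) / poisson_scale
  if (gaussian_sd > 0)
    frame <- frame + rnorm(length(frame), sd = gaussian_sd)
  frame
}

#' Render a synthetic liposome movie with ground truth
#'
#' Produces a two-channel calibrated stack (channel 1: membrane dye ring,
#' constant up to noise; channel 2: reporter partitioned between ring and
#' lumen according to the oscillation mode) plus per-frame ground truth. The
#' liposome outline is an area-preserving ellipse with semi-axes
#' `r * sqrt(e)` and `r / sqrt(e)` whose axis ratio `e(t)` oscillates with the
#' scene period, shifted by `elongation_phase_lag`. In noiseless scenes the
#' total reporter signal (membrane + lumen) is conserved exactly across
#' frames.
#'
#' @param spec a [liposome_scene_spec].
#' @return list with elements `stack` ([image_stack]), and `truth`: logical
#'   mask array (y, x, t), per-frame `membrane_fraction`, `elongation`,
#'   `area_px`, `time_s`, and the generating `mode` and `period`.
#' @export
render_liposome_movie <- function(spec) {
  stopifnot(inherits(spec, "liposome_scene_spec"))
  ny <- spec$image_size[1L]; nx <- spec$image_size[2L]
  nt <- spec$n_frames
  r_px <- spec$radius / spec$pixel_size
  sig_r <- spec$membrane_width / 2
  yy <- matrix(rep(seq_len(ny), nx), ny) - spec$center[1L]
  xx <- matrix(rep(seq_len(nx), each = ny), ny) - spec$center[2L]
  d <- sqrt(xx^2 + yy^2)
  phi <- atan2(yy, xx)
  tvec <- (seq_len(nt) - 1) * spec$frame_interval
  w <- 2 * pi / spec$period

  memb_frac <- switch(spec$mode,
    none            = rep(0, nt),
    static_membrane = rep(1, nt),
    pulsing         = 0.5 + 0.45 * cos(w * tvec),
    pole_to_pole    = rep(0.7, nt),
    circling        = rep(0.7, nt))
  elong <- if (spec$elongation_amplitude > 1) {
    1 + (spec$elongation_amplitude - 1) *
      (1 - cos(w * (tvec - spec$elongation_phase_lag))) / 2
  } else rep(1, nt)

  data <- array(0, c(ny, nx, 2L, nt))
  masks <- array(FALSE, c(ny, nx, nt))
  area_px <- numeric(nt)
  m_tot <- spec$reporter_amplitude * pi * r_px^2

  with_seed(spec$seed, {
    for (i in seq_len(nt)) {
      e <- elong[i]
      a <- r_px * sqrt(e); b <- r_px / sqrt(e)
      # radius of the (possibly elliptical) contour at each pixel's angle
      rc <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
      mask <- d <= rc
      ring <- exp(-(d - rc)^2 / (2 * sig_r^2))
      masks[, , i] <- mask
      area_px[i] <- sum(mask)

      # angular weight of the membrane-bound reporter
      wt <- switch(spec$mode,
        pole_to_pole = 1 + cos(w * tvec[i]) * cos(phi),
        circling     = 1 + cos(phi - w * tvec[i]),
        ring * 0 + 1)
      ring_w <- ring * wt
      memb_img <- if (memb_frac[i] > 0)
        memb_frac[i] * m_tot * ring_w / sum(ring_w) else ring * 0
      lumen_img <- mask * ((1 - memb_frac[i]) * m_tot / area_px[i])

      data[, , 1L, i] <- apply_noise(spec$membrane_dye_level * ring,
                                     spec$psf_sigma, spec$gaussian_sd,
                                     spec$poisson_scale)
      data[, , 2L, i] <- apply_noise(memb_img + lumen_img, spec$psf_sigma,
                                     spec$gaussian_sd, spec$poisson_scale)
    }
  })

  list(stack = image_stack(data, spec$pixel_size, spec$frame_interval),
       truth = list(masks = masks, membrane_fraction = memb_frac,
                    lumen_fraction = 1 - memb_frac, elongation = elong,
                    area_px = area_px, time_s = tvec, mode = spec$mode,
                    period = spec$period, reporter_total = m_tot))
}

#' Specification of a synthetic planar surface-wave movie
#'
#' Emulates Min-type protein waves on a supported lipid bilayer: either a
#' traveling plane wave `baseline + amplitude * (1 + cos(2*pi*(u - v*t)/
#' lambda))/2` (with `u` the coordinate along the propagation direction) or a
#' standing wave whose fixed spatial pattern oscillates with period `period`.
#' Optional small-scale speckle (a static Gaussian-correlated texture drawn
#' once per movie) emulates a stable cytoskeletal network superimposed on
#' the wave, as seen in cytoskeletal co-reconstitutions; per-frame Gaussian
#' and Poisson noise model the camera.
#'
#' @param image_size c(ny, nx) in px.
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @param n_frames number of frames.
#' @param kind `"traveling"` or `"standing"`.
#' @param wavelength um.
#' @param velocity um/s (traveling waves).
#' @param period s (standing waves; traveling waves imply
#'   `wavelength / velocity`).
#' @param direction propagation direction in degrees (0 = along +x).
#' @param amplitude peak-to-peak wave amplitude (counts).
#' @param baseline background intensity (counts).
#' @param psf_sigma Gaussian PSF SD in px.
#' @param gaussian_sd Gaussian noise SD (counts).
#' @param poisson_scale Poisson shot-noise scale (0 = none).
#' @param speckle_amplitude SD of the speckle component (counts, 0 = none).
#' @param speckle_scale correlation length of the speckle in px.
#' @param seed integer seed.
#' @return An `slb_wave_spec` list.
#' @export
slb_wave_spec <- function(image_size = c(256L, 256L), pixel_size = 1,
                          frame_interval = 2, n_frames = 150L,
                          kind = "traveling", wavelength = 40,
                          velocity = 0.5, period = 47, direction = 0,
                          amplitude = 100, baseline = 50, psf_sigma = 1,
                          gaussian_sd = 0, poisson_scale = 0,
                          speckle_amplitude = 0, speckle_scale = 2,
                          seed = 1L) {
  kind <- match.arg(kind, c("traveling", "standing"))
  if (wavelength <= 2 * pixel_size)
    stop("wavelength must exceed two pixels")
  if (kind == "traveling" && velocity <= 0) stop("velocity must be positive")
  if (kind == "standing" && period <= 2 * frame_interval)
    stop("period must exceed twice the frame interval (Nyquist)")
  spec <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
               frame_interval = frame_interval, n_frames = as.integer(n_frames),
               kind = kind, wavelength = wavelength, velocity = velocity,
               period = period, direction = direction, amplitude = amplitude,
               baseline = baseline, psf_sigma = psf_sigma,
               gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
               speckle_amplitude = speckle_amplitude,
               speckle_scale = speckle_scale, seed = as.integer(seed))
  class(spec) <- "slb_wave_spec"
  spec
}

#' Render a synthetic planar-wave movie
#'
#' @param spec an [slb_wave_spec].
#' @return A single-channel [image_stack].
#' @export
render_slb_movie <- function(spec) {
  stopifnot(inherits(spec, "slb_wave_spec"))
  ny <- spec$image_size[1L]; nx <- spec$image_size[2L]
  nt <- spec$n_frames
  th <- spec$direction * pi / 180
  xu <- (matrix(rep(seq_len(nx), each = ny), ny) - 1) * spec$pixel_size
  yu <- (matrix(rep(seq_len(ny), nx), ny) - 1) * spec$pixel_size
  u <- xu * cos(th) + yu * sin(th)
  data <- array(0, c(ny, nx, 1L, nt))
  with_seed(spec$seed, {
    speckle <- NULL
    if (spec$speckle_amplitude > 0) {
      # static small-scale texture (e.g. a stable cytoskeletal network)
      sp <- matrix(rnorm(ny * nx), ny)
      sp <- convolve2d(sp, gaussian_kernel(
        max(7, ceiling(6 * spec$speckle_scale)), spec$speckle_scale))
      speckle <- spec$speckle_amplitude * sp / sd(sp)
    }
    for (i in seq_len(nt)) {
      tt <- (i - 1) * spec$frame_interval
      frame <- if (spec$kind == "traveling") {
        spec$baseline + spec$amplitude *
          (1 + cos(2 * pi * (u - spec$velocity * tt) / spec$wavelength)) / 2
      } else {
        spec$baseline + spec$amplitude *
          (1 + cos(2 * pi * u / spec$wavelength)) / 2 *
          (1 + cos(2 * pi * tt / spec$period)) / 2
      }
      if (!is.null(speckle)) frame <- frame + speckle
      data[, , 1L, i] <- apply_noise(frame, spec$psf_sigma, spec$gaussian_sd,
                                     spec$poisson_scale)
    }
  })
  image_stack(data, spec$pixel_size, spec$frame_interval)
}

#' Simulate noisy expression-kinetics time courses
#'
#' Draws replicate time courses from the sigmoid expression model
#' `y(t) = k' + k * t^n / (t^n + K^n)` with additive Gaussian noise,
#' reproducible from `seed`. This is the generator used in parameter-recovery
#' experiments for cell-free expression kinetics.
#'
#' @param model a [kinetic_model].
#' @param timepoints strictly increasing non-negative times, minutes.
#' @param noise_sd Gaussian noise SD, uM (>= 0).
#' @param n_replicates replicates per time point.
#' @param seed integer seed.
#' @return data.frame with columns `time_min`, `conc_uM`, `replicate`.
#' @export
simulate_kinetics <- function(model, timepoints, noise_sd = 1,
                              n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"))
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be non-negative and strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- sigmoid_conc(timepoints, model)
  out <- data.frame(
    time_min = rep(timepoints, times = n_replicates),
    conc_uM = rep(mu, times = n_replicates),
    replicate = rep(seq_len(n_replicates), each = length(timepoints)))
  if (noise_sd > 0)
    out$conc_uM <- with_seed(seed,
      out$conc_uM + rnorm(nrow(out), sd = noise_sd))
  out
}
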