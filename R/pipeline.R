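#' Pipeline configuration
#'
#' Collects calibration and all stage parameters of the liposome analysis
#' pipeline with their defaults, validating ranges. The configuration plus
#' the input stack and initial seed fully determine the pipeline output.
#'
#' @param pixel_size um/px (> 0).
#' @param frame_interval s/frame (> 0).
#' @param membrane_channel,reporter_channel channel indices.
#' @param bg_radius disk radius for background correction, px.
#' @param n_orientations ridge-filter orientations over 180 degrees.
#' @param shrink_factor seed-propagation erosion factor.
#' @param band_width membrane band width for intensity traces, px.
#' @param smooth_size,smooth_sigma reporter smoothing kernel support/SD, px.
#' @param min_prominence autocorrelation peak prominence threshold.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_size, frame_interval,
                            membrane_channel = 1L, reporter_channel = 2L,
                            bg_radius = 4, n_orientations = 12L,
                            shrink_factor = 0.15, band_width = 3,
                            smooth_size = 10L, smooth_sigma = 1.2,
                            min_prominence = 0.3) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (bg_radius < 1) stop("bg_radius must be >= 1")
  if (n_orientations < 1) stop("n_orientations must be >= 1")
  if (shrink_factor <= 0 || shrink_factor >= 1)
    stop("shrink_factor must be in (0, 1)")
  if (band_width < 1) stop("band_width must be >= 1")
  if (smooth_sigma <= 0) stop("smooth_sigma must be positive")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 membrane_channel = as.integer(membrane_channel),
                 reporter_channel = as.integer(reporter_channel),
                 bg_radius = bg_radius,
                 n_orientations = as.integer(n_orientations),
                 shrink_factor = shrink_factor, band_width = band_width,
                 smooth_size = as.integer(smooth_size),
                 smooth_sigma = smooth_sigma,
                 min_prominence = min_prominence),
            class = "pipeline_config")
}

#' Run the liposome analysis pipeline end to end
#'
#' Tracks the liposome through the membrane-dye channel, smooths the
#' reporter channel, extracts the perimeter kymograph, membrane/lumen
#' intensity traces and the shape time series (area, elongation, normalized
#' perimeter), and classifies the oscillation mode. The result is
#' deterministic given the stack, seed and configuration; `provenance`
#' records every parameter and the package version.
#'
#' @param stack a two-channel [image_stack].
#' @param seed_mask logical seed matrix for frame 1.
#' @param config a [pipeline_config].
#' @return list with `masks`, `stats`, `kymograph`, `traces`, `shape`,
#'   `mode`, `provenance`.
#' @export
run_pipeline <- function(stack, seed_mask, config) {
  stopifnot(inherits(stack, "image_stack"), inherits(config, "pipeline_config"))
  track <- track_liposome(stack, seed_mask,
                          channel = config$membrane_channel,
                          bg_radius = config$bg_radius,
                          n_orientations = config$n_orientations,
                          shrink_factor = config$shrink_factor)
  nt <- n_frames(stack)
  smoothed <- lapply(seq_len(nt), function(i)
    smooth_reporter(get_frame(stack, i, config$reporter_channel),
                    config$smooth_size, config$smooth_sigma))
  paths <- lapply(track$masks, perimeter_path)
  kymo <- build_kymograph(paths, smoothed, config$pixel_size,
                          config$frame_interval)
  traces <- membrane_lumen_traces(track$masks, smoothed, config$band_width)
  traces$time_s <- (traces$frame - 1) * config$frame_interval
  shape <- data.frame(
    frame = seq_len(nt),
    time_s = (seq_len(nt) - 1) * config$frame_interval,
    area_px2 = track$stats$area_px2,
    area_um2 = track$stats$area_px2 * config$pixel_size^2,
    elongation = vapply(track$masks, elongation, 0),
    norm_perimeter_um = vapply(track$masks, normalized_perimeter, 0,
                               pixel_size = config$pixel_size))
  mode <- tryCatch(classify_oscillation_mode(kymo),
                   error = function(e)
                     list(label = "undetermined", period_s = NA_real_,
                          phase_profile = NULL, direction = NA_integer_))
  list(masks = track$masks, stats = track$stats, kymograph = kymo,
       traces = traces, shape = shape, mode = mode,
       provenance = list(
         package = "minwave",
         version = as.character(utils::packageVersion("minwave")),
         config = unclass(config)))
}

#' Write pipeline results to CSV / TIFF files
#'
#' Writes `traces.csv` (frame, time_s, membrane_mean, lumen_mean),
#' `shape.csv` (frame, time_s, area_um2, elongation, norm_perimeter_um),
#' `kymograph.csv` and `kymograph.tif` (32-bit float), and `masks.tif`
#' (8-bit labels). Outputs are byte-identical across reruns with the same
#' inputs and configuration.
#'
#' @param result output of [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_traces <- file.path(dir, "traces.csv")
  utils::write.csv(result$traces, f_traces, row.names = FALSE)
  f_shape <- file.path(dir, "shape.csv")
  utils::write.csv(result$shape, f_shape, row.names = FALSE)
  f_kcsv <- file.path(dir, "kymograph.csv")
  utils::write.csv(as.data.frame(result$kymograph$data), f_kcsv,
                   row.names = FALSE)
  f_ktif <- file.path(dir, "kymograph.tif")
  k <- result$kymograph$data
  rng <- range(k)
  tiff::writeTIFF(if (diff(rng) > 0) (k - rng[1L]) / diff(rng) else k * 0,
                  f_ktif, bits.per.sample = 32L)
  f_mtif <- file.path(dir, "masks.tif")
  tiff::writeTIFF(lapply(result$masks, function(m) (m > 0) * 1), f_mtif,
                  bits.per.sample = 8L)
  invisible(c(f_traces, f_shape, f_kcsv, f_ktif, f_mtif))
}
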