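# Small programmatic fixtures shared across test files.

make_disk_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  yy <- matrix(rep(seq_len(n), n), n) - center[1]
  xx <- matrix(rep(seq_len(n), each = n), n) - center[2]
  yy^2 + xx^2 <= radius^2
}

make_ellipse_mask <- function(n, a, b, angle = 0,
                              center = c((n + 1) / 2, (n + 1) / 2)) {
  yy <- matrix(rep(seq_len(n), n), n) - center[1]
  xx <- matrix(rep(seq_len(n), each = n), n) - center[2]
  u <- xx * cos(angle) + yy * sin(angle)
  v <- -xx * sin(angle) + yy * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

# Thin bright ring (radial Gaussian) on a flat background.
make_ring_frame <- function(n, radius, width = 2, amplitude = 100,
                            background = 0,
                            center = c((n + 1) / 2, (n + 1) / 2)) {
  yy <- matrix(rep(seq_len(n), n), n) - center[1]
  xx <- matrix(rep(seq_len(n), each = n), n) - center[2]
  d <- sqrt(yy^2 + xx^2)
  background + amplitude * exp(-(d - radius)^2 / (2 * (width / 2)^2))
}

# Straight bright 1-px line through the center at `angle_deg` from the
# x (column) axis.
make_line_frame <- function(n, angle_deg, amplitude = 1) {
  th <- angle_deg * pi / 180
  f <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  for (s in seq(-n, n, by = 0.25)) {
    y <- round(c0 + s * sin(th)); x <- round(c0 + s * cos(th))
    if (y >= 1 && y <= n && x >= 1 && x <= n) f[y, x] <- amplitude
  }
  f
}

# Default small liposome scene used by segmentation/kymograph tests.
small_scene <- function(mode = "pulsing", n_frames = 75L, seed = 1L, ...) {
  render_liposome_movie(liposome_scene_spec(mode = mode, n_frames = n_frames,
                                            seed = seed, ...))
}

# Interior-disk seed derived from a ground-truth mask.
seed_from_mask <- function(mask, shrink = 8) {
  EBImage::erode(mask * 1, minwave:::disk_kernel(shrink)) > 0
}

iou_masks <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) NA_real_ else sum(a & b) / u
}
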