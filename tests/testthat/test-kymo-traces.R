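test_that("reporter smoothing preserves constants and the impulse response", {
  expect_equal(smooth_reporter(matrix(3, 32, 32)), matrix(3, 32, 32),
               tolerance = 1e-9)
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  out <- smooth_reporter(imp)
  expect_equal(out[11:21, 11:21],
               minwave:::gaussian_kernel(10, 1.2)[1:11, 1:11],
               tolerance = 1e-12)
  # matches direct convolution on seeded noise
  set.seed(3)
  noise <- matrix(rnorm(32 * 32), 32)
  expect_equal(smooth_reporter(noise),
               oracle_convolve(noise, minwave:::gaussian_kernel(10, 1.2)),
               tolerance = 1e-12)
  # white-noise SD reduction ~ the 2-D Gaussian filter factor 1/(2*sigma*sqrt(pi))
  set.seed(4)
  big <- matrix(rnorm(200 * 200), 200)
  expect_equal(sd(smooth_reporter(big)[20:180, 20:180]),
               1 / (2 * 1.2 * sqrt(pi)), tolerance = 0.05)
})

test_that("perimeter paths trace closed clockwise boundaries", {
  one <- matrix(FALSE, 8, 8); one[4, 5] <- TRUE
  expect_equal(nrow(perimeter_path(one)), 1L)
  expect_error(perimeter_path(matrix(FALSE, 4, 4)), "empty")

  sq <- matrix(FALSE, 16, 16); sq[4:13, 4:13] <- TRUE
  p <- perimeter_path(sq)
  expect_equal(nrow(p), 36L)                 # boundary of a 10x10 square
  expect_equal(p[1L, ], c(y = 4L, x = 4L))   # topmost-then-leftmost start
  # clockwise in image orientation: positive shoelace sum with y down
  shoelace <- sum(p[, "x"] * c(p[-1L, "y"], p[1L, "y"]) -
                  c(p[-1L, "x"], p[1L, "x"]) * p[, "y"])
  expect_gt(shoelace, 0)
  # closed 8-connected chain
  steps <- cbind(diff(c(p[, 1L], p[1L, 1L])), diff(c(p[, 2L], p[1L, 2L])))
  expect_true(all(pmax(abs(steps[, 1L]), abs(steps[, 2L])) == 1))

  disk <- make_disk_mask(32, 10)
  pd <- perimeter_path(disk)
  # boundary-count oracle: mask pixels with a 4-neighbor outside (the
  # contour an 8-connected trace follows)
  n_boundary <- 0
  for (i in 2:31) for (j in 2:31)
    if (disk[i, j] && !(disk[i - 1, j] && disk[i + 1, j] &&
                        disk[i, j - 1] && disk[i, j + 1]))
      n_boundary <- n_boundary + 1
  expect_equal(nrow(pd), n_boundary)
  expect_lt(abs(nrow(pd) - 2 * pi * 10) / (2 * pi * 10), 0.15)
})

test_that("kymograph rows are linearly resampled to the longest path", {
  expect_equal(minwave:::resample_linear(c(0, 1, 2, 3, 4), 9),
               seq(0, 4, by = 0.5))
  expect_equal(minwave:::resample_linear(c(2, 5, 1), 3), c(2, 5, 1))
  set.seed(7)
  v <- runif(13)
  expect_equal(minwave:::resample_linear(v, 31), oracle_resample(v, 31),
               tolerance = 1e-12)
  # no overshoot: linear interpolation is range-bounded
  r <- minwave:::resample_linear(v, 57)
  expect_gte(min(r), min(v)); expect_lte(max(r), max(v))

  # constant movie gives a constant kymograph
  masks <- replicate(4, make_disk_mask(32, 9), simplify = FALSE)
  paths <- lapply(masks, perimeter_path)
  frames <- replicate(4, matrix(6, 32, 32), simplify = FALSE)
  k <- build_kymograph(paths, frames, 1, 2)
  expect_true(all(k$data == 6))
  expect_equal(ncol(k$data), max(vapply(paths, nrow, 0L)))
})

test_that("membrane and lumen traces separate ring and interior signal", {
  n <- 48
  mask <- make_disk_mask(n, 15)
  ring <- make_ring_frame(n, 15, width = 2, amplitude = 90)
  tr <- membrane_lumen_traces(list(mask), list(ring))
  expect_gt(tr$membrane_mean, 10 * max(tr$lumen_mean, 1e-9))
  # uniform fill: membrane ~ lumen
  fill <- mask * 42
  tr2 <- membrane_lumen_traces(list(mask), list(fill))
  expect_equal(tr2$membrane_mean, tr2$lumen_mean, tolerance = 1e-9)
  # liposome too small for the band: flagged
  tiny <- make_disk_mask(16, 3)
  tr3 <- membrane_lumen_traces(list(tiny), list(tiny * 1))
  expect_true(tr3$lumen_empty)
})

test_that("pulsing scenes give anticorrelated membrane and lumen traces", {
  sc <- small_scene(mode = "pulsing", n_frames = 50L, gaussian_sd = 5,
                    seed = 6L)
  masks <- lapply(seq_len(50), function(i) sc$truth$masks[, , i])
  frames <- lapply(seq_len(50),
                   function(i) smooth_reporter(get_frame(sc$stack, i, 2)))
  tr <- membrane_lumen_traces(masks, frames)
  expect_lt(cor(tr$membrane_mean, tr$lumen_mean), -0.5)
})

test_that("elongation agrees with moment oracles on reference shapes", {
  expect_equal(elongation(make_disk_mask(64, 20)), 1, tolerance = 0.02)
  expect_equal(elongation(make_ellipse_mask(64, 20, 10)), 2, tolerance = 0.05)
  strip <- matrix(FALSE, 4, 110); strip[2, 4:103] <- TRUE
  el <- elongation(strip)
  expect_true(is.finite(el) && el > 50)
  expect_equal(el, oracle_elongation(strip), tolerance = 1e-12)
  # rotation invariance within 2% on rasterized ellipses
  base <- elongation(make_ellipse_mask(96, 24, 12))
  for (ang in c(pi / 6, pi / 4, pi / 3)) {
    rot <- elongation(make_ellipse_mask(96, 24, 12, angle = ang))
    expect_lt(abs(rot - base) / base, 0.02, label = sprintf("angle %.2f", ang))
  }
  expect_error(elongation(matrix(FALSE, 4, 4)), "area")
})

test_that("normalized perimeter follows the equal-area-circle formula", {
  expect_equal(normalized_perimeter(make_disk_mask(64, 17)) /
                 (pi * sqrt(4 * sum(make_disk_mask(64, 17)) / pi)), 1)
  m <- matrix(TRUE, 10, 10)   # area exactly 100 px^2
  expect_equal(normalized_perimeter(m), pi * sqrt(400 / pi), tolerance = 1e-12)
  expect_equal(normalized_perimeter(m, pixel_size = 2),
               pi * sqrt(4 * 400 / pi), tolerance = 1e-12)
  expect_error(normalized_perimeter(matrix(FALSE, 4, 4)), "empty")
  # isoperimetric inequality: normalized perimeter <= true ellipse perimeter
  a <- 24; b <- 12
  ell <- make_ellipse_mask(96, a, b)
  h <- ((a - b) / (a + b))^2
  ramanujan <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_lt(normalized_perimeter(ell), ramanujan)
})

test_that("elongation phase lag recovers imposed shifts", {
  tt <- seq(0, 238, by = 2)
  e <- sin(2 * pi * tt / 60)
  expect_equal(elongation_phase_lag(e, e, 2), 0)
  lagged <- sin(2 * pi * (tt - 15) / 60)   # lumen delayed by 15 s
  expect_equal(elongation_phase_lag(e, lagged, 2), 15, tolerance = 2)
  expect_error(elongation_phase_lag(rep(1, 120), e, 2), "constant")
})
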