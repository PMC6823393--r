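test_that("per-pixel autocorrelation recovers sinusoid periods", {
  # all pixels oscillate at 47 s with dt 1 s
  nt <- 200L
  arr <- array(0, c(4, 4, 1, nt))
  for (i in seq_len(nt)) arr[, , 1, i] <- 10 + 5 * cos(2 * pi * (i - 1) / 47)
  st <- image_stack(arr, 1, 1)
  expect_equal(standing_wave_period(st), 47)
  # half the pixels at 40 s, half at 60 s: midpoint median = 50 s
  arr2 <- array(0, c(2, 2, 1, 200L))
  for (i in seq_len(200)) {
    tt <- i - 1
    arr2[, 1, 1, i] <- cos(2 * pi * tt / 40)
    arr2[, 2, 1, i] <- cos(2 * pi * tt / 60)
  }
  expect_equal(standing_wave_period(image_stack(arr2, 1, 1)), 50)
  # constant movie: no variance anywhere
  expect_error(standing_wave_period(image_stack(array(3, c(4, 4, 1, 50)),
                                                1, 1)), "variance")
})

test_that("the period estimator is unbiased on noiseless sinusoids", {
  for (period_frames in c(20L, 25L, 40L)) {
    nt <- 8L * period_frames
    arr <- array(0, c(3, 3, 1, nt))
    for (i in seq_len(nt))
      arr[, , 1, i] <- cos(2 * pi * (i - 1) / period_frames)
    st <- image_stack(arr, 1, 2)   # 2 s frames
    expect_equal(standing_wave_period(st), 2 * period_frames,
                 label = sprintf("period %d frames", period_frames))
  }
})

test_that("line kymographs sample along and across the wave", {
  mov <- render_slb_movie(slb_wave_spec(image_size = c(64L, 128L),
                                        pixel_size = 1, frame_interval = 2,
                                        n_frames = 60L, kind = "traveling",
                                        wavelength = 40, velocity = 0.5,
                                        psf_sigma = 0))
  k <- line_kymograph(mov, c(32, 1), c(32, 128))
  est <- estimate_traveling_wave(k, smooth_sigma = 0)
  expect_equal(est$velocity_um_s, 0.5, tolerance = 0.03)
  expect_equal(est$wavelength_um, 40, tolerance = 2)
  # perpendicular to propagation: constant along space, oscillating in time
  kp <- line_kymograph(mov, c(2, 64), c(62, 64))
  expect_lt(max(apply(kp$data, 1, sd)), 1e-6)
  expect_gt(sd(kp$data[, 30]), 1)
  expect_error(line_kymograph(mov, c(5, 5), c(5, 5)), "degenerate")
})

test_that("preblur suppresses small-scale speckle much more than the wave", {
  expect_identical(preblur(image_stack(array(1:16, c(4, 4, 1, 1)), 1, 1), 0),
                   image_stack(array(1:16, c(4, 4, 1, 1)), 1, 1))
  # impulse response is the blur kernel (support capped to the frame: 47 px)
  imp <- array(0, c(49, 49, 1, 1)); imp[25, 25, 1, 1] <- 1
  bl <- preblur(image_stack(imp, 1, 1), 8)
  expect_equal(bl$data[2:48, 2:48, 1, 1], minwave:::gaussian_kernel(47, 8),
               tolerance = 1e-9)
  # sinusoid attenuation follows the Gaussian transfer function
  n <- 128
  x <- matrix(rep(0:(n - 1), each = n), n)
  for (lam in c(4, 40)) {
    wav <- array(cos(2 * pi * x / lam), c(n, n, 1, 1))
    out <- preblur(image_stack(wav, 1, 1), 8)
    att <- max(abs(out$data[, , 1, 1][, 40:90]))
    expect_equal(att, exp(-2 * pi^2 * 64 / lam^2), tolerance = 0.05,
                 label = sprintf("lambda %d", lam))
  }
  # speckle (period 4 px) attenuated >= 10x more than the wave (40 px)
  expect_gt(exp(-2 * pi^2 * 64 / 40^2) / exp(-2 * pi^2 * 64 / 4^2), 10)
})

test_that("stripe geometry is recovered from constructed kymographs", {
  # moving stripes: v = 0.5 um/s (1 px/frame at dt 2), spacing 40 um
  nt <- 100L; nx <- 200L
  x <- matrix(rep(0:(nx - 1), each = nt), nt)
  y <- matrix(rep(0:(nt - 1), nx), nt)
  k <- structure(list(data = 50 + 50 * cos(2 * pi * (x - y) / 40),
                      pixel_size = 1, frame_interval = 2, origin = "synthetic"),
                 class = "kymograph")
  est <- estimate_traveling_wave(k, smooth_sigma = 0)
  expect_equal(est$wavelength_um, 40, tolerance = 2)
  expect_equal(est$velocity_um_s, 0.5, tolerance = 0.03)
  expect_equal(est$period_s, est$wavelength_um / est$velocity_um_s)
  # stationary stripes: zero velocity, wavelength = spacing
  k0 <- structure(list(data = 50 + 50 * cos(2 * pi * x / 40),
                       pixel_size = 1, frame_interval = 2, origin = "synthetic"),
                  class = "kymograph")
  est0 <- estimate_traveling_wave(k0, smooth_sigma = 0)
  expect_equal(est0$velocity_um_s, 0, tolerance = 0.01)
  expect_equal(est0$wavelength_um, 40, tolerance = 2)
  # blank kymograph
  kb <- structure(list(data = matrix(1, 50, 50), pixel_size = 1,
                       frame_interval = 2, origin = "synthetic"),
                  class = "kymograph")
  expect_error(estimate_traveling_wave(kb), "blank")
})

test_that("wavelength and velocity are recovered across a parameter grid", {
  for (lam in c(20, 40, 80)) for (v in c(0.25, 0.5, 1.0)) {
    width <- max(160L, as.integer(4 * lam))
    spec <- slb_wave_spec(image_size = c(24L, width), pixel_size = 1,
                          frame_interval = 2, n_frames = 100L,
                          kind = "traveling", wavelength = lam, velocity = v,
                          amplitude = 100, baseline = 50, gaussian_sd = 20,
                          seed = 100L + lam + round(100 * v))
    mov <- render_slb_movie(spec)
    k <- line_kymograph(mov, c(12, 1), c(12, width))
    est <- estimate_traveling_wave(k)
    lbl <- sprintf("lambda %g v %g", lam, v)
    expect_lt(abs(est$wavelength_um - lam) / lam, 0.10, label = lbl)
    expect_lt(abs(est$velocity_um_s - v) / v, 0.10, label = lbl)
  }
})

test_that("oscillation modes are classified from perimeter kymographs", {
  build_kymo <- function(mode, seed = 11L) {
    sc <- small_scene(mode = mode, n_frames = 75L, seed = seed)
    masks <- lapply(seq_len(75), function(i) sc$truth$masks[, , i])
    frames <- lapply(seq_len(75),
                     function(i) smooth_reporter(get_frame(sc$stack, i, 2)))
    build_kymograph(lapply(masks, perimeter_path), frames, 0.13, 2)
  }
  for (mode in c("pulsing", "pole_to_pole", "circling")) {
    cl <- classify_oscillation_mode(build_kymo(mode))
    expect_equal(cl$label, mode)
    expect_equal(cl$period_s, 50, tolerance = 5)
  }
  # the generator's circling mode advances the hotspot clockwise (in image
  # orientation), the same sense as the clockwise perimeter path
  expect_equal(classify_oscillation_mode(build_kymo("circling"))$direction, 1L)
  # a non-oscillating kymograph is undetermined
  flat <- structure(list(data = matrix(rnorm(75 * 60), 75), pixel_size = 0.13,
                         frame_interval = 2, origin = "synthetic"),
                    class = "kymograph")
  expect_equal(classify_oscillation_mode(flat)$label, "undetermined")
})
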