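test_that("spec constructors validate their invariants", {
  expect_error(liposome_scene_spec(radius = 10, image_size = c(64L, 64L),
                                   pixel_size = 0.13), "fit")
  expect_error(liposome_scene_spec(period = 3, frame_interval = 2), "Nyquist")
  expect_error(liposome_scene_spec(elongation_amplitude = 0.9), ">= 1")
  expect_error(liposome_scene_spec(membrane_width = 30), "thicker")
  expect_error(slb_wave_spec(wavelength = 1.5, pixel_size = 1), "two pixels")
  expect_error(slb_wave_spec(kind = "standing", period = 3,
                             frame_interval = 2), "Nyquist")
  m <- kinetic_model(0, 10, 100, 3)
  expect_error(simulate_kinetics(m, c(10, 5, 20)), "increasing")
  expect_error(simulate_kinetics(m, c(0, 10), noise_sd = -1), "noise_sd")
})

test_that("pulsing ground truth oscillates with the requested period", {
  spec <- liposome_scene_spec(mode = "pulsing", period = 50,
                              frame_interval = 2, n_frames = 200L,
                              gaussian_sd = 0, seed = 1L)
  sc <- render_liposome_movie(spec)
  f <- sc$truth$membrane_fraction
  # exact period by construction: shifting by one period reproduces the trace
  shift <- 50 / 2
  expect_equal(f[seq_len(200 - shift)], f[(shift + 1):200], tolerance = 1e-12)
  # and no smaller shift does
  expect_gt(max(abs(f[seq_len(190)] - f[11:200])), 0.1)
})

test_that("static membrane scenes have constant traces and empty lumen signal", {
  sc <- small_scene(mode = "static_membrane", n_frames = 10L)
  masks <- lapply(seq_len(10), function(i) sc$truth$masks[, , i])
  frames <- lapply(seq_len(10), function(i) get_frame(sc$stack, i, 2))
  tr <- membrane_lumen_traces(masks, frames)
  expect_lt(diff(range(tr$membrane_mean)) / mean(tr$membrane_mean), 1e-9)
  # all reporter on the ring: lumen mean far below membrane mean
  expect_lt(max(tr$lumen_mean), 0.05 * min(tr$membrane_mean))
})

test_that("reporter mass is conserved in noiseless scenes", {
  for (mode in c("pulsing", "pole_to_pole", "circling")) {
    sc <- small_scene(mode = mode, n_frames = 30L)
    sums <- vapply(seq_len(30), function(i) sum(get_frame(sc$stack, i, 2)), 0)
    expect_lt(diff(range(sums)) / mean(sums), 1e-9, label = mode)
  }
})

test_that("rendered elongation matches the moment oracle at its peak", {
  spec <- liposome_scene_spec(mode = "pulsing", elongation_amplitude = 1.2,
                              n_frames = 50L, seed = 2L)
  sc <- render_liposome_movie(spec)
  el <- vapply(seq_len(50), function(i) oracle_elongation(sc$truth$masks[, , i]),
               0)
  expect_equal(max(el), 1.2, tolerance = 0.02)
  expect_equal(min(el), 1.0, tolerance = 0.02)
})

test_that("identical spec and seed give bit-identical stacks", {
  s1 <- render_liposome_movie(liposome_scene_spec(gaussian_sd = 10,
                                                  poisson_scale = 0.5,
                                                  n_frames = 5L, seed = 9L))
  s2 <- render_liposome_movie(liposome_scene_spec(gaussian_sd = 10,
                                                  poisson_scale = 0.5,
                                                  n_frames = 5L, seed = 9L))
  expect_identical(s1$stack$data, s2$stack$data)
  w1 <- render_slb_movie(slb_wave_spec(image_size = c(32L, 32L),
                                       n_frames = 5L, gaussian_sd = 5,
                                       speckle_amplitude = 10, seed = 4L))
  w2 <- render_slb_movie(slb_wave_spec(image_size = c(32L, 32L),
                                       n_frames = 5L, gaussian_sd = 5,
                                       speckle_amplitude = 10, seed = 4L))
  expect_identical(w1$data, w2$data)
})

test_that("zero-amplitude wave movies are flat at baseline", {
  mov <- render_slb_movie(slb_wave_spec(image_size = c(32L, 32L),
                                        amplitude = 0, baseline = 77,
                                        psf_sigma = 0, n_frames = 4L))
  expect_equal(as.vector(mov$data), rep(77, length(mov$data)))
})

test_that("noiseless standing waves autocorrelate at their period", {
  mov <- render_slb_movie(slb_wave_spec(image_size = c(24L, 24L),
                                        pixel_size = 1, frame_interval = 1,
                                        n_frames = 200L, kind = "standing",
                                        wavelength = 11, period = 47,
                                        psf_sigma = 0))
  expect_equal(standing_wave_period(mov), 47)
})

test_that("traveling-wave crests advance at the requested speed", {
  # lambda 40 um, v 0.5 um/s, 1 um/px, dt 2 s: crest moves 1 px per frame
  mov <- render_slb_movie(slb_wave_spec(image_size = c(16L, 128L),
                                        pixel_size = 1, frame_interval = 2,
                                        n_frames = 20L, kind = "traveling",
                                        wavelength = 40, velocity = 0.5,
                                        psf_sigma = 0))
  crest <- vapply(seq_len(20), function(i) {
    row <- get_frame(mov, i, 1)[8, 30:80]
    which.max(row)
  }, 0L)
  expect_equal(diff(crest), rep(1L, 19))
})

test_that("kinetic simulation reproduces the model at zero noise", {
  m <- kinetic_model(0.7, 19, 120, 3)
  sim <- simulate_kinetics(m, c(0, 120, 120e6), noise_sd = 0,
                           n_replicates = 1L)
  expect_equal(sim$conc_uM[1], 0.7)                      # t = 0 -> baseline
  expect_equal(sim$conc_uM[2], 0.7 + 19 / 2)             # t = K -> midpoint
  expect_equal(sim$conc_uM[3], 0.7 + 19, tolerance = 1e-6)  # asymptote
  noisy <- simulate_kinetics(m, c(0, 60, 120), noise_sd = 1,
                             n_replicates = 2L, seed = 5L)
  expect_identical(noisy,
                   simulate_kinetics(m, c(0, 60, 120), noise_sd = 1,
                                     n_replicates = 2L, seed = 5L))
})
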