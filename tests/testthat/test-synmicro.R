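# Synthetic-microscopy generator: determinism, noise statistics, geometry
# and ground-truth fidelity.

near_zero_noise <- noise_model(photon_scale = 1e6, read_sigma = 0,
                               background_offset = 0)

test_that("identical configs generate bit-identical scenes", {
  cfg <- scene_config("hela_field", tag_ratio = 2, seed = 42)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth$objects, s2$truth$objects)

  bcfg <- scene_config("sted_timeseries", seed = 9, n_frames = 8)
  expect_identical(generate_bleach_series(bcfg)$stack$data,
                   generate_bleach_series(bcfg)$stack$data)
})

test_that("apply_noise has the configured first moments and is seeded", {
  img <- matrix(50, 120, 120)  # > 1e4 pixels
  out <- apply_noise(img, noise_model(1, 0, 0), seed = 1)
  se <- sqrt(50 / length(img))
  expect_lt(abs(mean(out) - 50), 3 * se)

  # Poisson mean identity with a background offset
  img2 <- matrix(20, 120, 120)
  out2 <- apply_noise(img2, noise_model(1, 0, 5), seed = 2)
  expect_lt(abs(mean(out2) - 25), 3 * sqrt(25 / length(img2)))

  # infinite-photon limit reproduces the input
  out3 <- apply_noise(img, near_zero_noise, seed = 3)
  expect_lt(max(abs(out3 - img)), 0.1)

  # determinism and error contract
  expect_identical(apply_noise(img, noise_model(), 7),
                   apply_noise(img, noise_model(), 7))
  expect_error(apply_noise(matrix(-1, 4, 4), noise_model(), 1),
               "non-negative")
})

test_that("egg-chamber field of view matches the pixel geometry", {
  cfg <- scene_config("egg_chamber", pixel_size_nm = 19.53,
                      image_shape = c(512, 512), seed = 1)
  fov_um <- cfg$image_shape[1] * cfg$pixel_size_nm / 1000
  expect_equal(fov_um, 10.0, tolerance = 0.01)
  sc <- generate_scene(cfg)
  expect_equal(dim(sc$stack$data)[1:2], c(512L, 512L))
})

test_that("noiseless structures have the ground-truth plateau intensity", {
  cfg <- scene_config("hela_field", seed = 5, psf_fwhm_nm = 60,
                      noise = near_zero_noise, intensity_cv = 0)
  sc <- generate_scene(cfg)
  marker <- sc$truth$noiseless$marker
  amp <- sc$truth$objects$mean_intensity
  # interior plateau: pixels well inside a blob reach the full amplitude
  expect_equal(max(marker), max(amp), tolerance = 1e-6)
  # pre-PSF structure is exactly the amplitude inside blobs
  struct <- sc$truth$structure$marker
  expect_setequal(unique(round(struct[struct > 0], 9)),
                  round(unique(amp[amp > 0]), 9))
})

test_that("dye-channel brightness ratio equals the configured tag ratio", {
  cfg <- scene_config("hela_field", tag_ratio = 4.5, seed = 11,
                      intensity_cv = 0)
  pr <- generate_condition_pair(cfg)
  m_halo <- mean(pr$halo$truth$objects$mean_intensity)
  m_snap <- mean(pr$snap$truth$objects$mean_intensity)
  expect_equal(m_halo / m_snap, 4.5, tolerance = 1e-12)
})

test_that("bleach series follows the half-life law and inverts exactly", {
  cfg <- scene_config("sted_timeseries", seed = 3, n_frames = 10,
                      frame_interval_s = 10, bleach_halflife_s = 50)
  sc <- generate_bleach_series(cfg)
  # frame at t = 50 s has expected fraction exactly 1/2
  expect_equal(sc$truth$decay[6], 0.5)
  # log-linear regression on the noiseless expected curve recovers the
  # configured half-life to numerical precision
  roi <- sc$truth$labels > 0
  base <- mean(sc$truth$noiseless$marker[roi])
  means <- base * sc$truth$decay
  slope <- unname(coef(lm(log2(means) ~ sc$truth$times))[2])
  expect_equal(-1 / slope, 50, tolerance = 1e-6)

  # no-bleaching sentinel: all frames share the expectation
  cfg2 <- scene_config("sted_timeseries", seed = 3, n_frames = 5,
                       bleach_halflife_s = Inf)
  expect_true(all(generate_bleach_series(cfg2)$truth$decay == 1))
  # a series needs at least two frames
  cfg3 <- scene_config("sted_timeseries", seed = 3, n_frames = 1)
  expect_error(generate_bleach_series(cfg3), "n_frames")
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config("hela_field", image_shape = c(32, 32)))
  expect_error(scene_config("hela_field", tag_ratio = 0))
  expect_error(scene_config("hela_field", transfected_fraction = 1.5))
  expect_error(scene_config("bogus_scene"))
  expect_error(noise_model(photon_scale = 0))
})

test_that("scenes round-trip through TIFF + sidecar", {
  cfg <- scene_config("hela_field", seed = 2, image_shape = c(64, 64),
                      transfected_fraction = 1)
  sc <- generate_scene(cfg)
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, "demo")
  expect_true(all(file.exists(paths)))
  back <- read_image_stack(paths[["tiff"]])
  expect_equal(back$data, sc$stack$data, tolerance = 1e-6)
  expect_equal(back$pixel_size_nm, sc$stack$pixel_size_nm)
  expect_identical(back$channel_names, sc$stack$channel_names)
})
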