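# Line profiles, FWHM fits and donut (peak-separation) fits.

gauss_ridge <- function(nr = 41, nc = 81, center = 41, sigma_px = 5,
                        amp = 100, base = 10) {
  v <- base + amp * exp(-((1:nc) - center)^2 / (2 * sigma_px^2))
  matrix(rep(v, each = nr), nr, nc)
}

test_that("profiles sample geometry and positions correctly", {
  flat <- extract_profile(matrix(4, 30, 30), c(10, 2), c(10, 28),
                          pixel_size_nm = 25)
  expect_true(all(flat$values == 4))

  # 100 one-pixel steps at 19.53 nm span 1953 nm
  pr <- extract_profile(matrix(0, 20, 120), c(10, 5), c(10, 105),
                        pixel_size_nm = 19.53)
  expect_equal(length(pr$positions_nm), 101L)
  expect_equal(max(pr$positions_nm), 1953, tolerance = 1e-9)

  # a cross-section through a Gaussian ridge is the 1-D Gaussian
  img <- gauss_ridge(sigma_px = 5)
  pr2 <- extract_profile(img, c(21, 11), c(21, 71), pixel_size_nm = 10)
  expected <- 10 + 100 * exp(-(pr2$positions_nm / 10 + 11 - 41)^2 / 50)
  expect_equal(pr2$values, expected, tolerance = 1e-9)

  expect_error(extract_profile(img, c(5, 5), c(5, 5)), "identical")
  expect_error(extract_profile(img, c(0, 5), c(5, 5)), "inside")
})

test_that("FWHM fits recover sigma * 2.3548 and are shift/scale invariant", {
  # sigma = 42.47 nm at 10-nm pixels -> FWHM 100.0 nm
  img <- gauss_ridge(sigma_px = 4.247)
  pr <- extract_profile(img, c(21, 11), c(21, 71), pixel_size_nm = 10)
  fit <- fit_fwhm(pr)
  expect_equal(fit$fwhm_nm, 100, tolerance = 1e-3)
  expect_gt(fit$r2, 0.999)

  # invariance under intensity scaling and baseline shift
  pr_mod <- pr; pr_mod$values <- 3.7 * pr$values + 55
  expect_equal(fit_fwhm(pr_mod)$fwhm_nm, fit$fwhm_nm, tolerance = 1e-6)

  # noisy recovery at SNR ~ 10 with a well-sampled baseline: median error
  # over seeded replicates under 5%
  imgw <- gauss_ridge(nc = 161, center = 81, sigma_px = 4.247)
  prw <- extract_profile(imgw, c(21, 11), c(21, 151), pixel_size_nm = 10)
  set.seed(21)
  errs <- replicate(9, {
    pr_noisy <- prw
    pr_noisy$values <- prw$values + rnorm(length(prw$values), 0, 10)
    abs(fit_fwhm(pr_noisy)$fwhm_nm - 100) / 100
  })
  expect_lt(median(errs), 0.05)

  expect_error(fit_fwhm(list(positions_nm = 1:5, values = 1:5)), "7")
})

test_that("fitted FWHM is monotone in the generator PSF width", {
  obj <- matrix(0, 41, 161); obj[, 78:84] <- 100  # 7-px wide bar
  fw <- sapply(c(3, 5, 8, 12), function(s) {
    img <- gaussian_blur(obj, s)
    fit_fwhm(extract_profile(img, c(21, 21), c(21, 141), pixel_size_nm = 10))$fwhm_nm
  })
  expect_true(all(diff(fw) > 0))
})

test_that("noiseless twin peaks are recovered at their separation", {
  x_nm <- seq(0, 400, by = 10)
  y <- 5 + 80 * (exp(-(x_nm - 150)^2 / (2 * 30^2)) +
                   exp(-(x_nm - 250)^2 / (2 * 30^2)))
  pr <- list(positions_nm = x_nm, values = y, step_nm = 10)
  fit <- fit_donut(pr)
  expect_equal(fit$model, "double_gaussian")
  expect_equal(fit$peak_separation_nm, 100, tolerance = 0.01)

  # mirror-reversed profile: identical separation
  pr_rev <- list(positions_nm = x_nm, values = rev(y), step_nm = 10)
  expect_equal(fit_donut(pr_rev)$peak_separation_nm, fit$peak_separation_nm,
               tolerance = 1e-6)
})

test_that("generator pits resolve under STED but not confocal PSF", {
  sted <- generate_scene(scene_config("clathrin_field", seed = 4,
                                      condition = "halo"))
  ob <- sted$truth$objects[1, ]
  pr <- extract_profile(get_frame(sted$stack, 1, "marker"),
                        c(ob$row, ob$col - 14), c(ob$row, ob$col + 14),
                        width_px = 3, pixel_size_nm = 10)
  fit <- fit_donut(pr)
  expect_true(fit$resolved)
  expect_lt(abs(fit$peak_separation_nm - 100), 10)

  conf <- generate_scene(scene_config("clathrin_field", seed = 4,
                                      condition = "halo", psf_fwhm_nm = 250))
  ob2 <- conf$truth$objects[1, ]
  pr2 <- extract_profile(get_frame(conf$stack, 1, "marker"),
                         c(ob2$row, ob2$col - 25), c(ob2$row, ob2$col + 25),
                         width_px = 3, pixel_size_nm = 10)
  expect_false(fit_donut(pr2)$resolved)
})
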