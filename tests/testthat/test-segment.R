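# DoG filtering, Renyi-entropy thresholding, component compositing and
# signal/background measurement, cross-checked against independent oracles.

test_that("DoG cancels constants and reproduces the sampled kernel difference", {
  expect_true(all(abs(difference_of_gaussians(matrix(7.3, 48, 48))) < 1e-10))

  # impulse response equals the direct 2-D kernel difference
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  out <- difference_of_gaussians(img, sigma = 2, k = 1.5)
  g2d <- function(s) {
    k1 <- dnorm(-20:20, sd = s); k1 <- k1 / sum(k1)
    outer(k1, k1)
  }
  expect_lt(max(abs(out - (g2d(2) - g2d(3)))), 1e-4)
})

test_that("the coarse DoG kernel has sigma k*sigma (5.6 px at defaults)", {
  img <- matrix(0, 61, 61); img[31, 31] <- 1
  out <- difference_of_gaussians(img, sigma = 4, k = 1.4)
  g2d <- function(s) {
    k1 <- dnorm(-30:30, sd = s); k1 <- k1 / sum(k1)
    outer(k1, k1)
  }
  expect_lt(max(abs(out - (g2d(4) - g2d(5.6)))), 1e-4)
})

test_that("Renyi threshold separates a perfectly bimodal histogram", {
  p <- numeric(256); p[11] <- 0.5; p[201] <- 0.5  # bins 10 and 200, 0-based
  for (m in c("renyi_combined", "renyi_single")) {
    t_idx <- renyi_entropy_threshold(p, m)
    expect_gt(t_idx, 11 - 1)
    expect_lt(t_idx, 201)
  }
  expect_error(renyi_entropy_threshold(c(0, 1, 0, 0)), "degenerate")
})

test_that("single-alpha threshold equals the exhaustive-search oracle", {
  set.seed(101)
  for (i in 1:120) {
    n <- sample(4:32, 1)
    p <- rgamma(n, 0.7)
    p[sample(n, sample(0:(n - 3), 1))] <- 0  # sparse histograms too
    if (sum(p > 0) < 2) p[1:2] <- 1
    p <- p / sum(p)
    alpha <- sample(c(0.5, 1, 2, runif(1, 0.2, 3)), 1)
    expect_identical(renyi_entropy_threshold(p, "renyi_single", alpha),
                     renyi_threshold_oracle(p, alpha),
                     label = sprintf("case %d (n=%d, alpha=%.3f)", i, n, alpha))
  }
})

test_that("the threshold objective respects histogram symmetry", {
  # mirror equivariance: thresholding the reversed histogram mirrors the cut
  set.seed(7)
  for (i in 1:20) {
    p <- rgamma(16, 1) + 0.05; p <- p / sum(p)
    n <- length(p)
    t_fwd <- renyi_entropy_threshold(p, "renyi_single", alpha = 1)
    t_rev <- renyi_entropy_threshold(rev(p), "renyi_single", alpha = 1)
    expect_lte(abs(t_rev - (n - t_fwd)), 1)  # 1-bin slack for ties
  }
  # a symmetric unimodal histogram cuts within one bin of its midpoint
  p <- dbinom(0:15, 15, 0.5)
  t_idx <- renyi_entropy_threshold(p, "renyi_single", alpha = 1)
  expect_lte(abs(t_idx - 8), 1)
  expect_identical(t_idx, renyi_threshold_oracle(p, 1))
})

test_that("minimum area is inclusive and areas convert to um^2", {
  m <- matrix(0, 60, 80)
  m[3:22, 3:27] <- 1          # 20 x 25 = 500 px
  m[30:49, 40:64] <- 1; m[30, 40] <- 0  # 499 px
  res <- extract_signal_mask(m, threshold = 0.5, min_area_px = 500,
                             pixel_size_nm = 180.2)
  expect_equal(nrow(res$regions), 1L)
  expect_equal(res$regions$area_px, 500L)
  expect_equal(res$regions$area_um2, 16.24, tolerance = 1e-3)
  expect_equal(sum(res$mask), sum(res$regions$area_px))  # area conservation
})

test_that("component labeling equals a flood-fill oracle", {
  set.seed(33)
  for (i in 1:12) {
    m <- matrix(runif(40 * 40) < 0.4, 40, 40)
    res <- extract_signal_mask(m * 1, threshold = 0.5, min_area_px = 1)
    expect_true(same_partition(res$labels, flood_fill_label(m, 8)),
                label = sprintf("random mask %d", i))
  }
  # diagonal-only touching pixels are one 8-connected component
  d <- matrix(0, 5, 5); d[2, 2] <- 1; d[3, 3] <- 1; d[4, 2] <- 1
  expect_equal(nrow(extract_signal_mask(d, 0.5, 1)$regions), 1L)
})

test_that("signal/background measurement is exact piecewise arithmetic", {
  img <- matrix(4, 20, 20); mask <- matrix(FALSE, 20, 20)
  mask[5:10, 5:10] <- TRUE; img[mask] <- 10
  m <- measure_signal_background(img, mask)
  expect_equal(c(m$signal_mean, m$background_mean, m$corrected_signal),
               c(10, 4, 6))

  # half-plane mask over a column gradient: analytic means
  g <- matrix(rep(1:40, each = 30), 30, 40)
  left <- col(g) <= 20
  m2 <- measure_signal_background(g, left)
  expect_equal(m2$signal_mean, mean(1:20))
  expect_equal(m2$background_mean, mean(21:40))

  # constant image: corrected signal is exactly zero
  half10 <- col(matrix(0, 10, 10)) <= 5
  m3 <- measure_signal_background(matrix(3.7, 10, 10), half10)
  expect_equal(m3$corrected_signal, 0)

  expect_error(measure_signal_background(g, g > 100), "empty")
  expect_error(measure_signal_background(g, g > -1), "full")
})

test_that("quantification is shift-invariant and scale-equivariant", {
  cfg <- scene_config("egg_chamber", image_shape = c(256, 256), seed = 21)
  sc <- generate_scene(cfg)
  img <- get_frame(sc$stack, 1, "marker")
  q0 <- quantify_image(img, pixel_size_nm = 180)
  q_shift <- quantify_image(img + 50, pixel_size_nm = 180)
  expect_identical(q_shift$mask, q0$mask)
  expect_equal(q_shift$corrected_signal, q0$corrected_signal, tolerance = 1e-9)
  q_scale <- quantify_image(img * 2, pixel_size_nm = 180)  # exact in binary fp
  expect_identical(q_scale$mask, q0$mask)
  expect_equal(q_scale$corrected_signal, 2 * q0$corrected_signal)
})

test_that("uniform images yield the empty-result flag, not an error", {
  q <- quantify_image(matrix(5, 128, 128), pixel_size_nm = 100)
  expect_true(q$empty)
  expect_true(is.na(q$corrected_signal))
})

test_that("the pipeline recovers egg-chamber fold ratios across a grid", {
  # end-to-end ratio recovery for tag ratios {1, 2, 4.5, 9} at default noise
  for (r in c(1, 2, 4.5, 9)) {
    vals <- list(halo = c(), snap = c())
    for (i in 1:10) {
      cfg <- scene_config("egg_chamber", image_shape = c(256, 256),
                          tag_ratio = r, seed = 3000 + 100 * i)
      pr <- generate_condition_pair(cfg)
      for (cond in c("halo", "snap")) {
        q <- quantify_image(get_frame(pr[[cond]]$stack, 1, "marker"),
                            pixel_size_nm = 180)
        vals[[cond]] <- c(vals[[cond]], q$corrected_signal)
      }
    }
    est <- mean(vals$halo) / mean(vals$snap)
    expect_lt(abs(est - r) / r, 0.10, label = sprintf("tag_ratio %g", r))
  }
})
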