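# Per-cell detection, co-labeling classification, efficiency, distribution
# fits, fold ratios and t-tests.

test_that("reporter-cell detection finds exactly the generated cells", {
  cfg <- scene_config("hela_field", seed = 3, condition = "halo")
  sc <- generate_scene(cfg)
  det <- detect_reporter_cells(get_frame(sc$stack, 1, "reporter"),
                               pixel_size_nm = 300)
  expect_equal(det$n_cells, nrow(sc$truth$objects))

  # blank reporter channel: no cells, no error
  blank <- detect_reporter_cells(matrix(0, 128, 128))
  expect_equal(blank$n_cells, 0L)
  expect_equal(nrow(measure_cells(blank, matrix(1, 128, 128))), 0L)
})

test_that("co-labeling classification follows the k-sigma rule", {
  expect_false(classify_colabeled(0, c(10, 2), k_sigma = 3))
  expect_true(classify_colabeled(6.1, c(10, 2), k_sigma = 3))
  expect_identical(classify_colabeled(c(-1, 5, 7), c(0, 2)),
                   c(FALSE, FALSE, TRUE))
  # scale invariance: rescaling intensities and stats together is a no-op
  x <- c(3, 8, 15); st <- c(1, 4)
  expect_identical(classify_colabeled(10 * x, 10 * st),
                   classify_colabeled(x, st))
  expect_warning(classify_colabeled(5, c(0, 0)), "degenerate")
})

test_that("cells drawn from the background have a <=1% false-positive rate", {
  set.seed(12)
  bg_sd <- 4; cell_area <- 100
  cell_means <- rnorm(1e4, 0, bg_sd / sqrt(cell_area))  # corrected ~ 0
  fp <- mean(classify_colabeled(cell_means, c(0, bg_sd), k_sigma = 3))
  expect_lte(fp, 0.01)
})

test_that("labeling efficiency is exact bounded arithmetic", {
  recs <- data.frame(colabeled = c(rep(TRUE, 688), rep(FALSE, 740 - 688)))
  eff <- labeling_efficiency(recs)
  expect_equal(eff$n_reporter_positive, 740)
  expect_equal(eff$efficiency_pct, 100 * 688 / 740)
  expect_equal(round(eff$efficiency_pct), 93)
  expect_equal(labeling_efficiency(rep(FALSE, 10))$efficiency_pct, 0)
  expect_equal(labeling_efficiency(rep(TRUE, 10))$efficiency_pct, 100)
  expect_error(labeling_efficiency(logical(0)), "no reporter-positive")
})

test_that("Gaussian intensity fits recover parameters and flag mixtures", {
  set.seed(5)
  fit <- fit_intensity_distribution(rnorm(500, 100, 15))
  expect_lt(abs(fit$mu - 100), 2)
  expect_lt(abs(fit$sigma - 15), 2)
  expect_true(fit$unimodal_ok)

  expect_error(fit_intensity_distribution(rep(5, 50)), "zero variance")
  expect_error(fit_intensity_distribution(1:5), "at least 10")

  mix <- c(rnorm(300, 10, 1), rnorm(300, 30, 1))
  expect_false(fit_intensity_distribution(mix)$unimodal_ok)
})

test_that("fold ratios are exact, antisymmetric and bootstrapped", {
  expect_equal(fold_ratio(c(2, 4), c(1, 1), seed = 1)$ratio, 3)
  same <- fold_ratio(c(5, 6, 7), c(5, 6, 7), seed = 2)
  expect_equal(same$ratio, 1)
  expect_true(same$ci[1] <= 1 && same$ci[2] >= 1)

  set.seed(9)
  a <- rlnorm(30, 2, 0.3); b <- rlnorm(25, 1.5, 0.3)
  expect_equal(fold_ratio(a, b, seed = 3)$ratio *
                 fold_ratio(b, a, seed = 3)$ratio, 1, tolerance = 1e-12)
  expect_error(fold_ratio(c(1, 2), c(-3, 1)), "positive")
})

test_that("the unpaired t-test matches the closed-form pooled statistic", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- unpaired_t_test(a, b)
  orc <- student_t_oracle(a, b)
  expect_equal(res$t_stat, orc$t, tolerance = 1e-12)
  expect_equal(res$df, orc$df)
  expect_equal(res$p_two_tailed, orc$p, tolerance = 1e-12)

  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    r <- unpaired_t_test(x, y); o <- student_t_oracle(x, y)
    expect_equal(r$t_stat, o$t, tolerance = 1e-10)
    expect_equal(r$p_two_tailed, o$p, tolerance = 1e-10)
  }
})

test_that("t-test conventions, stars and the Welch variant behave", {
  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_two_tailed, 1)
  expect_equal(same$stars, "ns")

  # zero variance in both groups with equal means: p = 1 by convention
  flat <- unpaired_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(flat$p_two_tailed, 1)
  expect_error(unpaired_t_test(c(2, 2), c(3, 3)), "zero variance")

  set.seed(4)
  far <- unpaired_t_test(rnorm(20, 0), rnorm(20, 10))
  expect_equal(far$stars, "****")

  # Welch and Student agree for equal variances and sizes
  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)
  st <- unpaired_t_test(a, b, welch = FALSE)
  we <- unpaired_t_test(a, b, welch = TRUE)
  expect_equal(st$t_stat, we$t_stat, tolerance = 1e-9)
  expect_equal(st$p_two_tailed, we$p_two_tailed, tolerance = 1e-9)

  expect_equal(significance_stars(0.2), "ns")
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.009), "**")
  expect_equal(significance_stars(0.0009), "***")
  expect_equal(significance_stars(0.00009), "****")
  expect_equal(significance_stars(0.05), "ns")  # boundary falls on ns side
})

test_that("per-cell fold recovery holds across a tag-ratio grid", {
  errs <- c()
  for (r in c(1, 2, 2.8, 6)) {
    vals <- list(halo = c(), snap = c())
    for (i in 1:6) {
      cfg <- scene_config("hela_field", tag_ratio = r, seed = 4000 + 97 * i)
      pr <- generate_condition_pair(cfg)
      for (cond in c("halo", "snap")) {
        sc <- pr[[cond]]
        det <- detect_reporter_cells(get_frame(sc$stack, 1, "reporter"),
                                     pixel_size_nm = 300)
        cells <- measure_cells(det, get_frame(sc$stack, 1, "marker"))
        vals[[cond]] <- c(vals[[cond]], cells$marker_corrected)
      }
    }
    est <- mean(vals$halo) / mean(vals$snap)
    errs <- c(errs, abs(est - r) / r)
  }
  expect_lt(median(errs), 0.10)
  expect_lt(max(errs), 0.15)
})
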