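test_that("cross-correlation: hand values, symmetry, affine invariance", {
  a <- matrix(0:3, 2); b <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(cross_correlation(a, b), 0.8, tolerance = 1e-12)
  expect_equal(cross_correlation(b, a), 0.8, tolerance = 1e-12)
  expect_equal(cross_correlation(a, a), 1)
  expect_equal(cross_correlation(a, -a + 7), -1)
  expect_equal(cross_correlation(2.5 * a + 3, b),
               cross_correlation(a, b), tolerance = 1e-12)
  expect_warning(z <- cross_correlation(matrix(1, 2, 2), b), "zero-variance")
  expect_identical(z, 0)
  expect_error(cross_correlation(a, matrix(0, 3, 3)), "dimensions")
})

test_that("edge resolution recovers closed forms on synthetic edges", {
  # Gaussian-blurred step: resolution = 2 * qnorm(0.75) * blur_sd pixels
  x <- 0:199
  for (blur_sd in c(3, 5, 8)) {
    prof <- pnorm((100 - x) / blur_sd)     # analytic blurred step, bright left
    expect_equal(edge_resolution(prof, pixel_nm = 1),
                 2 * qnorm(0.75) * blur_sd, tolerance = 0.02)
    # pixel size scales the answer; reversal does not change it
    expect_equal(edge_resolution(prof, pixel_nm = 50),
                 50 * edge_resolution(prof, 1), tolerance = 1e-12)
    expect_equal(edge_resolution(rev(prof), 1), edge_resolution(prof, 1),
                 tolerance = 1e-9)
    expect_equal(edge_resolution(3 + 10 * prof, 1), edge_resolution(prof, 1),
                 tolerance = 1e-9)
  }
  expect_equal(2 * qnorm(0.75), 1.349, tolerance = 1e-3)
  # linear ramp of width w: the 0.75 and 0.25 levels are w/2 apart
  ramp <- c(rep(1, 30), seq(1, 0, length.out = 20), rep(0, 30))
  expect_equal(edge_resolution(ramp, 1), (20 - 1) / 2, tolerance = 0.05)
  # ideal step: both crossings inside one sample gap
  step <- c(rep(1, 40), rep(0, 40))
  expect_lte(edge_resolution(step, 1), 1)
})

test_that("edge resolution rejects profiles without a clean single edge", {
  expect_error(edge_resolution(rep(1, 30)), "flat")
  wiggly <- c(rep(1, 20), 0.2, 0.9, rep(0, 20))
  expect_error(edge_resolution(wiggly, 1), "exactly once")
})

test_that("averaged edge profiles feed the estimator from images", {
  set.seed(6)
  img <- matrix(rep(pnorm((60 - (1:120)) / 5), 40), 120, 40) +
    matrix(rnorm(120 * 40, 0, 0.01), 120, 40)
  prof <- edge_profile(img, "x")
  expect_length(prof, 120)
  expect_equal(edge_resolution(prof, pixel_nm = 50), 50 * 1.349 * 5,
               tolerance = 0.05)
})

test_that("history summary extracts the convergence landmarks", {
  h <- data.frame(cycle = 1:3, T = c(10, 1, 0.1),
                  error = c(10, 5, 2.5),
                  cc_pos1 = c(0, 0.5, 0.9), cc_pos2 = c(0, 0.6, 0.96))
  s <- history_summary(h)
  expect_equal(s$initial_error, 10)
  expect_equal(s$final_error, 2.5)
  expect_equal(s$half_life_cycle, 2)   # first cycle with E <= E0/2
  expect_equal(s$final_T, 0.1)
  expect_equal(s$final_cc_min, 0.9)
  expect_equal(s$final_cc_mean, 0.93)
  s1 <- history_summary(h[1, ])
  expect_equal(s1$initial_error, s1$final_error)
  expect_error(history_summary(h[0, ]), "non-empty")
})

test_that("history plot builds without evaluation errors", {
  h <- data.frame(cycle = 1:5, T = 10 * 0.5^(0:4), error = 32 / 2^(0:4),
                  cc_pos1 = seq(0, 0.9, length.out = 5),
                  cc_pos2 = seq(0, 0.95, length.out = 5))
  p <- plot_history(h)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
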