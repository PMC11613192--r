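test_that("sphere phantom: binary film-tangent spheres of the right volume", {
  ph <- sphere_phantom(grid = c(48, 48, 24), n = 2, diameter_um = 4,
                       voxel_um = 0.25, seed = 3)
  r <- attr(ph, "radius_vox")        # 8 voxels
  expect_equal(r, 8)
  expect_setequal(unique(as.vector(ph$values)), c(0, 1))
  expect_equal(sum(ph$values), 2 * 4 / 3 * pi * r^3, tolerance = 0.05)
  centers <- attr(ph, "centers")
  expect_true(all(centers[, 3] == r))          # tangent to the film
  # zero spheres: empty volume
  ph0 <- sphere_phantom(n = 0)
  expect_true(all(ph0$values == 0))
  # determinism
  expect_identical(sphere_phantom(seed = 5)$values,
                   sphere_phantom(seed = 5)$values)
  expect_error(sphere_phantom(grid = c(16, 16, 16), n = 40, diameter_um = 3,
                              voxel_um = 0.25),
               "non-overlapping|exceeds")
})

test_that("emulsion shell phantom: bright rim around a dim interior", {
  ph <- emulsion_shell_phantom(grid = c(48, 48, 48), inner_um = 3.5,
                               outer_um = 4.5, voxel_um = 0.25)
  ri <- 14; ro <- 18
  rim_n <- sum(ph$values == 1.0)
  expect_equal(rim_n, 4 / 3 * pi * (ro^3 - ri^3), tolerance = 0.1)
  expect_setequal(unique(as.vector(ph$values)), c(0, 0.2, 1.0))
  # central slice through the center shows an annulus
  ctr <- attr(ph, "center")
  sl <- ph$values[, , round(ctr[3]) + 1]
  mid <- round(ctr[1]) + 1
  expect_equal(sl[mid, round(ctr[2]) + 1], 0.2)      # interior dim
  expect_true(any(sl[mid, ] == 1.0))                 # rim bright
  # degenerate: inner == outer leaves no rim
  phd <- emulsion_shell_phantom(inner_um = 4, outer_um = 4)
  expect_equal(sum(phd$values == 1.0), 0)
  expect_error(emulsion_shell_phantom(inner_um = 5, outer_um = 4), "inner")
})

test_that("cell phantom: four intensity levels, granules in cytoplasm", {
  ph <- cell_phantom(seed = 2)
  expect_setequal(unique(as.vector(ph$values)), c(0, 0.3, 0.5, 1.0))
  expect_identical(cell_phantom(seed = 2)$values, ph$values)
  expect_false(identical(cell_phantom(seed = 3)$values, ph$values))
  # no granules: two-compartment ellipsoid only
  ph0 <- cell_phantom(n_granules = 0)
  expect_setequal(unique(as.vector(ph0$values)), c(0, 0.3, 0.5))
  # granule centers keep clear of the nucleus
  ctr <- c(23.5, 23.5, 10)
  gc <- attr(ph, "granule_centers")
  d <- sqrt(rowSums(sweep(gc, 2, ctr)^2))
  expect_true(all(d >= (1.4 + 0.5) / 0.25 - 1e-9))
  expect_error(cell_phantom(nucleus_um = 3, axes_um = c(3, 3, 2.5)),
               "nucleus")
})

test_that("tilt-series simulator adds calibrated Gaussian noise", {
  ph <- cell_phantom(grid = c(36, 36, 36), axes_um = c(3, 2.5, 2),
                     nucleus_um = 1, n_granules = 5, seed = 1)
  clean <- simulate_tilt_series(ph, noise_sd = 0)
  expect_identical(clean$images, project_all(ph)$images)
  expect_identical(clean$provenance, "simulated")
  noisy <- simulate_tilt_series(ph, noise_sd = 0.05, seed = 4)
  rng <- max(vapply(clean$images, max, 0)) - min(vapply(clean$images, min, 0))
  resid <- unlist(noisy$images) - unlist(clean$images)
  expect_gt(length(resid), 1e4)
  expect_equal(sd(resid), 0.05 * rng, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(resid)))
  # different seeds: same clean component, different noise
  noisy2 <- simulate_tilt_series(ph, noise_sd = 0.05, seed = 5)
  expect_false(identical(noisy$images, noisy2$images))
  expect_error(simulate_tilt_series(ph, noise_sd = -1), ">= 0")
})
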