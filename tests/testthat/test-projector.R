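test_that("uniform volume projects to value times depth at zero tilt", {
  v <- volume_grid(array(0.7, c(6, 5, 9)))
  expect_equal(project(v, 0), matrix(0.7 * 9, 6, 5))
})

test_that("a unit voxel projects to unit mass at the sheared position", {
  for (ang in c(0, 3.3, 27.2, -15.9)) {
    v <- volume_grid(array(0, c(16, 16, 16)))
    v$values[5, 9, 7] <- 1
    im <- project(v, ang)
    expect_equal(sum(im), 1, tolerance = 1e-12)
    centroid <- sum(im * (row(im) - 1)) / sum(im)
    expect_equal(centroid, 4 + 6 * tan(ang * pi / 180), tolerance = 1e-12)
    expect_equal(sum(im[, 9]), 1)               # no spread along y
  }
})

test_that("projection matches the scatter-form ray-integration oracle", {
  for (seed in 1:3) {
    v <- random_volume(side = 12, seed = seed)
    for (ang in c(27.2, 9.8, -3.3, -27.2, 40)) {
      expect_equal(project(v, ang), oracle_project(v, ang),
                   tolerance = 1e-8)
    }
  }
})

test_that("projection is linear and mirror-antisymmetric", {
  v1 <- random_volume(10, 1); v2 <- random_volume(10, 2)
  v12 <- v1; v12$values <- 2 * v1$values - 3 * v2$values
  expect_equal(project(v12, 15.9),
               2 * project(v1, 15.9) - 3 * project(v2, 15.9),
               tolerance = 1e-12)
  # project(mirror_x(V), -theta) = mirror_x(project(V, theta))
  m <- project(mirror_x_vol(v1), -15.9)
  expect_equal(m, project(v1, 15.9)[10:1, ], tolerance = 1e-12)
})

test_that("mass is conserved for interior support and bounded otherwise", {
  v <- volume_grid(array(0, c(24, 8, 8)))
  v$values[10:14, 3:6, 2:5] <- runif(length(v$values[10:14, 3:6, 2:5]))
  expect_equal(sum(project(v, 0)), sum(v$values), tolerance = 1e-12)
  # support interior enough that the 27.2 deg shear stays in bounds
  expect_equal(sum(project(v, 27.2)), sum(v$values), tolerance = 1e-10)
  # a voxel sheared outside loses mass
  ve <- volume_grid(array(0, c(8, 4, 8)))
  ve$values[8, 2, 8] <- 1
  expect_lt(sum(project(ve, 27.2)), 1)
  expect_error(project(v, 90), "90")
})

test_that("project_all reprojects every position of the geometry", {
  g <- default_geometry()
  v0 <- volume_grid(array(0, c(8, 8, 8)))
  ts0 <- project_all(v0, g)
  expect_s3_class(ts0, "tilt_series")
  expect_identical(ts0$provenance, "reprojected")
  expect_true(all(vapply(ts0$images, function(im) all(im == 0), TRUE)))
  v <- random_volume(12, 4)
  ts <- project_all(v, g)
  expect_equal(ts$images[[4]], project(v, 3.3))
  expect_equal(ts$angles_deg, g$angles_deg)
  # x-mirror-symmetric volume: position k is the x-mirror of position 9-k
  vs <- v; vs$values <- v$values + v$values[12:1, , ]
  tss <- project_all(vs, g)
  for (k in 1:8)
    expect_equal(tss$images[[k]], tss$images[[9 - k]][12:1, ],
                 tolerance = 1e-12)
})

test_that("project_delta equals the difference of full projections", {
  set.seed(42)
  v <- random_volume(32, 5)
  for (ang in c(27.2, -9.8)) {
    base <- project(v, ang)
    dvals <- array(rnorm(5^3), c(5, 5, 5))
    off <- c(14L, 20L, 26L)
    delta <- voxel_delta(dvals, off)
    v2 <- apply_delta(v, delta)
    inc <- project_delta(delta, ang, dim(v))
    expect_equal(base + inc, project(v2, ang), tolerance = 1e-8)
  }
  # zero delta, single-voxel delta
  z <- voxel_delta(array(0, c(2, 2, 2)), c(1L, 1L, 1L))
  expect_true(all(project_delta(z, 15.9, c(8L, 8L, 8L)) == 0))
  s <- voxel_delta(array(3, c(1, 1, 1)), c(4L, 5L, 6L))
  inc <- project_delta(s, 27.2, c(16L, 16L, 16L))
  expect_equal(sum(inc), 3, tolerance = 1e-12)
  expect_equal(sum(inc * (row(inc) - 1)) / 3, 3 + 5 * tan(27.2 * pi / 180),
               tolerance = 1e-12)
  # out-of-bounds footprint is rejected
  expect_error(project_delta(voxel_delta(array(1, c(4, 4, 4)), c(7L, 1L, 1L)),
                             0, c(8L, 8L, 8L)),
               "out of volume bounds")
})
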