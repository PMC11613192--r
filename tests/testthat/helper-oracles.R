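# Independent oracles, deliberately written as plain triple loops so they
# share no code path with the package implementations they check.

# Scatter-form ray integration: walk every voxel, deposit its mass into the
# two image bins straddling x + z*tan(theta).
oracle_project <- function(vol, angle_deg) {
  d <- dim(vol$values)
  tn <- tan(angle_deg * pi / 180)
  out <- matrix(0, d[1], d[2])
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    v <- vol$values[x, y, z]
    if (v == 0) next
    xp <- (x - 1) + (z - 1) * tn
    f <- floor(xp)
    w <- xp - f
    if (f >= 0 && f <= d[1] - 1) out[f + 1, y] <- out[f + 1, y] + v * (1 - w)
    if (f + 1 >= 0 && f + 1 <= d[1] - 1)
      out[f + 2, y] <- out[f + 2, y] + v * w
  }
  out
}

# Double-loop residual sum of squares.
oracle_rss <- function(a, b) {
  s <- 0
  for (k in seq_along(a$images)) {
    pa <- a$images[[k]]; pb <- b$images[[k]]
    for (j in seq_len(ncol(pa))) for (i in seq_len(nrow(pa)))
      s <- s + (pa[i, j] - pb[i, j])^2
  }
  s
}

random_volume <- function(side = 8, seed = 1) {
  set.seed(seed)
  volume_grid(array(stats::rnorm(side^3), rep(side, 3)))
}

mirror_x_vol <- function(vol) {
  vol$values <- vol$values[dim(vol$values)[1]:1, , , drop = FALSE]
  vol
}

small_cell_series <- function(noise_sd = 0.02, grid = 16, seed = 1) {
  stopifnot(grid >= 12)
  ax <- c(0.40, 0.35, 0.30) * grid * 0.25   # semi-axes scale with the grid
  ph <- cell_phantom(grid = rep(grid, 3),
                     axes_um = ax, nucleus_um = 0.375,
                     n_granules = 3, granule_um = 0.2,
                     voxel_um = 0.25, seed = seed)
  simulate_tilt_series(ph, noise_sd = noise_sd, seed = seed + 1L)
}
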