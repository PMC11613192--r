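# Synthetic phantoms emulating the three imaged sample classes: polystyrene
# spheres attached to the SiN film, an emulsion droplet with a bright rim,
# and a cell with nucleus and bright intracellular granules. Higher voxel
# value = higher impedance-proxy signal (bright in amplitude images).

# Internal: squared distance field from a center, on the 0-based voxel grid.
dist2_grid <- function(dims, center0) {
  dx <- (0:(dims[1] - 1)) - center0[1]
  dy <- (0:(dims[2] - 1)) - center0[2]
  dz <- (0:(dims[3] - 1)) - center0[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
}

#' Film-attached sphere phantom
#'
#' Binary-intensity spheres (value 1) on a zero background, each tangent
#' to the support-film plane z = 0 (center depth = radius), mimicking
#' 3 um polystyrene spheres settled on the film. Lateral centers are drawn
#' uniformly; placements that would overlap an existing sphere are
#' rejected, with an error after bounded retries.
#'
#' @param grid integer length-3 voxel dimensions.
#' @param n number of spheres.
#' @param diameter_um sphere diameter in micrometres (3 for the standard
#'   polystyrene sample).
#' @param voxel_um voxel edge in micrometres.
#' @param seed integer seed (placements are deterministic given seed).
#' @param max_tries rejection-sampling budget per sphere.
#' @return a [volume_grid()].
#' @export
sphere_phantom <- function(grid = c(48, 48, 48), n = 3, diameter_um = 3,
                           voxel_um = 0.25, seed = 1, max_tries = 200) {
  r <- diameter_um / 2 / voxel_um
  if (2 * r > min(grid[1:2]) || 2 * r > grid[3])
    stop("sphere diameter exceeds the grid extent")
  set.seed(as.integer(seed))
  vals <- array(0, grid)
  centers <- matrix(NA_real_, 0, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, r, grid[1] - 1 - r)
      cy <- stats::runif(1, r, grid[2] - 1 - r)
      ctr <- c(cx, cy, r)               # tangent to the film plane z = 0
      ok <- !nrow(centers) ||
        all(sqrt(rowSums(sweep(centers, 2, ctr)^2)) >= 2 * r)
      if (ok) { centers <- rbind(centers, ctr); placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping spheres in ",
           max_tries, " tries per sphere")
    vals[dist2_grid(grid, ctr) <= r^2] <- 1
  }
  v <- volume_grid(vals, voxel_um)
  attr(v, "centers") <- centers
  attr(v, "radius_vox") <- r
  v
}

#' Emulsion-droplet shell phantom
#'
#' A droplet with a low-intensity interior and a high-intensity rim
#' between the inner and outer radii, emulating the bright high-impedance
#' contour seen at the periphery of emulsion droplets. The droplet is
#' tangent to the film plane (center depth = outer radius).
#'
#' @param grid integer length-3 voxel dimensions.
#' @param inner_um,outer_um inner and outer rim radii in micrometres
#'   (`inner_um < outer_um`).
#' @param interior,rim intensities of the interior and the rim.
#' @param voxel_um voxel edge in micrometres.
#' @return a [volume_grid()].
#' @export
emulsion_shell_phantom <- function(grid = c(48, 48, 48), inner_um = 3.5,
                                   outer_um = 4.5, interior = 0.2,
                                   rim = 1.0, voxel_um = 0.25) {
  if (inner_um > outer_um) stop("inner radius must not exceed outer radius")
  ri <- inner_um / voxel_um
  ro <- outer_um / voxel_um
  if (2 * ro > min(grid)) stop("droplet does not fit in the grid")
  ctr <- c((grid[1] - 1) / 2, (grid[2] - 1) / 2, ro)
  d2 <- dist2_grid(grid, ctr)
  vals <- array(0, grid)
  vals[d2 <= ro^2] <- interior
  vals[d2 <= ro^2 & d2 > ri^2] <- rim
  v <- volume_grid(vals, voxel_um)
  attr(v, "center") <- ctr
  v
}

#' Cell phantom with nucleus and bright granules
#'
#' An ellipsoidal cell body (intensity 0.3) resting on the film, with a
#' spherical nucleus (0.5) and `n_granules` small bright spheres (1.0)
#' placed uniformly in the cytoplasm, non-overlapping with the nucleus —
#' the morphology of a pigment cell whose melanosome-like granules image
#' as high-impedance puncta. A generated volume contains exactly the four
#' intensity levels {0, cytoplasm, nucleus, granule}.
#'
#' @param grid integer length-3 voxel dimensions.
#' @param axes_um cell ellipsoid semi-axes (x, y, z) in micrometres.
#' @param nucleus_um nucleus radius in micrometres.
#' @param n_granules number of granules.
#' @param granule_um granule radius in micrometres.
#' @param levels intensities for cytoplasm, nucleus, granules.
#' @param voxel_um voxel edge in micrometres.
#' @param seed integer seed.
#' @param max_tries placement budget per granule.
#' @return a [volume_grid()].
#' @export
cell_phantom <- function(grid = c(48, 48, 48), axes_um = c(5, 4, 2.5),
                         nucleus_um = 1.4, n_granules = 12,
                         granule_um = 0.5,
                         levels = c(cytoplasm = 0.3, nucleus = 0.5,
                                    granule = 1.0),
                         voxel_um = 0.25, seed = 1, max_tries = 400) {
  ax <- axes_um / voxel_um
  rn <- nucleus_um / voxel_um
  rg <- granule_um / voxel_um
  if (rn + rg >= min(ax)) stop("nucleus does not fit inside the cell")
  if (any(2 * ax > grid)) stop("cell ellipsoid does not fit in the grid")
  ctr <- c((grid[1] - 1) / 2, (grid[2] - 1) / 2, ax[3])  # rests on the film
  dx <- ((0:(grid[1] - 1)) - ctr[1]) / ax[1]
  dy <- ((0:(grid[2] - 1)) - ctr[2]) / ax[2]
  dz <- ((0:(grid[3] - 1)) - ctr[3]) / ax[3]
  ell <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)   # <= 1 inside the cell
  vals <- array(0, grid)
  vals[ell <= 1] <- levels[["cytoplasm"]]
  nd2 <- dist2_grid(grid, ctr)
  vals[nd2 <= rn^2] <- levels[["nucleus"]]
  set.seed(as.integer(seed))
  centers <- matrix(NA_real_, 0, 3)
  for (i in seq_len(n_granules)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      # uniform in the bounding box, accepted if the whole granule lies in
      # the cytoplasm (inside the shrunken ellipsoid, outside the nucleus)
      cand <- ctr + stats::runif(3, -1, 1) * (ax - rg)
      e <- sum(((cand - ctr) / (ax - rg))^2)
      far_nuc <- sqrt(sum((cand - ctr)^2)) >= rn + rg
      far_gr <- !nrow(centers) ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= 2 * rg)
      if (e <= 1 && far_nuc && far_gr) {
        centers <- rbind(centers, cand); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n_granules, " granules in the cytoplasm")
    vals[dist2_grid(grid, cand) <= rg^2] <- levels[["granule"]]
  }
  v <- volume_grid(vals, voxel_um)
  attr(v, "granule_centers") <- centers
  v
}

#' Simulate a noisy tilt-series acquisition of a phantom
#'
#' Instrument stand-in: forward-projects the volume at the geometry's
#' eight angles and adds i.i.d. Gaussian noise with standard deviation
#' `noise_sd` times the dynamic range (max - min) of the clean series.
#'
#' @param volume a [volume_grid()].
#' @param geometry an [electrode_geometry()][default_geometry].
#' @param noise_sd noise level as a fraction of the clean dynamic range
#'   (`>= 0`).
#' @param seed integer seed for the noise.
#' @return a [tilt_series()] with provenance `"simulated"`.
#' @export
simulate_tilt_series <- function(volume, geometry = default_geometry(),
                                 noise_sd = 0.02, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  clean <- project_all(volume, geometry)
  clean$provenance <- "simulated"
  if (noise_sd > 0) {
    rng <- max(vapply(clean$images, max, 0)) -
           min(vapply(clean$images, min, 0))
    set.seed(as.integer(seed))
    clean$images <- lapply(clean$images, function(im)
      im + stats::rnorm(length(im), 0, noise_sd * rng))
  }
  clean
}
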