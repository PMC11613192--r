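#' Forward-project a volume at one tilt angle
#'
#' Parallel-beam shear-sum projection along direction
#' (sin theta, 0, cos theta): each z-slice of the volume is shifted
#' laterally along x by `z * tan(theta)` with linear interpolation (mass
#' shifted outside the lateral bounds is dropped), then all slices are
#' summed over z. The tilt axis is y, perpendicular to the electrode-array
#' axis x, matching the 1D linear-array geometry; no resampling occurs
#' along y.
#'
#' By default no path-length weighting is applied (the projection is a
#' shear-plus-sum, not an arc-length integral); with
#' `pathlength_weighting = TRUE` the image is scaled by `1 / cos(theta)`,
#' the per-voxel ray path length at tilt theta. This is a global per-angle
#' scale and is absorbed by image normalization in the reconstruction.
#'
#' @param volume a [volume_grid()].
#' @param angle_deg tilt angle in degrees, `|angle| < 90`.
#' @param pathlength_weighting logical; scale by `1/cos(theta)`.
#' @return numeric matrix of dimension `nx` x `ny` (same lateral grid as
#'   the volume).
#' @examples
#' v <- volume_grid(array(1, c(8, 8, 4)))
#' all(project(v, 0) == 4)  # uniform volume: every pixel = value * depth
#' @export
project <- function(volume, angle_deg, pathlength_weighting = FALSE) {
  stopifnot(inherits(volume, "volume_grid"))
  if (!is.finite(angle_deg) || abs(angle_deg) >= 90)
    stop("|angle_deg| must be < 90")
  d <- dim(volume)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  tn <- tan(angle_deg * pi / 180)
  out <- matrix(0, nx, ny)
  x_out <- 0:(nx - 1)
  for (z in 0:(nz - 1)) {
    # gather form of the linear-interpolation shear: pixel x receives the
    # slice sampled at x - z*tan(theta) (equivalent to scattering each
    # voxel to x + z*tan(theta))
    xs <- x_out - z * tn
    f <- floor(xs)
    w <- xs - f
    slice <- volume$values[, , z + 1L]
    v1 <- f >= 0 & f <= nx - 1
    if (any(v1))
      out[v1, ] <- out[v1, ] + slice[f[v1] + 1L, , drop = FALSE] * (1 - w[v1])
    v2 <- f >= -1 & f <= nx - 2
    if (any(v2))
      out[v2, ] <- out[v2, ] + slice[f[v2] + 2L, , drop = FALSE] * w[v2]
  }
  if (pathlength_weighting) out <- out / cos(angle_deg * pi / 180)
  out
}

#' Reproject a volume at every configured angle
#'
#' Computes the eight reprojections of a candidate volume at the tilt
#' angles of the acquisition geometry, ordered by electrode position. This
#' is the forward model compared against the measured tilt images inside
#' the annealing loop.
#'
#' @param volume a [volume_grid()].
#' @param geometry an [electrode_geometry()][default_geometry].
#' @param pathlength_weighting passed to [project()].
#' @return a [tilt_series()] with provenance `"reprojected"`.
#' @export
project_all <- function(volume, geometry = default_geometry(),
                        pathlength_weighting = FALSE) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  imgs <- lapply(geometry$angles_deg, function(a)
    project(volume, a, pathlength_weighting))
  tilt_series(imgs, geometry$angles_deg, pixel_um = volume$voxel_um,
              provenance = "reprojected")
}

#' Localized voxel change (perturbation delta)
#'
#' A compact representation of a localized change to a volume: the changed
#' values over a box footprint plus the 1-based offset of the footprint's
#' first voxel. Produced by [propose_perturbation()] and consumed by
#' [project_delta()] and [apply_delta()].
#'
#' @param values numeric 3D array of voxel increments.
#' @param offset integer length-3 vector; 1-based index in the volume of
#'   `values[1, 1, 1]`.
#' @return an object of class `voxel_delta`.
#' @export
voxel_delta <- function(values, offset) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(offset) == 3L)
  structure(list(values = values, offset = as.integer(offset)),
            class = "voxel_delta")
}

check_delta_bounds <- function(delta, vol_dim) {
  lo <- delta$offset
  hi <- delta$offset + dim(delta$values) - 1L
  if (any(lo < 1L) || any(hi > vol_dim))
    stop("delta footprint [", paste(lo, collapse = ","), "]..[",
         paste(hi, collapse = ","), "] is out of volume bounds ",
         paste(vol_dim, collapse = "x"))
  invisible(TRUE)
}

#' Project a localized volume change into image space
#'
#' Returns the image increment D such that
#' `project(V + delta, theta) = project(V, theta) + D` for any volume V of
#' dimension `vol_dim` containing the footprint. Only the footprint is
#' traversed, which is what makes per-step error updates in the annealing
#' loop cheap compared to a full reprojection.
#'
#' @param delta a [voxel_delta()].
#' @param angle_deg tilt angle in degrees.
#' @param vol_dim integer length-3 volume dimensions (bounds and image
#'   shape).
#' @param pathlength_weighting passed through as in [project()].
#' @return numeric `nx` x `ny` increment image (dense; zero outside the
#'   sheared footprint).
#' @export
project_delta <- function(delta, angle_deg, vol_dim,
                          pathlength_weighting = FALSE) {
  stopifnot(inherits(delta, "voxel_delta"))
  if (!is.finite(angle_deg) || abs(angle_deg) >= 90)
    stop("|angle_deg| must be < 90")
  check_delta_bounds(delta, vol_dim)
  nx <- vol_dim[1]; ny <- vol_dim[2]
  dd <- dim(delta$values)
  out <- matrix(0, nx, ny)
  tn <- tan(angle_deg * pi / 180)
  ycols <- delta$offset[2]:(delta$offset[2] + dd[2] - 1L)
  x0 <- delta$offset[1] - 1L            # 0-based x of footprint start
  for (kz in seq_len(dd[3])) {
    z <- delta$offset[3] - 1L + kz - 1L # 0-based depth
    shift <- z * tn
    fs <- floor(shift)
    w <- shift - fs
    xt <- x0 + (seq_len(dd[1]) - 1L) + fs      # 0-based target bin (lower)
    sl <- delta$values[, , kz, drop = FALSE]
    dim(sl) <- dd[1:2]
    v1 <- xt >= 0 & xt <= nx - 1
    if (any(v1))
      out[xt[v1] + 1L, ycols] <- out[xt[v1] + 1L, ycols] +
        sl[v1, , drop = FALSE] * (1 - w)
    v2 <- xt >= -1 & xt <= nx - 2
    if (any(v2))
      out[xt[v2] + 2L, ycols] <- out[xt[v2] + 2L, ycols] +
        sl[v2, , drop = FALSE] * w
  }
  if (pathlength_weighting) out <- out / cos(angle_deg * pi / 180)
  out
}

#' Apply a localized change to a volume
#'
#' @param volume a [volume_grid()].
#' @param delta a [voxel_delta()].
#' @param scale multiply the delta by this factor before adding (use -1 to
#'   undo a previously applied delta).
#' @return the updated [volume_grid()].
#' @export
apply_delta <- function(volume, delta, scale = 1) {
  stopifnot(inherits(volume, "volume_grid"), inherits(delta, "voxel_delta"))
  check_delta_bounds(delta, dim(volume))
  lo <- delta$offset
  hi <- delta$offset + dim(delta$values) - 1L
  volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
    scale * delta$values
  volume
}
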