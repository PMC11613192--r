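#' 3D reconstruction volume
#'
#' A `volume_grid` holds the voxel intensities of the reconstruction space
#' as a numeric 3D array indexed `[x, y, z]`, where x is the electrode-array
#' axis, y the scan-line axis and z the depth measured from the SiN film
#' plane (z = 0 at the film, increasing into the sample). Voxels are
#' isotropic cubes of edge `voxel_um` micrometres; voxel centers sit at
#' integer coordinates (0-based internally). Intensities are dimensionless
#' impedance-proxy values: brighter means higher impedance.
#'
#' @param values numeric 3D array of voxel intensities, all finite.
#' @param voxel_um isotropic voxel edge length in micrometres.
#' @return an object of class `volume_grid`.
#' @examples
#' v <- volume_grid(array(0, c(16, 16, 16)), voxel_um = 0.25)
#' dim(v)
#' @export
volume_grid <- function(values, voxel_um = 0.1) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume values must all be finite")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("`voxel_um` must be a single positive number")
  structure(list(values = values, voxel_um = voxel_um),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.4g um/voxel\n",
              d[1], d[2], d[3], x$voxel_um))
  cat(sprintf("  intensity range [%.4g, %.4g], total mass %.6g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' Number of voxels in a volume or grid side
#'
#' @param x a `volume_grid`, or an integer vector of grid dimensions.
#' @return total voxel count as a double (240^3 overflows 32-bit ints).
#' @examples
#' n_voxels(c(240, 240, 240))  # 13824000
#' @export
n_voxels <- function(x) {
  d <- if (inherits(x, "volume_grid")) dim(x) else x
  prod(as.numeric(d))
}

#' Tilt series of co-registered projection images
#'
#' The common container for measured impedance images, reprojections of a
#' candidate volume, and simulated projections of a phantom: one real-valued
#' 2D image per electrode position, all of identical shape, indexed
#' `[x, y]` with x the electrode-array axis. `angles_deg[k]` is the tilt
#' angle of image k in the x-z plane.
#'
#' @param images list of numeric matrices of identical dimensions.
#' @param angles_deg numeric vector, one signed tilt angle (degrees) per image.
#' @param pixel_um pixel edge length in micrometres.
#' @param provenance one of `"measured"`, `"reprojected"`, `"simulated"`.
#' @return an object of class `tilt_series`.
#' @export
tilt_series <- function(images, angles_deg, pixel_um = 0.1,
                        provenance = c("measured", "reprojected", "simulated")) {
  provenance <- match.arg(provenance)
  if (!is.list(images) || !length(images))
    stop("`images` must be a non-empty list of matrices")
  if (length(images) != length(angles_deg))
    stop("need one tilt angle per image: got ", length(images),
         " images and ", length(angles_deg), " angles")
  d1 <- dim(images[[1L]])
  for (im in images) {
    if (!is.matrix(im) || !identical(dim(im), d1))
      stop("all images must be matrices of one common shape")
    if (!all(is.finite(im))) stop("image values must all be finite")
  }
  if (!all(is.finite(angles_deg)) || any(abs(angles_deg) >= 90))
    stop("tilt angles must be finite and |angle| < 90 degrees")
  structure(list(images = images, angles_deg = as.numeric(angles_deg),
                 pixel_um = pixel_um, provenance = provenance),
            class = "tilt_series")
}

#' @export
length.tilt_series <- function(x) length(x$images)

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<tilt_series> %d images of %d x %d px (%s), %.4g um/px\n",
              length(x), d[1], d[2], x$provenance, x$pixel_um))
  cat("  angles (deg): ", paste(format(x$angles_deg), collapse = ", "), "\n")
  invisible(x)
}

# Internal: check two series are comparable (same shapes, same angle order).
check_series_match <- function(a, b) {
  if (length(a) != length(b))
    stop("tilt series differ in image count: ", length(a), " vs ", length(b))
  if (!identical(dim(a$images[[1L]]), dim(b$images[[1L]])))
    stop("tilt series differ in image shape")
  if (max(abs(a$angles_deg - b$angles_deg)) > 1e-9)
    stop("tilt series differ in angle ordering")
  invisible(TRUE)
}

#' Min-max normalize a tilt series jointly across positions
#'
#' Rescales all images with one global minimum and maximum to
#' \[0, `scale`\], so inter-position contrast differences (which encode
#' the tilt information) are preserved. A constant series is shifted to
#' all-zero. With `scale = 255` this is the 8-bit grey-scale convention
#' of the image-conditioning chain, and the scale on which the annealing
#' constants (temperature 10 to 0.1, perturbation SD 0.2 to 0.1 grey
#' levels) are expressed; [reconstruct()] applies it to measured images
#' before annealing.
#'
#' @param ts a [tilt_series()].
#' @param scale upper end of the target intensity range (1 by default;
#'   255 for the 8-bit convention).
#' @return list with elements `series` (normalized [tilt_series()]),
#'   `min` and `max` (the global extrema used) and `scale`.
#' @export
normalize_series <- function(ts, scale = 1) {
  stopifnot(inherits(ts, "tilt_series"), scale > 0)
  lo <- min(vapply(ts$images, min, 0))
  hi <- max(vapply(ts$images, max, 0))
  span <- if (hi > lo) hi - lo else 1
  ts$images <- lapply(ts$images, function(im) (im - lo) / span * scale)
  list(series = ts, min = lo, max = hi, scale = scale)
}

#' Center-crop and resample a tilt series to a square side
#'
#' Acquired images are generally rectangular (e.g. 1280 x 960) while the
#' reconstruction space is cubic; this crops each image to its central
#' square and bilinearly resamples it to `side` x `side` pixels. The pixel
#' size is rescaled accordingly.
#'
#' @param ts a [tilt_series()].
#' @param side target square side in pixels.
#' @return a [tilt_series()] of `side` x `side` images.
#' @export
prepare_tilt_series <- function(ts, side) {
  stopifnot(inherits(ts, "tilt_series"), side >= 2)
  d <- dim(ts$images[[1L]])
  s <- min(d)
  ox <- (d[1] - s) %/% 2L
  oy <- (d[2] - s) %/% 2L
  ts$images <- lapply(ts$images, function(im) {
    sq <- im[(ox + 1L):(ox + s), (oy + 1L):(oy + s), drop = FALSE]
    resample_bilinear(sq, side, side)
  })
  ts$pixel_um <- ts$pixel_um * s / side
  ts
}

# Internal: bilinear resampling of a matrix to nx x ny.
resample_bilinear <- function(m, nx, ny) {
  d <- dim(m)
  if (all(d == c(nx, ny))) return(m)
  # map output pixel centers onto input pixel-center coordinates (0-based)
  xs <- (seq_len(nx) - 0.5) * d[1] / nx - 0.5
  ys <- (seq_len(ny) - 0.5) * d[2] / ny - 0.5
  xs <- pmin(pmax(xs, 0), d[1] - 1)
  ys <- pmin(pmax(ys, 0), d[2] - 1)
  x0 <- pmin(floor(xs), d[1] - 2); wx <- xs - x0
  y0 <- pmin(floor(ys), d[2] - 2); wy <- ys - y0
  i0 <- as.integer(x0) + 1L; j0 <- as.integer(y0) + 1L
  a <- m[i0, j0, drop = FALSE]; b <- m[i0 + 1L, j0, drop = FALSE]
  c_ <- m[i0, j0 + 1L, drop = FALSE]; d_ <- m[i0 + 1L, j0 + 1L, drop = FALSE]
  top <- a * (1 - wx) + b * wx          # recycles wx down columns (x-major)
  bot <- c_ * (1 - wx) + d_ * wx
  top * rep(1 - wy, each = nx) + bot * rep(wy, each = nx)
}
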