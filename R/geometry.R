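#' Linear-array electrode geometry
#'
#' Encodes the fixed acquisition geometry of the 8-electrode linear-array
#' impedance system: each electrode position carries a distinct applied
#' frequency, and the electron-beam incidence relative to each electrode
#' defines a fixed tilt angle, so the eight demodulated frequency channels
#' are projections at eight angles acquired in a single scan. Positions are
#' numbered 1-8 left to right; the leftmost electrode carries the lowest
#' frequency and the largest positive tilt angle.
#'
#' Angles are stored directly as constants and never derived from physical
#' electrode positions (the electrode pitch is not part of the model; only
#' the 0.3 mm electrode width is recorded).
#'
#' @param positions integer position indices (1-8, left to right).
#' @param frequencies_khz applied frequency per position, kHz, strictly
#'   increasing in 10 kHz steps from 200 to 270.
#' @param angles_deg signed tilt angle per position in the array-axis/
#'   beam-axis plane; strictly decreasing, antisymmetric about the array
#'   center, all within +/- 27.2 degrees.
#' @param electrode_width_mm physical electrode width (0.3 mm).
#' @return an object of class `electrode_geometry`.
#' @seealso [default_geometry()]
#' @export
electrode_geometry <- function(positions, frequencies_khz, angles_deg,
                               electrode_width_mm = 0.3) {
  g <- structure(list(positions = as.integer(positions),
                      frequencies_khz = as.numeric(frequencies_khz),
                      angles_deg = as.numeric(angles_deg),
                      electrode_width_mm = electrode_width_mm),
                 class = "electrode_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  n <- length(g$positions)
  if (n != 8L || !identical(g$positions, 1:8))
    stop("geometry must have exactly 8 positions numbered 1..8")
  if (length(g$frequencies_khz) != n || length(g$angles_deg) != n)
    stop("frequencies and angles must have one entry per position")
  if (!isTRUE(all.equal(g$frequencies_khz, seq(200, 270, by = 10))))
    stop("frequencies must increase by 10 kHz from 200 to 270")
  a <- g$angles_deg
  if (any(diff(a) >= 0))
    stop("tilt angles must be strictly decreasing with position")
  if (max(abs(a + rev(a))) > 1e-9)
    stop("tilt angles must be antisymmetric: angle[k] = -angle[9-k]")
  if (any(abs(a) > 27.2 + 1e-9))
    stop("tilt angles must satisfy |angle| <= 27.2 degrees")
  invisible(g)
}

#' The standard 8-position acquisition geometry
#'
#' Position 1 (leftmost) carries 200 kHz at +27.2 degrees, position 8
#' (rightmost) 270 kHz at -27.2 degrees; angles are antisymmetric and sum
#' to zero.
#'
#' @return an `electrode_geometry` with angles
#'   27.2, 15.9, 9.8, 3.3, -3.3, -9.8, -15.9, -27.2 degrees and
#'   frequencies 200-270 kHz in 10 kHz steps.
#' @examples
#' g <- default_geometry()
#' g$angles_deg[1]   # 27.2
#' sum(g$angles_deg) # 0
#' @export
default_geometry <- function() {
  electrode_geometry(
    positions = 1:8,
    frequencies_khz = seq(200, 270, by = 10),
    angles_deg = c(27.2, 15.9, 9.8, 3.3, -3.3, -9.8, -15.9, -27.2),
    electrode_width_mm = 0.3
  )
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat("<electrode_geometry> 8-position linear array,",
      x$electrode_width_mm, "mm electrodes\n")
  print(data.frame(position = x$positions,
                   frequency_khz = x$frequencies_khz,
                   angle_deg = x$angles_deg))
  invisible(x)
}

#' Map an applied frequency to its electrode position
#'
#' Inverts the frequency-to-position assignment of the array: each
#' demodulated frequency channel identifies one electrode position and
#' hence one tilt angle.
#'
#' @param geometry an `electrode_geometry`.
#' @param f_khz a configured frequency in kHz.
#' @return the position index (1-8) whose frequency equals `f_khz`.
#' @examples
#' frequency_to_position(default_geometry(), 200)  # 1
#' frequency_to_position(default_geometry(), 240)  # 5
#' @export
frequency_to_position <- function(geometry, f_khz) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  i <- which(abs(geometry$frequencies_khz - f_khz) < 1e-9)
  if (length(i) != 1L)
    stop("unknown frequency ", f_khz, " kHz; valid frequencies are ",
         paste(geometry$frequencies_khz, collapse = ", "), " kHz")
  geometry$positions[i]
}

#' Electron-beam dwell time per pixel
#'
#' The per-pixel beam residence time for one full scan:
#' `scan_s / (width_px * height_px)`, returned in microseconds. An 80 s
#' scan of a 1280 x 960 frame gives about 65 us per pixel.
#'
#' @param scan_s total scan duration in seconds.
#' @param width_px,height_px frame size in pixels.
#' @return dwell time in microseconds.
#' @examples
#' dwell_time_us(80, 1280, 960)  # ~65.1
#' @export
dwell_time_us <- function(scan_s, width_px, height_px) {
  if (scan_s <= 0 || width_px <= 0 || height_px <= 0)
    stop("scan duration and frame dimensions must all be positive")
  scan_s / (width_px * height_px) * 1e6
}

#' Read or write a geometry as YAML/JSON
#'
#' Serialized keys: `positions`, `frequencies_khz`, `angles_deg`,
#' `electrode_width_mm`. Format follows the file extension (.yaml/.yml or
#' .json).
#'
#' @param geometry an `electrode_geometry`.
#' @param path file path ending in .yaml, .yml or .json.
#' @return `read_geometry` returns an `electrode_geometry`;
#'   `write_geometry` returns `path` invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  rec <- list(positions = geometry$positions,
              frequencies_khz = geometry$frequencies_khz,
              angles_deg = geometry$angles_deg,
              electrode_width_mm = geometry$electrode_width_mm)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(rec, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(rec, path, auto_unbox = FALSE, digits = NA)
  } else stop("geometry path must end in .yaml, .yml or .json")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("geometry path must end in .yaml, .yml or .json")
  electrode_geometry(rec$positions, rec$frequencies_khz, rec$angles_deg,
                     rec$electrode_width_mm)
}
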