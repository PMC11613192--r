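# Readers and writers. TIFF pages are stored min-max scaled to [0, 1]
# (the representation r-tiff round-trips exactly to ~2^-32 of the range),
# with the true scale, angles and voxel/pixel sizes in a JSON sidecar.
# MRC is the lossless float32 path for volumes.

sidecar_path <- function(path) paste0(path, ".json")

scale_01 <- function(x) {
  lo <- min(x); hi <- max(x)
  s <- if (hi > lo) hi - lo else 1
  list(data = (x - lo) / s, min = lo, max = hi)
}

#' Write or read a tilt series as multi-page TIFF
#'
#' One page per electrode position, ordered by position, with tilt
#' angles, pixel size, provenance and the intensity scale recorded in a
#' sidecar `<path>.json`. `read_tilt_series` also accepts a directory of
#' eight single-page files named `pos1.tiff` ... `pos8.tiff` with an
#' `angles.json` sidecar (fields `angles_deg`, optionally `pixel_um`).
#'
#' @param ts a [tilt_series()].
#' @param path a `.tiff`/`.tif` file (or, for reading, a directory).
#' @param n_expected expected image count when reading (default 8).
#' @return `read_tilt_series` returns a [tilt_series()]; the writer
#'   returns `path` invisibly.
#' @export
write_tilt_series <- function(ts, path) {
  stopifnot(inherits(ts, "tilt_series"))
  sc <- scale_01(unlist(ts$images))
  d <- dim(ts$images[[1L]])
  n <- length(ts$images)
  pages <- lapply(seq_len(n), function(k) {
    m <- matrix(sc$data[((k - 1) * prod(d) + 1):(k * prod(d))], d[1], d[2])
    t(m)  # TIFF convention: rows are scan lines (y)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(angles_deg = ts$angles_deg,
                            pixel_um = ts$pixel_um,
                            provenance = ts$provenance,
                            intensity_min = sc$min, intensity_max = sc$max),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tilt_series
#' @export
read_tilt_series <- function(path, n_expected = 8L) {
  if (dir.exists(path)) return(read_tilt_dir(path, n_expected))
  if (!file.exists(path)) stop("no such tilt-series file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n_expected)
    stop("expected ", n_expected, " pages, found ", length(pages),
         " in ", path)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing sidecar with tilt angles: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$angles_deg) || length(meta$angles_deg) != n_expected)
    stop("sidecar must list one angle per page")
  span <- meta$intensity_max - meta$intensity_min
  if (!length(span) || !is.finite(span)) { span <- 1; meta$intensity_min <- 0 }
  if (span == 0) span <- 1
  imgs <- lapply(pages, function(p) t(p) * span + meta$intensity_min)
  tilt_series(imgs, meta$angles_deg,
              pixel_um = if (is.null(meta$pixel_um)) 0.1 else meta$pixel_um,
              provenance = if (is.null(meta$provenance)) "measured"
                           else meta$provenance)
}

read_tilt_dir <- function(path, n_expected) {
  files <- file.path(path, sprintf("pos%d.tiff", seq_len(n_expected)))
  alt <- file.path(path, sprintf("pos%d.tif", seq_len(n_expected)))
  files <- ifelse(file.exists(files), files, alt)
  if (!all(file.exists(files)))
    stop("directory form needs files pos1.tiff .. pos", n_expected,
         ".tiff; missing: ",
         paste(basename(files[!file.exists(files)]), collapse = ", "))
  side <- file.path(path, "angles.json")
  if (!file.exists(side)) stop("missing ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  imgs <- lapply(files, function(f) t(tiff::readTIFF(f)))
  tilt_series(imgs, meta$angles_deg,
              pixel_um = if (is.null(meta$pixel_um)) 0.1 else meta$pixel_um,
              provenance = "measured")
}

#' Write or read a reconstruction volume (MRC or TIFF z-stack)
#'
#' `.mrc` stores float32 voxels in a minimal mode-2 MRC file whose header
#' records the voxel size (in Angstrom, 1 um = 1e4 A); the round trip is
#' exact to float32 precision. `.tiff`/`.tif` stores one page per z-slice,
#' min-max scaled, with the scale and voxel size in a JSON sidecar.
#'
#' @param volume a [volume_grid()].
#' @param path output path ending in `.mrc`, `.tiff` or `.tif`.
#' @return `read_volume` returns a [volume_grid()]; the writer returns
#'   `path` invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  if (grepl("\\.mrc$", path, ignore.case = TRUE)) {
    write_mrc(volume, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    sc <- scale_01(volume$values)
    d <- dim(volume)
    pages <- lapply(seq_len(d[3]), function(z) t(sc$data[, , z]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(list(voxel_um = volume$voxel_um,
                              intensity_min = sc$min,
                              intensity_max = sc$max,
                              nz = d[3]),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else stop("unknown volume extension (use .mrc or .tiff): ", path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  if (grepl("\\.mrc$", path, ignore.case = TRUE)) return(read_mrc(path))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unknown volume extension (use .mrc or .tiff): ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  span <- meta$intensity_max - meta$intensity_min
  if (span == 0) span <- 1
  vals <- vapply(pages, function(p) t(p) * span + meta$intensity_min,
                 matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  volume_grid(vals, meta$voxel_um)
}

# Minimal MRC (mode 2, float32, no extended header). Voxel size is
# recorded through the cell dimensions: cella = n * voxel_um * 1e4 A.
write_mrc <- function(volume, path) {
  d <- dim(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  cella <- d * volume$voxel_um * 1e4
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(cella, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(volume$values), max(volume$values),
                        mean(volume$values))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(100), con)                                  # extra (25 words)
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")  # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)         # little-endian stamp
  writeBin(as.numeric(stats::sd(volume$values)), con, size = 4,
           endian = "little")
  writeBin(0L, con, size = 4, endian = "little")           # nlabl
  writeBin(raw(800), con)                                  # labels
  writeBin(as.numeric(volume$values), con, size = 4, endian = "little")
  invisible(path)
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head_ints <- readBin(con, integer(), n = 10, size = 4, endian = "little")
  d <- head_ints[1:3]
  mode <- head_ints[4]
  if (mode != 2L) stop("only mode-2 (float32) MRC files are supported")
  cella <- readBin(con, numeric(), n = 6, size = 4, endian = "little")[1:3]
  seek(con, 92)
  nsymbt <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- prod(as.numeric(d))
  vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(vals) < n)
    stop("truncated MRC file: expected ", n, " voxels, read ", length(vals))
  voxel_um <- cella[1] / d[1] / 1e4
  volume_grid(array(vals, d), voxel_um = voxel_um)
}

#' Write a reconstruction history as CSV
#'
#' Columns: `cycle`, `T`, `kernel_sd`, `perturb_sd`, `error`,
#' `accept_rate`, `uphill_rate`, `cc_pos1` ... `cc_pos8`.
#'
#' @param history the history data.frame of a [reconstruct()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Read or write an annealing schedule as YAML
#'
#' Keys: `T0`, `Tf`, `k0`, `kf`, `s0`, `sf`, `cycles`,
#' `iters_per_cycle`.
#'
#' @param schedule an [anneal_schedule()].
#' @param path `.yaml`/`.yml` path.
#' @return `read_schedule` returns an [anneal_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  yaml::write_yaml(unclass(schedule), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  rec <- yaml::read_yaml(path)
  anneal_schedule(rec$T0, rec$Tf, rec$k0, rec$kf, rec$s0, rec$sf,
                  rec$cycles, rec$iters_per_cycle)
}

# Tiny FNV-1a-style hash for provenance records (no external digest
# dependency). Arithmetic stays below 2^53, so the modular reduction is
# exact in doubles; bitwXor needs < 2^31 operands, hence the 16-bit split.
fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    h <- (h - h %% 65536) + lo
    # h * p mod 2^32, split so every product stays exact in doubles
    h <- (h %% 65536 * p + (h %/% 65536 * p) %% 65536 * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a machine-readable provenance record
#'
#' Every pipeline run records its configuration hash, seed and package
#' version beside its outputs, so a result can be traced to the exact
#' invocation that produced it.
#'
#' @param path output JSON path.
#' @param config named list of run parameters.
#' @param seed the run seed.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(path, config, seed) {
  cfg_str <- paste(deparse(config), collapse = "")
  jsonlite::write_json(
    list(seed = seed,
         config = config,
         config_hash = fnv1a(cfg_str),
         package = "satomo",
         version = as.character(utils::packageVersion("satomo")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
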