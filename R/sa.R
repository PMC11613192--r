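#' Residual sum of squares between two tilt series
#'
#' The reconstruction error: `E = sum_k sum_pixels (P_k - I_k)^2`, summed
#' over all positions, between the reprojections of a candidate volume and
#' the measured images.
#'
#' @param reprojections,measured [tilt_series()] objects of matching shape
#'   and angle ordering.
#' @return non-negative scalar error.
#' @export
rss_error <- function(reprojections, measured) {
  stopifnot(inherits(reprojections, "tilt_series"),
            inherits(measured, "tilt_series"))
  check_series_match(reprojections, measured)
  sum(vapply(seq_along(reprojections$images), function(k)
    sum((reprojections$images[[k]] - measured$images[[k]])^2), 0))
}

#' Draw a random localized Gaussian perturbation
#'
#' One annealing proposal: a center drawn uniformly over the volume, a
#' shared amplitude `a ~ Normal(0, perturb_sd)`, and the peak-1 Gaussian
#' kernel scaled by `a`, clipped at the volume faces without
#' renormalization. Consumes exactly 3 uniform draws (center) followed by
#' 1 normal draw (amplitude) from the R random stream, in that order —
#' the same stream discipline as the compiled annealing engine, so R-level
#' and compiled runs are reproducible from one seed.
#'
#' @param vol_dim integer length-3 volume dimensions.
#' @param kernel_sd current kernel standard deviation (voxels).
#' @param perturb_sd current amplitude standard deviation.
#' @param truncation kernel truncation in multiples of `kernel_sd`.
#' @return a [voxel_delta()]; the attribute `"amplitude"` carries the
#'   drawn amplitude and `"center"` the 1-based center voxel.
#' @export
propose_perturbation <- function(vol_dim, kernel_sd, perturb_sd,
                                 truncation = 2) {
  u <- stats::runif(3)
  ctr0 <- pmin(floor(u * vol_dim), vol_dim - 1L)   # 0-based center
  a <- stats::rnorm(1L, 0, perturb_sd)
  h <- ceiling(truncation * kernel_sd)
  k <- gaussian_kernel_3d(kernel_sd, truncation)
  lo0 <- pmax(ctr0 - h, 0)
  hi0 <- pmin(ctr0 + h, vol_dim - 1L)
  ks <- lapply(1:3, function(i) (lo0[i] - ctr0[i] + h + 1L):(hi0[i] - ctr0[i] + h + 1L))
  vals <- a * k[ks[[1]], ks[[2]], ks[[3]], drop = FALSE]
  d <- voxel_delta(vals, lo0 + 1L)
  attr(d, "amplitude") <- a
  attr(d, "center") <- as.integer(ctr0 + 1L)
  d
}

#' Annealing state (reference R engine)
#'
#' Holds the current volume, the cached reprojections, the cached error
#' and the cycle index for the step-by-step R implementation of the
#' annealing loop. The cached reprojections are updated incrementally via
#' [project_delta()]; on a rejected step they are restored exactly.
#'
#' @param measured the measured/simulated [tilt_series()] (already
#'   normalized to the scale the schedule assumes).
#' @param geometry an [electrode_geometry()][default_geometry].
#' @param nz volume depth in voxels (default: cubic, `nz = nx`).
#' @return an object of class `sa_state` with elements `volume`,
#'   `reprojections`, `measured`, `geometry`, `error`, `cycle`,
#'   `accepted`, `attempted`.
#' @export
sa_state <- function(measured, geometry = default_geometry(), nz = NULL) {
  stopifnot(inherits(measured, "tilt_series"))
  if (length(measured) != length(geometry$angles_deg))
    stop("measured series must have one image per geometry position")
  if (max(abs(measured$angles_deg - geometry$angles_deg)) > 1e-9)
    stop("measured series angles do not match the geometry")
  d <- dim(measured$images[[1L]])
  if (d[1] != d[2])
    stop("images must be square; see prepare_tilt_series()")
  if (is.null(nz)) nz <- d[1]
  vol <- volume_grid(array(0, c(d[1], d[2], nz)),
                     voxel_um = measured$pixel_um)
  repro <- project_all(vol, geometry)
  structure(list(volume = vol, reprojections = repro, measured = measured,
                 geometry = geometry, error = rss_error(repro, measured),
                 cycle = 1L, accepted = 0L, attempted = 0L,
                 uphill_accepted = 0L, uphill_attempted = 0L),
            class = "sa_state")
}

#' One annealing step (reference R engine)
#'
#' Proposes a random localized Gaussian perturbation, computes the error
#' change incrementally through [project_delta()] (only the perturbation
#' footprint is reprojected), and applies the Boltzmann acceptance rule.
#' On acceptance the volume, cached reprojections and cached error are
#' updated incrementally; on rejection the state is returned unchanged.
#'
#' This R implementation is the readable reference for the compiled
#' engine used by [reconstruct()]; both consume the random stream
#' identically (3 uniforms, 1 normal, then 1 uniform only for an uphill
#' proposal).
#'
#' @param state an [sa_state()].
#' @param T current virtual temperature.
#' @param kernel_sd,perturb_sd current kernel and amplitude SDs.
#' @param truncation kernel truncation in multiples of `kernel_sd`.
#' @param nonneg reject proposals that would push any voxel below zero
#'   (the optional non-negativity constraint; infeasible proposals are
#'   rejected before the Boltzmann draw).
#' @return the updated `sa_state`.
#' @export
anneal_step <- function(state, T, kernel_sd, perturb_sd, truncation = 2,
                        nonneg = FALSE) {
  stopifnot(inherits(state, "sa_state"))
  d <- dim(state$volume)
  delta <- propose_perturbation(d, kernel_sd, perturb_sd, truncation)
  angs <- state$geometry$angles_deg
  incs <- lapply(angs, function(a) project_delta(delta, a, d))
  dE <- 0
  for (k in seq_along(angs)) {
    r <- state$reprojections$images[[k]] - state$measured$images[[k]]
    dE <- dE + sum(incs[[k]] * (incs[[k]] + 2 * r))
  }
  feasible <- TRUE
  if (nonneg && attr(delta, "amplitude") < 0) {
    lo <- delta$offset; hi <- delta$offset + dim(delta$values) - 1L
    feasible <- all(state$volume$values[lo[1]:hi[1], lo[2]:hi[2],
                                        lo[3]:hi[3]] + delta$values >= 0)
  }
  uphill <- feasible && dE > 0
  acc <- if (!feasible) FALSE
         else if (!uphill) TRUE
         else boltzmann_accept(dE, T, stats::runif(1L))
  state$attempted <- state$attempted + 1L
  if (uphill) state$uphill_attempted <- state$uphill_attempted + 1L
  if (acc && uphill) state$uphill_accepted <- state$uphill_accepted + 1L
  if (acc) {
    state$volume <- apply_delta(state$volume, delta)
    for (k in seq_along(angs))
      state$reprojections$images[[k]] <- state$reprojections$images[[k]] + incs[[k]]
    state$error <- state$error + dE
    state$accepted <- state$accepted + 1L
  }
  state
}

#' Simulated-annealing volume reconstruction from a tilt series
#'
#' Reconstructs a 3D impedance-proxy volume from the 8 fixed-angle tilt
#' images. The volume starts from all zeros; each step perturbs a random
#' position with a Gaussian-weighted bump whose amplitude is drawn from
#' `Normal(0, perturb_sd)`, reprojects the change at the 8 angles,
#' evaluates the change in the residual sum of squares against the
#' measured images, and accepts or rejects it by the Boltzmann rule at the
#' current virtual temperature. Temperature, kernel size and amplitude SD
#' decay geometrically over the outer cycles (see [anneal_schedule()]).
#'
#' Input images are min-max normalized jointly across the 8 positions to
#' the 8-bit grey range \[0, 255\] before annealing (one global
#' minimum/maximum, so relative contrast between positions is preserved).
#' This is the scale produced by the image-conditioning chain's 8-bit
#' conversion, and the scale on which the annealing constants are
#' expressed: the perturbation amplitude SD of 0.2 to 0.1 is in grey
#' levels, small against typical voxel values, and the temperature 10 to
#' 0.1 is small against the squared-grey-level error, so the search is a
#' fine-grained, near-greedy refinement with occasional thermal escapes —
#' the regime in which the error falls by orders of magnitude before
#' saturating. Set `normalize = FALSE` if the series is already on the
#' intended scale.
#'
#' @param measured a [tilt_series()] of square images, one per geometry
#'   position, with matching angles.
#' @param geometry an [electrode_geometry()][default_geometry].
#' @param schedule an [anneal_schedule()].
#' @param seed integer seed; a given (inputs, schedule, seed) triple
#'   yields a bit-identical volume and history.
#' @param nz volume depth in voxels (default cubic: `nz = nx`).
#' @param normalize jointly min-max normalize the inputs first.
#' @param truncation kernel truncation radius in multiples of the kernel
#'   SD.
#' @param clip_negative enforce voxel non-negativity by rejecting any
#'   proposal that would push a voxel below zero. Off by default: the
#'   model itself imposes no non-negativity constraint, but the option is
#'   a useful prior for film-mounted samples.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical stream, far slower).
#' @return an object of class `sa_reconstruction`: list with `volume`
#'   ([volume_grid()]), `reprojections` ([tilt_series()]), `error` (final
#'   RSS), `history` (one row per cycle: `cycle`, `T`, `kernel_sd`,
#'   `perturb_sd`, `error`, `accept_rate`, `uphill_rate` — the fraction of
#'   error-increasing proposals accepted — and `cc_pos1..cc_pos8`),
#'   `geometry`, `schedule`, `seed`, `normalization` (the min/max used).
#' @examples
#' \donttest{
#' ph <- cell_phantom(grid = c(24, 24, 24), seed = 1)
#' ts <- simulate_tilt_series(ph, noise_sd = 0, seed = 2)
#' rec <- reconstruct(ts, schedule = anneal_schedule(cycles = 40,
#'                                                   iters_per_cycle = 400),
#'                    seed = 3)
#' min(unlist(rec$history[nrow(rec$history), paste0("cc_pos", 1:8)]))
#' }
#' @export
reconstruct <- function(measured, geometry = default_geometry(),
                        schedule = anneal_schedule(), seed = 1L,
                        nz = NULL, normalize = TRUE, truncation = 2,
                        clip_negative = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(measured, "tilt_series"),
            inherits(geometry, "electrode_geometry"),
            inherits(schedule, "anneal_schedule"))
  norm_rec <- c(NA_real_, NA_real_)
  if (normalize) {
    nr <- normalize_series(measured, scale = 255)
    measured <- nr$series
    norm_rec <- c(nr$min, nr$max)
  }
  sched <- schedule_at(schedule, seq_len(schedule$cycles))
  set.seed(as.integer(seed))
  if (engine == "cpp") {
    res <- run_engine_cpp(measured, geometry, sched, schedule$iters_per_cycle,
                          nz, truncation, clip_negative)
  } else {
    res <- run_engine_r(measured, geometry, sched, schedule$iters_per_cycle,
                        nz, truncation, clip_negative)
  }
  if (any(res$degenerate))
    warning("zero-variance reprojection in ", sum(res$degenerate),
            " cycle/position cell(s); cross-correlation recorded as 0")
  structure(list(volume = res$volume, reprojections = res$reprojections,
                 error = res$error, history = res$history,
                 geometry = geometry, schedule = schedule,
                 seed = as.integer(seed), normalization = norm_rec),
            class = "sa_reconstruction")
}

# Compiled engine wrapper: packs/unpacks the flat arrays the C++ core uses.
run_engine_cpp <- function(measured, geometry, sched, iters, nz, truncation,
                           nonneg) {
  d <- dim(measured$images[[1L]])
  if (d[1] != d[2]) stop("images must be square; see prepare_tilt_series()")
  if (is.null(nz)) nz <- d[1]
  K <- length(measured)
  meas <- array(unlist(measured$images), c(d[1], d[2], K))
  out <- sa_engine_cpp(as.integer(c(d[1], d[2], nz)), meas,
                       tan(geometry$angles_deg * pi / 180),
                       sched$T, sched$kernel_sd, sched$perturb_sd,
                       as.integer(iters), truncation, nonneg)
  vol <- volume_grid(array(out$volume, c(d[1], d[2], nz)),
                     voxel_um = measured$pixel_um)
  repro <- tilt_series(
    lapply(seq_len(K), function(k)
      matrix(out$residuals[, , k] + meas[, , k], d[1], d[2])),
    geometry$angles_deg, pixel_um = measured$pixel_um,
    provenance = "reprojected")
  hist <- as.data.frame(out$history)
  names(hist) <- c("cycle", "T", "kernel_sd", "perturb_sd", "error",
                   "accept_rate", "uphill_rate", paste0("cc_pos", seq_len(K)))
  list(volume = vol, reprojections = repro, error = out$error,
       history = hist, degenerate = out$degenerate)
}

# Reference engine: the same loop written over anneal_step(). Slow —
# intended for small volumes and validation runs.
run_engine_r <- function(measured, geometry, sched, iters, nz, truncation,
                         nonneg) {
  state <- sa_state(measured, geometry, nz)
  C <- length(sched$T)
  K <- length(measured)
  hist <- matrix(NA_real_, C, 7L + K)
  degen <- FALSE
  for (cyc in seq_len(C)) {
    state$cycle <- cyc
    state$accepted <- 0L; state$attempted <- 0L
    state$uphill_accepted <- 0L; state$uphill_attempted <- 0L
    for (i in seq_len(iters))
      state <- anneal_step(state, sched$T[cyc], sched$kernel_sd[cyc],
                           sched$perturb_sd[cyc], truncation, nonneg)
    ccs <- vapply(seq_len(K), function(k) {
      p <- state$reprojections$images[[k]]
      m <- state$measured$images[[k]]
      if (stats::sd(p) == 0 || stats::sd(m) == 0) { degen <<- TRUE; 0 }
      else stats::cor(as.vector(p), as.vector(m))
    }, 0)
    hist[cyc, ] <- c(cyc, sched$T[cyc], sched$kernel_sd[cyc],
                     sched$perturb_sd[cyc], state$error,
                     state$accepted / max(state$attempted, 1L),
                     state$uphill_accepted / max(state$uphill_attempted, 1L),
                     ccs)
  }
  hist <- as.data.frame(hist)
  names(hist) <- c("cycle", "T", "kernel_sd", "perturb_sd", "error",
                   "accept_rate", "uphill_rate", paste0("cc_pos", seq_len(K)))
  list(volume = state$volume, reprojections = state$reprojections,
       error = state$error, history = hist, degenerate = degen)
}

#' @export
print.sa_reconstruction <- function(x, ...) {
  d <- dim(x$volume)
  last <- x$history[nrow(x$history), ]
  ccs <- unlist(last[grep("^cc_pos", names(x$history))])
  cat(sprintf("<sa_reconstruction> %d x %d x %d volume, seed %d\n",
              d[1], d[2], d[3], x$seed))
  cat(sprintf("  %d cycles x %d iterations; final error %.6g\n",
              x$schedule$cycles, x$schedule$iters_per_cycle, x$error))
  cat(sprintf("  reprojection cross-correlation: min %.4f, mean %.4f\n",
              min(ccs), mean(ccs)))
  invisible(x)
}
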