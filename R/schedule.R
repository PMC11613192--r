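#' Annealing schedule
#'
#' All control constants of the simulated-annealing reconstruction and
#' their decay law. Three quantities decay together, each geometrically
#' interpolated from its initial to its final value across the outer
#' cycles: the virtual temperature `T` (10 to 0.1), the perturbation-kernel
#' standard deviation (15 to 2 voxels) and the perturbation-amplitude
#' standard deviation (0.2 to 0.1, in grey levels of the jointly
#' min-max-normalized 8-bit \[0, 255\] input images).
#' Within a cycle the three are held constant while `iters_per_cycle`
#' perturbations are attempted; the full-scale run uses 100,000 iterations
#' per cycle over 5,000 cycles.
#'
#' @param T0,Tf initial and final virtual temperature (10, 0.1).
#' @param k0,kf initial and final kernel standard deviation in voxels
#'   (15, 2).
#' @param s0,sf initial and final perturbation-amplitude standard
#'   deviation (0.2, 0.1).
#' @param cycles number of outer cycles (5000 at full scale).
#' @param iters_per_cycle inner perturbation attempts per cycle (100,000
#'   at full scale).
#' @return an object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T0 = 10, Tf = 0.1, k0 = 15, kf = 2,
                            s0 = 0.2, sf = 0.1,
                            cycles = 5000L, iters_per_cycle = 100000L) {
  if (!(T0 > Tf && Tf > 0)) stop("need T0 > Tf > 0")
  if (!(k0 >= kf && kf > 0)) stop("need k0 >= kf > 0")
  if (!(s0 >= sf && sf > 0)) stop("need s0 >= sf > 0")
  if (cycles < 1 || iters_per_cycle < 1)
    stop("cycles and iters_per_cycle must be >= 1")
  structure(list(T0 = T0, Tf = Tf, k0 = k0, kf = kf, s0 = s0, sf = sf,
                 cycles = as.integer(cycles),
                 iters_per_cycle = as.integer(iters_per_cycle)),
            class = "anneal_schedule")
}

#' @export
print.anneal_schedule <- function(x, ...) {
  cat(sprintf(paste0("<anneal_schedule> %d cycles x %d iterations\n",
                     "  T %.4g -> %.4g, kernel SD %.4g -> %.4g voxels,",
                     " perturbation SD %.4g -> %.4g\n"),
              x$cycles, x$iters_per_cycle, x$T0, x$Tf, x$k0, x$kf,
              x$s0, x$sf))
  invisible(x)
}

#' Schedule values at a given cycle
#'
#' Geometric interpolation across cycles for each controlled quantity:
#' `v(c) = v0 * (vf / v0) ^ ((c - 1) / (C - 1))`, so cycle 1 returns the
#' initial values exactly and cycle C the final values exactly. With a
#' single-cycle schedule the initial values are returned.
#'
#' @param schedule an [anneal_schedule()].
#' @param cycle cycle index, `1 <= cycle <= cycles` (vectorized).
#' @return list with numeric elements `T`, `kernel_sd`, `perturb_sd`.
#' @examples
#' s <- anneal_schedule()
#' schedule_at(s, 1)     # T = 10, kernel_sd = 15, perturb_sd = 0.2
#' schedule_at(s, 5000)  # T = 0.1, kernel_sd = 2, perturb_sd = 0.1
#' @export
schedule_at <- function(schedule, cycle) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  if (any(cycle < 1 | cycle > schedule$cycles))
    stop("cycle out of range 1..", schedule$cycles)
  t <- if (schedule$cycles == 1L) rep(0, length(cycle))
       else (cycle - 1) / (schedule$cycles - 1)
  geo <- function(v0, vf) v0 * (vf / v0)^t
  list(T = geo(schedule$T0, schedule$Tf),
       kernel_sd = geo(schedule$k0, schedule$kf),
       perturb_sd = geo(schedule$s0, schedule$sf))
}

#' Average voxel-update count of a schedule
#'
#' Total perturbation attempts divided by the voxel count, floored: at
#' full scale, 100,000 x 5,000 attempts over a 240^3 = 13,824,000-voxel
#' space give 36 updates per voxel on average.
#'
#' @param schedule an [anneal_schedule()].
#' @param n_vox total voxel count (see [n_voxels()]).
#' @return integer-valued double, `floor(cycles * iters / n_vox)`.
#' @export
updates_per_voxel <- function(schedule, n_vox) {
  stopifnot(inherits(schedule, "anneal_schedule"), n_vox > 0)
  floor(as.numeric(schedule$cycles) * schedule$iters_per_cycle / n_vox)
}

#' Boltzmann acceptance rule
#'
#' An error-decreasing change (`dE <= 0`) is accepted unconditionally. An
#' error-increasing change is accepted iff the uniform draw `u` satisfies
#' `u < exp(-dE / T)` (strict comparison), the Boltzmann probability at
#' the current virtual temperature.
#'
#' @param dE change in the reprojection error.
#' @param T current virtual temperature, `> 0`.
#' @param u a uniform(0, 1) random draw.
#' @return logical: accept the change?
#' @examples
#' boltzmann_accept(-1, 5, 0.99)          # TRUE: downhill, unconditional
#' boltzmann_accept(log(2), 1, 0.49)      # TRUE:  P = 0.5, u < P
#' boltzmann_accept(log(2), 1, 0.51)      # FALSE: P = 0.5, u > P
#' @export
boltzmann_accept <- function(dE, T, u) {
  if (!is.finite(T) || T <= 0) stop("temperature must be > 0")
  dE <= 0 | u < exp(-dE / T)
}

#' Isotropic 3D Gaussian perturbation kernel
#'
#' Weight footprint of one perturbation: an isotropic 3D Gaussian with
#' peak value 1 at the center, truncated at `truncation * sd` voxels (the
#' footprint is a cube of side `2 * ceiling(truncation * sd) + 1`). The
#' kernel is deliberately peak-normalized, not unit-sum: the perturbation
#' amplitude scales the peak.
#'
#' @param sd kernel standard deviation in voxels, `> 0`.
#' @param truncation truncation radius in multiples of `sd` (default 2).
#' @return numeric 3D array of weights in (0, 1\].
#' @export
gaussian_kernel_3d <- function(sd, truncation = 2) {
  if (!is.finite(sd) || sd <= 0) stop("kernel sd must be > 0")
  h <- ceiling(truncation * sd)
  r <- (-h):h
  g <- exp(-0.5 * (r / sd)^2)
  k <- outer(outer(g, g), g)
  dim(k) <- c(length(r), length(r), length(r))
  k
}
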