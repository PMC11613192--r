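#' Pearson cross-correlation between two images
#'
#' The per-position convergence diagnostic: Pearson correlation over all
#' pixels between a reprojection and the corresponding measured image. It
#' is symmetric and invariant to positive affine rescaling of either
#' argument. If either image has zero variance the correlation is
#' undefined; following the reconstruction's degenerate-image rule it is
#' recorded as 0 with a warning.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return correlation in \[-1, 1\].
#' @examples
#' cross_correlation(matrix(0:3, 2), matrix(c(1, 3, 2, 4), 2))  # 0.8
#' @export
cross_correlation <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance image; cross-correlation recorded as 0")
    return(0)
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Cross-correlations of a reconstruction against its inputs
#'
#' @param reprojections,measured [tilt_series()] objects of matching
#'   shape and angle ordering.
#' @return numeric vector, one correlation per position.
#' @export
series_correlations <- function(reprojections, measured) {
  check_series_match(reprojections, measured)
  vapply(seq_along(reprojections$images), function(k)
    cross_correlation(reprojections$images[[k]], measured$images[[k]]), 0)
}

#' Edge-spread spatial resolution (0.75 to 0.25 rule)
#'
#' Resolution from an averaged edge profile: after normalization the
#' distance over which the intensity falls from 0.75 to 0.25, located by
#' linear interpolation between samples, converted to nanometres by the
#' pixel size. Plateau levels are estimated robustly as the means of the
#' two end thirds of the profile; the profile is oriented bright-side
#' first, so the result is invariant to intensity scaling and to reversal
#' of the scan direction. For a step edge blurred by a Gaussian of
#' standard deviation `s` pixels the expected value is `1.349 * s` pixels
#' (twice the 0.75 normal quantile, 0.6745).
#'
#' @param intensity numeric vector: the edge profile, averaged across
#'   scan lines.
#' @param pixel_nm physical pixel size in nanometres.
#' @return resolution in nanometres.
#' @export
edge_resolution <- function(intensity, pixel_nm = 1) {
  stopifnot(is.numeric(intensity), length(intensity) >= 6,
            all(is.finite(intensity)), pixel_nm > 0)
  n <- length(intensity)
  third <- max(2L, floor(n / 3))
  lo_end <- mean(intensity[(n - third + 1):n])
  hi_end <- mean(intensity[1:third])
  if (hi_end < lo_end) {                 # orient bright side first
    intensity <- rev(intensity)
    tmp <- hi_end; hi_end <- lo_end; lo_end <- tmp
  }
  if (hi_end == lo_end) stop("profile has no edge (flat plateaus)")
  y <- (intensity - lo_end) / (hi_end - lo_end)
  x75 <- crossing_position(y, 0.75)
  x25 <- crossing_position(y, 0.25)
  abs(x25 - x75) * pixel_nm
}

# Internal: unique downward crossing of `level`, linearly interpolated
# (0-based position). Errors if the profile crosses 0, or more than one,
# time.
crossing_position <- function(y, level) {
  s <- sign(y - level)
  cross <- which(s[-length(s)] > 0 & s[-1] <= 0)
  cross <- cross[y[cross] != y[cross + 1]]
  up <- which(s[-length(s)] <= 0 & s[-1] > 0)
  if (length(cross) != 1L || length(up) > 0)
    stop("profile must cross the ", level,
         " level exactly once after normalization (found ",
         length(cross), " downward and ", length(up),
         " upward crossings); smooth or re-window the profile")
  i <- cross
  (i - 1) + (y[i] - level) / (y[i] - y[i + 1])
}

#' Extract an averaged edge profile from an image
#'
#' Averages the image across the axis perpendicular to `direction`,
#' producing the 1D profile [edge_resolution()] consumes.
#'
#' @param img numeric matrix.
#' @param direction `"x"` (profile along rows) or `"y"`.
#' @return numeric vector.
#' @export
edge_profile <- function(img, direction = c("x", "y")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(img))
  if (direction == "x") rowMeans(img) else colMeans(img)
}

#' Summarize an annealing history
#'
#' @param history the per-cycle history data.frame of a
#'   [reconstruct()] result (columns `cycle`, `T`, `error`,
#'   `cc_pos1...`).
#' @return list with `initial_error`, `final_error`, `half_life_cycle`
#'   (first cycle with error at or below half the initial error, NA if
#'   never reached), `final_T`, `final_cc_min`, `final_cc_mean`.
#' @export
history_summary <- function(history) {
  if (!is.data.frame(history) || nrow(history) == 0)
    stop("history must be a non-empty data.frame")
  cc_cols <- grep("^cc_pos", names(history))
  e0 <- history$error[1]
  ef <- history$error[nrow(history)]
  half <- which(history$error <= e0 / 2)
  ccs <- if (length(cc_cols)) unlist(history[nrow(history), cc_cols])
         else numeric(0)
  list(initial_error = e0, final_error = ef,
       half_life_cycle = if (length(half)) history$cycle[half[1]] else NA,
       final_T = history$T[nrow(history)],
       final_cc_min = if (length(ccs)) min(ccs) else NA_real_,
       final_cc_mean = if (length(ccs)) mean(ccs) else NA_real_)
}

#' Plot error, temperature and correlation histories
#'
#' Two-panel convergence diagnostic: error and virtual temperature versus
#' cycle (log-log), and the eight per-position cross-correlations versus
#' cycle.
#'
#' @param history a reconstruction history data.frame.
#' @return a ggplot object.
#' @export
plot_history <- function(history) {
  stopifnot(is.data.frame(history), nrow(history) > 0)
  cc_cols <- grep("^cc_pos", names(history), value = TRUE)
  long <- do.call(rbind, lapply(cc_cols, function(cn)
    data.frame(cycle = history$cycle, position = sub("cc_pos", "", cn),
               cc = history[[cn]])))
  ggplot2::ggplot(long, ggplot2::aes(x = cycle, y = cc,
                                     colour = position)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "annealing cycle", y = "cross-correlation",
                  colour = "position",
                  title = "Reprojection agreement by electrode position") +
    ggplot2::theme_minimal()
}
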