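#' Gaussian smoothing with a truncated, renormalized kernel
#'
#' 2D Gaussian convolution with a `ksize` x `ksize` truncated kernel
#' renormalized to unit sum, applied separably with half-sample symmetric
#' (reflective) boundary handling. With a unit-sum kernel a constant image
#' is preserved exactly, and the symmetric boundary makes the smoothing
#' operator doubly stochastic, so the image mean is preserved exactly as
#' well. The standard narrow filter of the conditioning chain uses a 7 x 7
#' kernel with SD 1.2 pixels; the broad background filter uses 201 x 201
#' with SD 100.
#'
#' @param img numeric matrix (raw amplitude or phase image).
#' @param ksize odd kernel side in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(img, ksize = 7, sigma = 1.2) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (ksize %% 2 != 1) stop("ksize must be odd")
  if (sigma <= 0) stop("sigma must be > 0")
  h <- (ksize - 1) / 2
  g <- exp(-0.5 * ((-h):h / sigma)^2)
  g <- g / sum(g)              # unit-sum 1D factor => unit-sum 2D kernel
  conv_sym <- function(m, g) {
    # pad rows by reflection (half-sample symmetric), convolve columnwise
    n <- nrow(m)
    idx <- reflect_index(c((1 - h):0, 1:n, (n + 1):(n + h)), n)
    p <- m[idx, , drop = FALSE]
    f <- stats::filter(p, g, sides = 2)
    matrix(f[(h + 1):(h + n), ], n, ncol(m))
  }
  t(conv_sym(t(conv_sym(img, g)), g))
}

# Half-sample symmetric index folding: ... 2 1 | 1 2 ... n | n n-1 ...
# iterated so kernels wider than the image remain defined.
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  j <- ifelse(j >= n, 2 * n - 1 - j, j)
  j + 1L
}

#' Background removal by broad-Gaussian subtraction
#'
#' The band-pass step of the image-conditioning chain: the narrowly
#' smoothed image (7 x 7 kernel, SD 1.2) minus the broadly smoothed image
#' (201 x 201 kernel, SD 100). Slowly varying background (constants,
#' gentle ramps) passes both filters identically and cancels, while
#' sample-scale structure survives the narrow filter but is strongly
#' attenuated by the broad one, so it is retained.
#'
#' @param img numeric matrix.
#' @param ksize,sigma narrow-filter parameters.
#' @param bg_ksize,bg_sigma broad-filter parameters.
#' @return background-subtracted matrix (zero-mean for pure backgrounds).
#' @export
remove_background <- function(img, ksize = 7, sigma = 1.2,
                              bg_ksize = 201, bg_sigma = 100) {
  if (any(dim(img) < 2)) stop("image must be larger than 1 x 1")
  gaussian_smooth(img, ksize, sigma) - gaussian_smooth(img, bg_ksize, bg_sigma)
}

#' Convert to 8-bit grey scale
#'
#' Linear rescale of the finite-valued image so the minimum maps to 0 and
#' the maximum to 255, with half-away-from-zero rounding. A constant image
#' has no range and maps to all zeros (with a warning).
#'
#' @param img numeric matrix.
#' @return integer matrix with values in 0..255.
#' @examples
#' to_uint8(matrix(c(0, 0.5, 1), 1))  # 0 128 255
#' @export
to_uint8 <- function(img) {
  stopifnot(is.matrix(img) || is.numeric(img))
  if (!all(is.finite(img))) stop("image values must be finite")
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    warning("constant image has no intensity range; converted to all 0")
    out <- img * 0
  } else {
    out <- floor((img - lo) / (hi - lo) * 255 + 0.5)
  }
  storage.mode(out) <- "integer"
  out
}

#' Full image-conditioning chain
#'
#' Narrow Gaussian smoothing, broad-Gaussian background subtraction, then
#' 8-bit conversion, in that fixed order.
#'
#' @param img numeric matrix.
#' @inheritParams remove_background
#' @param bit8 convert to 8-bit at the end (set `FALSE` to keep floats
#'   for quantitative use).
#' @return processed matrix.
#' @export
preprocess_image <- function(img, ksize = 7, sigma = 1.2,
                             bg_ksize = 201, bg_sigma = 100, bit8 = TRUE) {
  out <- remove_background(img, ksize, sigma, bg_ksize, bg_sigma)
  if (bit8) out <- to_uint8(out)
  out
}
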