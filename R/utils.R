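# Shared numerical helpers: FFT conventions, grids, validation.
#
# Conventions used throughout the package:
#  * 0-based physical indexing: pixel/voxel i has its centre at i * pixel_size.
#  * (row, col) array order; for volumes the third index is the beam axis z.
#  * Frequency axes follow the usual DFT layout (DC first); `fftshift` moves
#    DC to the array centre. Centred transforms are fftshift(fft(ifftshift(x))).

#' Stop with a classed invalid-parameter error
#' @noRd
stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("ptychotomo_invalid_parameter", "error")))
}

#' @noRd
assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

#' DFT sample frequencies (cycles per unit length)
#'
#' Equivalent to numpy's fftfreq: for n samples spaced d apart, returns
#' c(0, 1, ..., ceil(n/2)-1, -floor(n/2), ..., -1) / (n * d).
#'
#' @param n number of samples
#' @param d sample spacing
#' @return numeric vector of length n
#' @export
fft_freq <- function(n, d = 1) {
  if (n < 1) stop_invalid("'n' must be >= 1")
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' Shift DC component to (from) the array centre
#'
#' @param x vector, matrix or 3D array
#' @return array of the same shape
#' @export
fftshift <- function(x) .fftshift_gen(x, inverse = FALSE)

#' @rdname fftshift
#' @export
ifftshift <- function(x) .fftshift_gen(x, inverse = TRUE)

#' @noRd
.fftshift_gen <- function(x, inverse) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- if (inverse) ceiling(n / 2) else floor(n / 2)
    c(seq_len(n)[-seq_len(h)], seq_len(h))
  })
  if (length(d) == 1L) x[idx[[1L]]]
  else if (length(d) == 2L) x[idx[[1L]], idx[[2L]], drop = FALSE]
  else if (length(d) == 3L) x[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  else stop_invalid("fftshift supports up to 3 dimensions")
}

#' @noRd
fft2 <- function(x) stats::fft(x)

#' @noRd
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
fftn <- function(x) stats::fft(x)

#' @noRd
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Real-space sampling grid
#'
#' @param shape integer vector (rows, cols); a single number is recycled
#' @param pixel_size real-space sampling in nm per pixel
#' @return object of class `grid2d`
#' @export
grid2d <- function(shape, pixel_size) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (any(shape < 2L)) stop_invalid("grid shape entries must be >= 2")
  assert_scalar_num(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop_invalid("'pixel_size' must be > 0")
  structure(list(shape = shape, pixel_size = pixel_size), class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d px, %.4g nm/px (%.4g x %.4g nm)\n",
              x$shape[1], x$shape[2], x$pixel_size,
              x$shape[1] * x$pixel_size, x$shape[2] * x$pixel_size))
  invisible(x)
}

#' Complex wave on a grid
#'
#' @param values complex matrix
#' @param grid a [grid2d()]
#' @return object of class `complex_wave`
#' @export
complex_wave <- function(values, grid) {
  if (!all(dim(values) == grid$shape)) stop_invalid("values do not match grid shape")
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop_invalid("wave values must be finite")
  structure(list(values = values, grid = grid), class = "complex_wave")
}

#' Total intensity (sum of squared moduli) of a wave
#' @param wave a [complex_wave()]
#' @return scalar
#' @export
total_intensity <- function(wave) sum(Mod(wave$values)^2)

#' @export
print.complex_wave <- function(x, ...) {
  cat(sprintf("<complex_wave> %d x %d px, %.4g nm/px, total intensity %.6g\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$pixel_size,
              total_intensity(x)))
  invisible(x)
}

#' Squared radial frequency grid |k|^2 for a grid2d (cycles^2/nm^2, DC first)
#' @noRd
k2_grid <- function(grid) {
  ky <- fft_freq(grid$shape[1], grid$pixel_size)
  kx <- fft_freq(grid$shape[2], grid$pixel_size)
  outer(ky^2, kx^2, `+`)
}

#' Centred pixel-radius grid: distance (px) from the array centre pixel
#' (floor(n/2)+1 in 1-based terms, the DC pixel after fftshift)
#' @noRd
centre_radius_grid <- function(shape) {
  cy <- floor(shape[1] / 2) + 1L
  cx <- floor(shape[2] / 2) + 1L
  ry <- (seq_len(shape[1]) - cy)^2
  rx <- (seq_len(shape[2]) - cx)^2
  sqrt(outer(ry, rx, `+`))
}

#' Shift a 2D image by (dy, dx) pixels via the Fourier shift theorem
#'
#' Supports sub-pixel shifts; the image is treated as periodic.
#'
#' @param img numeric matrix
#' @param shift_px c(dy, dx) in pixels
#' @return shifted matrix
#' @export
fourier_shift <- function(img, shift_px) {
  ky <- fft_freq(nrow(img))
  kx <- fft_freq(ncol(img))
  ph <- exp(-2i * pi * (outer(ky * shift_px[1], kx * shift_px[2], `+`)))
  out <- ifft2(fft2(img) * ph)
  if (is.complex(img)) out else Re(out)
}

#' Derive a child RNG seed from a master seed (kept below 2^31)
#' @param master integer master seed
#' @param stage integer stage offset
#' @return integer seed
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + as.numeric(stage) * 104729) %% 2147483629)
}
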