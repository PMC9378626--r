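# Forward simulation of defocused-probe 4D-STEM data: probe x projected
# phase object (multiplicative thin-object model) -> far-field intensities,
# scaled to the electron budget per pattern, with optional Poisson shot
# noise, bright-field cropping and threshold preprocessing.
#
# Detector model: ideal counting detector (Poisson noise only, no MTF or
# readout noise). Patterns are stored fftshift-centred: the unscattered
# bright-field disc sits at the array centre. Detector pixel pitch in
# frequency is 1/(window_px * pixel_size).

#' Raster scan pattern
#'
#' Probe centres on a (rows x cols) raster with pitch `step_nm`, centred on
#' `centre_nm` (defaults to the middle of the raster extent at the origin;
#' in [simulate_4dstem()] positions are interpreted in the projection's
#' physical frame, pixel 0 at 0 nm). Optional seeded sub-pixel jitter breaks
#' raster-grid pathology; off by default.
#'
#' @param shape c(rows, cols) of the raster
#' @param step_nm scan step (nm), > 0
#' @param centre_nm c(y, x) centre of the raster (nm)
#' @param jitter_nm sd of random position jitter (nm), 0 = off
#' @param seed seed for the jitter
#' @return object of class `scan_pattern` with `positions_nm` (n x 2, raster
#'   row-major order)
#' @export
scan_pattern <- function(shape = c(10, 10), step_nm = 20,
                         centre_nm = c(0, 0), jitter_nm = 0, seed = 1) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop_invalid("scan shape entries must be >= 1")
  if (step_nm <= 0) stop_invalid("'step_nm' must be > 0")
  oy <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * step_nm
  ox <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * step_nm
  pos <- cbind(rep(oy, each = shape[2]) + centre_nm[1],
               rep(ox, times = shape[1]) + centre_nm[2])
  if (jitter_nm > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    pos <- pos + matrix(stats::rnorm(length(pos), sd = jitter_nm), ncol = 2)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  colnames(pos) <- c("y_nm", "x_nm")
  structure(list(positions_nm = pos, step_nm = step_nm, shape = shape),
            class = "scan_pattern")
}

#' Simulate a 4D-STEM dataset from a 2D phase projection
#'
#' For each scan position p the exit wave is
#' \eqn{\psi_p(r) = P(r - p)\,e^{i\varphi(r)}} on a fixed `window_px` crop
#' centred on the probe; the recorded pattern is \eqn{|F\psi_p|^2} scaled so
#' its total equals the electron budget `dose$electrons_per_pattern`, then
#' Poisson sampled unless `noiseless`.
#'
#' Scan positions are rounded to the nearest projection pixel (the rounded
#' positions are stored); every probe window must lie fully inside the
#' projection.
#'
#' @param projection 2D phase image (radians), matrix
#' @param pixel_size_nm projection sampling (nm/px)
#' @param optics an [optics_config()] (defocus gives the probe)
#' @param scan a [scan_pattern()]; positions in the projection frame where
#'   pixel (0,0) is at 0 nm
#' @param dose a [dose_spec()]
#' @param window_px detector/probe window size (pixels, power of two
#'   recommended)
#' @param seed RNG seed for the shot noise
#' @param noiseless skip Poisson sampling
#' @return object of class `diffraction_stack`: `intensities`
#'   (n_pos x window_px x window_px, centred patterns), `positions_px`
#'   (integer probe-centre pixels, 0-based), `probe` (the simulation probe),
#'   plus scan/optics/dose/geometry metadata
#' @export
simulate_4dstem <- function(projection, pixel_size_nm, optics, scan, dose,
                            window_px = 64, seed = 1, noiseless = FALSE) {
  if (dose$dose_per_area < 0) stop_invalid("negative dose")
  wgrid <- grid2d(window_px, pixel_size_nm)
  probe <- make_probe(wgrid, optics)
  half <- window_px %/% 2
  pos_px <- round(scan$positions_nm / pixel_size_nm)
  d <- dim(projection)
  if (any(pos_px[, 1] - half < 0) || any(pos_px[, 1] + half > d[1]) ||
      any(pos_px[, 2] - half < 0) || any(pos_px[, 2] + half > d[2]))
    stop(errorCondition(
      "probe window extends outside the projection at some scan position",
      class = c("ptychotomo_field_of_view_error", "error")))
  n_pos <- nrow(pos_px)
  ne <- dose$electrons_per_pattern
  inten <- array(0, dim = c(n_pos, window_px, window_px))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (j in seq_len(n_pos)) {
    ys <- (pos_px[j, 1] - half + 1):(pos_px[j, 1] + half)
    xs <- (pos_px[j, 2] - half + 1):(pos_px[j, 2] + half)
    psi <- probe$values * exp(1i * projection[ys, xs])
    pat <- Mod(fft2(psi))^2
    pat <- pat * (ne / sum(pat))
    if (!noiseless && ne > 0)
      pat <- array(stats::rpois(length(pat), pat), dim = dim(pat))
    inten[j, , ] <- fftshift(pat)
  }
  lam <- electron_wavelength(optics$voltage_kv)
  bf_radius_px <- (optics$alpha_mrad * 1e-3 / lam) * window_px * pixel_size_nm
  structure(list(intensities = inten, positions_px = pos_px,
                 scan = scan, optics = optics, dose = dose,
                 pixel_size_nm = pixel_size_nm, window_px = window_px,
                 bf_radius_px = bf_radius_px, probe = probe, seed = seed,
                 noiseless = noiseless, cropped_radius_factor = NA_real_,
                 threshold = 0),
            class = "diffraction_stack")
}

#' @export
print.diffraction_stack <- function(x, ...) {
  cat(sprintf(paste0("<diffraction_stack> %d patterns of %d x %d px, ",
                     "%.4g nm/px\n  dose %.4g e-/A^2 (%.4g e-/pattern), ",
                     "BF radius %.3g px, seed %d%s\n"),
              dim(x$intensities)[1], x$window_px, x$window_px,
              x$pixel_size_nm, x$dose$dose_per_area,
              x$dose$electrons_per_pattern, x$bf_radius_px, x$seed,
              if (isTRUE(x$noiseless)) ", noiseless" else ""))
  invisible(x)
}

#' Restrict patterns to the bright-field disc
#'
#' Zeroes detector pixels beyond `radius_factor` times the bright-field disc
#' radius; only the signal inside the disc then drives the reconstruction.
#'
#' @param stack a `diffraction_stack`
#' @param radius_factor multiple of the BF radius to keep, >= 1
#' @return modified stack (operation recorded in `cropped_radius_factor`)
#' @export
crop_to_bf <- function(stack, radius_factor = 1) {
  if (radius_factor < 1) stop_invalid("'radius_factor' must be >= 1")
  r <- centre_radius_grid(c(stack$window_px, stack$window_px))
  keep <- r <= radius_factor * stack$bf_radius_px
  n_pos <- dim(stack$intensities)[1]
  for (j in seq_len(n_pos))
    stack$intensities[j, , ] <- stack$intensities[j, , ] * keep
  stack$cropped_radius_factor <- radius_factor
  stack
}

#' Threshold preprocessing of recorded counts
#'
#' Sets pixels with counts below `threshold` to 0 (dark-noise suppression on
#' real detectors; the default 0 is an identity for synthetic data).
#'
#' @param stack a `diffraction_stack`
#' @param threshold counts, >= 0
#' @return modified stack
#' @export
threshold_preprocess <- function(stack, threshold = 0) {
  if (threshold < 0) stop_invalid("'threshold' must be >= 0")
  stack$intensities[stack$intensities < threshold] <- 0
  stack$threshold <- threshold
  stack
}
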