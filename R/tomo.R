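# Tilt-series handling: translational alignment by phase correlation
# (cosine-stretched running reference) and 3D reconstruction by a Fourier
# iterative algorithm in the GENFIRE style: measured projection spectra are
# gridded onto an oversampled 3D frequency grid by the Fourier slice
# theorem, then alternately constrained in real space (positivity, optional
# support) and reset to the measured values in Fourier space.

#' Tilt series of 2D phase projections
#'
#' @param projections 3D array (n_proj x rows x cols) or list of matrices,
#'   phase in radians on a common grid
#' @param orientations list of [orientation()], one per projection
#' @param pixel_size_nm common sampling (nm/px)
#' @param defocus_nm per-tilt defocus values (nm); recycled if length 1
#' @param shifts_px per-projection applied (dy, dx) alignment shifts
#' @return object of class `tilt_series`
#' @export
tilt_series <- function(projections, orientations, pixel_size_nm = 1,
                        defocus_nm = 0, shifts_px = NULL) {
  if (is.list(projections)) {
    projections <- aperm(simplify2array(projections), c(3, 1, 2))
  }
  n <- dim(projections)[1]
  if (length(orientations) != n)
    stop_invalid("need one orientation per projection")
  if (length(defocus_nm) == 1L) defocus_nm <- rep(defocus_nm, n)
  if (length(defocus_nm) != n)
    stop_invalid("need one defocus per projection")
  if (is.null(shifts_px)) shifts_px <- matrix(0, n, 2)
  structure(list(projections = projections, orientations = orientations,
                 pixel_size_nm = pixel_size_nm, defocus_nm = defocus_nm,
                 shifts_px = shifts_px, warnings = logical(n)),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("<tilt_series> %d projections of %d x %d px, %.3g nm/px\n",
              d[1], d[2], d[3], x$pixel_size_nm))
  invisible(x)
}

#' Correlation shift between two images
#'
#' Returns the (dy, dx) shift such that `b` best matches
#' `fourier_shift(a, shift)`. Both images are mean-subtracted and windowed
#' by a soft-edged circular mask, then correlated via FFT. The default
#' `method = "xcorr"` (plain cross-correlation) is markedly more robust
#' than classic phase correlation when the two images are projections at
#' neighbouring tilt angles (decorrelated content); `method = "phase"`
#' whitens the cross-power spectrum first. Sub-pixel position from a
#' parabolic fit around the correlation peak unless `subpixel = FALSE`, in
#' which case the integer peak lag is returned.
#'
#' @param a,b equally sized numeric matrices
#' @param method "xcorr" or "phase"
#' @param subpixel parabolic sub-pixel refinement (default TRUE)
#' @return c(dy, dx) in pixels, with the normalized correlation peak as
#'   attribute `"peak"`
#' @export
correlate_shift <- function(a, b, method = c("xcorr", "phase"),
                            subpixel = TRUE) {
  method <- match.arg(method)
  n <- dim(a)
  m <- soft_mask(n)
  wa <- (a - mean(a)) * m
  wb <- (b - mean(b)) * m
  R <- fft2(wb) * Conj(fft2(wa))
  if (method == "phase") R <- R / pmax(Mod(R), 1e-12)
  cc <- Re(ifft2(R))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  parfit <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (cm - cp) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dy <- dx <- 0
  if (subpixel) {
    dy <- parfit(cc[wrap(pk[1] - 1, n[1]), pk[2]], cc[pk[1], pk[2]],
                 cc[wrap(pk[1] + 1, n[1]), pk[2]])
    dx <- parfit(cc[pk[1], wrap(pk[2] - 1, n[2])], cc[pk[1], pk[2]],
                 cc[pk[1], wrap(pk[2] + 1, n[2])])
  }
  sh <- c(pk[1] - 1, pk[2] - 1) + c(dy, dx)
  sh <- ((sh + n / 2) %% n) - n / 2   # wrap to [-n/2, n/2)
  structure(sh, peak = max(cc) /
              sqrt(sum(wa^2) * sum(wb^2)))
}

#' @rdname correlate_shift
#' @export
phase_correlate <- function(a, b) correlate_shift(a, b, method = "phase")

#' Stretch an image about its centre (anisotropic scaling, bilinear)
#' @noRd
stretch_image <- function(img, fy = 1, fx = 1) {
  n <- dim(img)
  cy <- (n[1] - 1) / 2; cx <- (n[2] - 1) / 2
  ys <- (seq_len(n[1]) - 1 - cy) / fy + cy
  xs <- (seq_len(n[2]) - 1 - cx) / fx + cx
  y0 <- floor(ys); x0 <- floor(xs)
  wy <- ys - y0; wx <- xs - x0
  at <- function(iy, ix) {
    iy <- pmin(pmax(iy, 0), n[1] - 1); ix <- pmin(pmax(ix, 0), n[2] - 1)
    img[cbind(rep(iy + 1, times = n[2]), rep(ix + 1, each = n[1]))]
  }
  m <- matrix(0, n[1], n[2])
  m <- (1 - wy) %o% (1 - wx) * matrix(at(y0, x0), n[1]) +
       wy %o% (1 - wx) * matrix(at(y0 + 1, x0), n[1]) +
       (1 - wy) %o% wx * matrix(at(y0, x0 + 1), n[1]) +
       wy %o% wx * matrix(at(y0 + 1, x0 + 1), n[1])
  m
}

#' Translational alignment of a tilt series
#'
#' Estimates per-projection shifts by phase correlation against the running
#' aligned neighbour; before correlating, the neighbour is cosine-stretched
#' along the foreshortened axis to compensate the tilt difference. Shifts
#' are applied by Fourier shift and accumulated in `shifts_px`. A projection
#' whose correlation peak falls below `peak_threshold` is flagged in
#' `warnings` (alignment still applied).
#'
#' @param series a [tilt_series()] with >= 2 projections
#' @param reference index of the anchor projection (default: the one with
#'   the smallest total tilt); its shift is 0 by definition
#' @param peak_threshold normalized-correlation quality threshold in [0, 1]
#' @param method correlation method, see [correlate_shift()]
#' @param subpixel sub-pixel shift estimation (FALSE = integer shifts)
#' @return aligned [tilt_series()]
#' @export
align_projections <- function(series, reference = NULL,
                              peak_threshold = 0.1,
                              method = "xcorr", subpixel = TRUE) {
  n <- dim(series$projections)[1]
  if (n < 2) stop_invalid("need >= 2 projections to align")
  tilts <- vapply(series$orientations,
                  function(o) abs(o$tilt1_deg) + abs(o$tilt2_deg), numeric(1))
  if (is.null(reference)) reference <- which.min(tilts)
  ordv <- order(abs(seq_len(n) - reference))
  aligned <- series$projections
  for (idx in ordv) {
    if (idx == reference) next
    nb <- idx + if (idx > reference) -1L else 1L
    ref_img <- aligned[nb, , ]
    oc <- series$orientations[[idx]]; or <- series$orientations[[nb]]
    fy <- cos(oc$tilt2_deg * pi / 180) / cos(or$tilt2_deg * pi / 180)
    fx <- cos(oc$tilt1_deg * pi / 180) / cos(or$tilt1_deg * pi / 180)
    if (abs(fy - 1) > 1e-12 || abs(fx - 1) > 1e-12)
      ref_img <- stretch_image(ref_img, fy, fx)
    sh <- correlate_shift(ref_img, aligned[idx, , ], method, subpixel)
    if (attr(sh, "peak") < peak_threshold) series$warnings[idx] <- TRUE
    aligned[idx, , ] <- fourier_shift(aligned[idx, , ], -as.numeric(sh))
    series$shifts_px[idx, ] <- series$shifts_px[idx, ] - as.numeric(sh)
  }
  series$projections <- aligned
  series
}

#' Centred FFT helpers
#' @noRd
cfft <- function(x) fftshift(stats::fft(ifftshift(x)))
#' @noRd
cifft <- function(x) fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / length(x)

#' Fourier iterative (GENFIRE-style) tomographic reconstruction
#'
#' Each projection is zero-padded by `oversampling`, Fourier transformed,
#' and its samples are placed on the oversampled 3D frequency grid at the
#' coordinates given by the Fourier slice theorem for its orientation;
#' samples within `interpolation_radius_px` of a grid point contribute with
#' inverse-distance weights (distance floored at 1e-3 px; collisions
#' averaged by weight). The volume is then refined by alternating real-space
#' constraints (positivity, optional support) with resetting the measured
#' Fourier samples.
#'
#' @param series an aligned [tilt_series()]
#' @param oversampling zero-padding factor (default 2)
#' @param interpolation_radius_px gridding radius (default 0.7)
#' @param n_iterations constraint iterations (default 100)
#' @param positivity enforce non-negativity (default TRUE)
#' @param support optional logical 3D array (original N^3 grid), TRUE inside
#'   the allowed region
#' @return object of class `volume3d`: `values` (N^3 array, phase density in
#'   rad/nm), `voxel_size_nm`, `provenance`
#' @export
genfire_reconstruct <- function(series, oversampling = 2,
                                interpolation_radius_px = 0.7,
                                n_iterations = 100, positivity = TRUE,
                                support = NULL) {
  P <- series$projections
  n_proj <- dim(P)[1]
  N <- dim(P)[2]
  if (dim(P)[3] != N) stop_invalid("projections must be square")
  if (n_proj < 3)
    warning("fewer than 3 projections: reconstruction will be very poor")
  t1 <- vapply(series$orientations, `[[`, numeric(1), "tilt1_deg")
  t2 <- vapply(series$orientations, `[[`, numeric(1), "tilt2_deg")
  if (max(t1) - min(t1) < 60 && max(t2) - min(t2) < 60)
    warning("angular range < 60 degrees: expect severe missing-wedge artefacts")
  M <- as.integer(oversampling * N)
  pad0 <- (M - N) %/% 2
  vs <- series$pixel_size_nm

  # centred integer frequency coordinates of a projection slice
  kc <- seq_len(M) - (floor(M / 2) + 1L)
  ky <- rep(kc, times = M); kx <- rep(kc, each = M)
  half_lim <- M / 2 - 1

  re_acc <- numeric(M^3); im_acc <- numeric(M^3); w_acc <- numeric(M^3)
  for (p in seq_len(n_proj)) {
    img <- matrix(0, M, M)
    img[pad0 + seq_len(N), pad0 + seq_len(N)] <- P[p, , ]
    Fp <- cfft(img) / vs            # values on the 3D-DFT scale
    R <- orientation_matrix(series$orientations[[p]])
    q <- t(R) %*% rbind(ky, kx, 0)  # slice-theorem coordinates
    ok <- abs(q[1, ]) <= half_lim & abs(q[2, ]) <= half_lim &
          abs(q[3, ]) <= half_lim
    qv <- q[, ok, drop = FALSE]
    fv <- as.vector(Fp)[ok]
    f0 <- floor(qv)
    for (dy in 0:1) for (dx in 0:1) for (dz in 0:1) {
      gy <- f0[1, ] + dy; gx <- f0[2, ] + dx; gz <- f0[3, ] + dz
      dist <- sqrt((qv[1, ] - gy)^2 + (qv[2, ] - gx)^2 + (qv[3, ] - gz)^2)
      sel <- dist <= interpolation_radius_px
      if (!any(sel)) next
      w <- 1 / pmax(dist[sel], 1e-3)
      lin <- (gy[sel] + floor(M / 2)) +
             (gx[sel] + floor(M / 2)) * M +
             (gz[sel] + floor(M / 2)) * M^2 + 1
      sums <- rowsum(cbind(Re(fv[sel]) * w, Im(fv[sel]) * w, w), lin)
      ii <- as.integer(rownames(sums))
      re_acc[ii] <- re_acc[ii] + sums[, 1]
      im_acc[ii] <- im_acc[ii] + sums[, 2]
      w_acc[ii] <- w_acc[ii] + sums[, 3]
    }
  }
  mask <- w_acc > 0
  if (!any(mask))
    stop(errorCondition("empty Fourier constraint set",
                        class = c("ptychotomo_degenerate_data", "error")))
  meas <- complex(real = re_acc[mask] / w_acc[mask],
                  imaginary = im_acc[mask] / w_acc[mask])

  S <- array(0 + 0i, dim = c(M, M, M))
  S[mask] <- meas
  sup_big <- NULL
  if (!is.null(support)) {
    sup_big <- array(FALSE, dim = c(M, M, M))
    sup_big[pad0 + seq_len(N), pad0 + seq_len(N), pad0 + seq_len(N)] <- support
  }
  v <- NULL
  for (it in seq_len(n_iterations)) {
    v <- Re(cifft(S))
    if (anyNA(v))
      stop(errorCondition(sprintf("NaN in reconstruction at iteration %d", it),
                          class = c("ptychotomo_numerical_failure", "error")))
    if (positivity) v[v < 0] <- 0
    if (!is.null(sup_big)) v[!sup_big] <- 0
    S <- cfft(v)
    S[mask] <- meas
  }
  v <- Re(cifft(S))
  if (positivity) v[v < 0] <- 0
  if (!is.null(sup_big)) v[!sup_big] <- 0
  out <- v[pad0 + seq_len(N), pad0 + seq_len(N), pad0 + seq_len(N)]
  structure(list(values = out, voxel_size_nm = vs,
                 provenance = list(n_proj = n_proj,
                                   oversampling = oversampling,
                                   interpolation_radius_px =
                                     interpolation_radius_px,
                                   n_iterations = n_iterations,
                                   positivity = positivity)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.3g nm/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size_nm, min(x$values), max(x$values)))
  invisible(x)
}

#' Reproject a reconstructed volume at an orientation
#'
#' Uses the same projector (rotate then integrate along the beam axis) as
#' [project_phantom()], for data-consistency checks.
#'
#' @param volume a `volume3d` or plain 3D array
#' @param orient an [orientation()]
#' @param voxel_size_nm voxel size when `volume` is a plain array
#' @return matrix of projected values
#' @export
reproject <- function(volume, orient = orientation(), voxel_size_nm = NULL) {
  if (inherits(volume, "volume3d")) {
    project_phantom(volume$values, orient, volume$voxel_size_nm)
  } else {
    project_phantom(volume, orient,
                    if (is.null(voxel_size_nm)) 1 else voxel_size_nm)
  }
}

#' Intensity-weighted centroids of bright particles in a volume
#'
#' Thresholds at `threshold_frac` of the maximum, labels the resulting
#' voxels by 6-connected components, keeps the `n_particles` largest, and
#' returns their intensity-weighted centroids (0-based voxel coordinates,
#' ordered by z).
#'
#' @param volume a `volume3d` or 3D array
#' @param n_particles expected particle count
#' @param threshold_frac threshold as a fraction of the volume maximum
#' @return matrix (n_particles x 3) of (y, x, z) centroids in voxels
#' @export
find_particle_centroids <- function(volume, n_particles = 2,
                                    threshold_frac = 0.5) {
  v <- if (inherits(volume, "volume3d")) volume$values else volume
  d <- dim(v)
  mask <- v >= threshold_frac * max(v)
  lab <- array(0L, dim = d)
  cur <- 0L
  idx_all <- which(mask)
  offs <- c(-1, 1, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  coord <- function(lin) {
    lin0 <- lin - 1
    cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
  }
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      x0 <- queue[1]; queue <- queue[-1]
      cz <- coord(x0)
      for (k in seq_along(offs)) {
        nb <- x0 + offs[k]
        if (nb < 1 || nb > length(v)) next
        # forbid wrap across array faces
        cn <- coord(nb)
        if (sum(abs(cn - cz)) != 1) next
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- cur; queue <- c(queue, nb) }
      }
    }
  }
  if (cur < n_particles)
    stop(errorCondition(sprintf(
      "found only %d connected components above threshold", cur),
      class = c("ptychotomo_degenerate_data", "error")))
  sizes <- tabulate(lab[lab > 0], nbins = cur)
  keep <- order(sizes, decreasing = TRUE)[seq_len(n_particles)]
  cents <- t(vapply(keep, function(ci) {
    lin <- which(lab == ci)
    w <- v[lin]
    colSums(coord(lin) * w) / sum(w)
  }, numeric(3)))
  colnames(cents) <- c("y", "x", "z")
  cents[order(cents[, "z"]), , drop = FALSE]
}
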