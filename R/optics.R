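# Electron-optical constants, analytic resolution/dose formulas, probe
# formation and free-space propagation.
#
# Units: lengths nm, angles mrad at the interface (radians internally),
# voltage kV, dose e-/A^2, spherical aberration mm.
#
# Sign conventions (pinned by a regression test):
#  * defocus < 0 means underfocus; the reference acquisition probe is formed at
#    defocus_nm = -4e4 (i.e. -40 um).
#  * aberration phase chi(k) = pi*lambda*df*k^2 + (pi/2)*Cs*lambda^3*k^4 is
#    applied to the aperture as exp(-1i * chi); free-space propagation over
#    dz multiplies the spectrum by exp(-1i * pi * lambda * dz * k^2), so
#    propagating a probe formed at defocus df by dz = -df refocuses it
#    exactly.

# CODATA 2018 constants (SI)
.codata <- list(
  h  = 6.62607015e-34,   # Planck constant, J s
  m0 = 9.1093837015e-31, # electron rest mass, kg
  e  = 1.602176634e-19,  # elementary charge, C
  c  = 2.99792458e8      # speed of light, m/s
)

#' Electron-optical configuration
#'
#' @param voltage_kv accelerating voltage (kV)
#' @param alpha_mrad probe-forming convergence semi-angle (mrad)
#' @param beta_mrad collection semi-angle (mrad). Defaults to `alpha_mrad`,
#'   the bright-field-only case in which the transfer band
#'   \eqn{\lambda/(\alpha+\beta)} reduces to \eqn{\lambda/(2\alpha)}.
#' @param defocus_nm signed defocus (nm); negative = underfocus
#' @param cs_mm spherical aberration coefficient (mm); 0 for an
#'   aberration-corrected instrument
#' @return object of class `optics_config`
#' @examples
#' opt <- optics_config(60, 1.5, defocus_nm = -40e3)
#' electron_wavelength(opt$voltage_kv)
#' @export
optics_config <- function(voltage_kv, alpha_mrad, beta_mrad = alpha_mrad,
                          defocus_nm = 0, cs_mm = 0) {
  assert_scalar_num(voltage_kv, "voltage_kv")
  assert_scalar_num(alpha_mrad, "alpha_mrad")
  assert_scalar_num(beta_mrad, "beta_mrad")
  assert_scalar_num(defocus_nm, "defocus_nm")
  assert_scalar_num(cs_mm, "cs_mm")
  if (voltage_kv <= 0) stop_invalid("'voltage_kv' must be > 0")
  if (alpha_mrad <= 0) stop_invalid("'alpha_mrad' must be > 0")
  if (beta_mrad < alpha_mrad) stop_invalid("'beta_mrad' must be >= alpha_mrad")
  if (cs_mm < 0) stop_invalid("'cs_mm' must be >= 0")
  structure(list(voltage_kv = voltage_kv, alpha_mrad = alpha_mrad,
                 beta_mrad = beta_mrad, defocus_nm = defocus_nm,
                 cs_mm = cs_mm),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(paste0("<optics_config> %g kV, alpha %g mrad, beta %g mrad, ",
                     "defocus %g nm, Cs %g mm\n   lambda = %.6g nm\n"),
              x$voltage_kv, x$alpha_mrad, x$beta_mrad, x$defocus_nm, x$cs_mm,
              electron_wavelength(x$voltage_kv)))
  invisible(x)
}

#' Relativistic electron wavelength
#'
#' \eqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / (2 m_0 c^2))}} with CODATA
#' 2018 constants.
#'
#' @param voltage_kv accelerating voltage (kV)
#' @return wavelength (nm)
#' @examples
#' electron_wavelength(60)   # ~0.004866 nm
#' @export
electron_wavelength <- function(voltage_kv) {
  assert_scalar_num(voltage_kv, "voltage_kv")
  if (voltage_kv <= 0) stop_invalid("'voltage_kv' must be > 0")
  V <- voltage_kv * 1e3
  with(.codata,
       h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * c^2))) * 1e9)
}

#' Theoretical ptychographic transfer-band resolution
#'
#' The diffraction-limited resolution of a ptychographic reconstruction,
#' \eqn{\lambda/(\alpha+\beta)}. With the collection angle defaulted to the
#' convergence angle (bright-field disc only) this is \eqn{\lambda/(2\alpha)}.
#'
#' @param optics an [optics_config()]
#' @return resolution (nm)
#' @examples
#' ptycho_resolution(optics_config(60, 1.5))   # 1.62 nm
#' @export
ptycho_resolution <- function(optics) {
  lam <- electron_wavelength(optics$voltage_kv)
  lam / ((optics$alpha_mrad + optics$beta_mrad) * 1e-3)
}

#' Aberration phase chi(k) in radians; k in cycles/nm
#' @noRd
aberration_phase <- function(k2, lambda_nm, defocus_nm, cs_mm) {
  cs_nm <- cs_mm * 1e6
  pi * lambda_nm * defocus_nm * k2 + (pi / 2) * cs_nm * lambda_nm^3 * k2^2
}

#' First zero crossing of the phase contrast transfer function
#'
#' With `cs_mm = 0` the first zero of \eqn{\sin\chi} lies at
#' \eqn{|\chi| = \pi}, giving the closed form \eqn{d = \sqrt{\lambda |\Delta f|}}.
#' With spherical aberration the first positive root of \eqn{\sin\chi(k)} is
#' located numerically (bisection, relative tolerance 1e-6).
#'
#' @param optics an [optics_config()]; requires nonzero defocus or Cs
#' @return resolution d = 1/k of the first CTF zero (nm)
#' @examples
#' ctf_first_zero(optics_config(60, 1.5, defocus_nm = -2800))  # 3.69 nm
#' @export
ctf_first_zero <- function(optics) {
  lam <- electron_wavelength(optics$voltage_kv)
  df <- optics$defocus_nm
  cs <- optics$cs_mm
  if (df == 0 && cs == 0)
    stop(errorCondition("CTF has no zero crossing: defocus and Cs are both 0",
                        class = c("ptychotomo_no_zero_crossing", "error")))
  if (cs == 0) return(sqrt(lam * abs(df)))
  # scan for the first sign change of sin(chi) away from k = 0, then bisect
  kmax <- 2 / sqrt(lam * max(abs(df), 1)) + (2 / (lam^3 * cs * 1e6))^0.25
  ks <- seq(0, kmax, length.out = 20000L)[-1L]
  s <- sin(aberration_phase(ks^2, lam, df, cs))
  flip <- which(s[-1L] * s[-length(s)] <= 0 & abs(s[-1L] - s[-length(s)]) > 0)
  if (!length(flip))
    stop(errorCondition("no CTF zero crossing found in scanned band",
                        class = c("ptychotomo_no_zero_crossing", "error")))
  f <- function(k) sin(aberration_phase(k^2, lam, df, cs))
  r <- stats::uniroot(f, c(ks[flip[1L]], ks[flip[1L] + 1L]), tol = 1e-6 * ks[flip[1L]])
  1 / r$root
}

#' Geometric-optics diameter of a defocused probe
#'
#' \eqn{2 \alpha |\Delta f|}: at defocus the converging cone illuminates a
#' disc of this diameter at the specimen (0 at exact focus; the
#' diffraction-limited Airy width is then the physical floor).
#'
#' @param optics an [optics_config()]
#' @return disc diameter (nm)
#' @examples
#' probe_geometric_diameter(optics_config(60, 1.5, defocus_nm = -40e3)) # 120
#' @export
probe_geometric_diameter <- function(optics) {
  2 * optics$alpha_mrad * 1e-3 * abs(optics$defocus_nm)
}

#' Linear probe-overlap ratio of adjacent scan positions
#'
#' The linear definition \eqn{\max(0, 1 - s/d)} for step s and probe
#' diameter d (20 nm step on a 120 nm probe gives 83%). The areal overlap of
#' two discs at centre distance s is returned as attribute `"areal"`.
#'
#' @param step_nm scan step (nm), >= 0
#' @param diameter_nm probe diameter (nm), > 0
#' @return linear overlap fraction in [0, 1]
#' @export
overlap_ratio <- function(step_nm, diameter_nm) {
  assert_scalar_num(step_nm, "step_nm")
  assert_scalar_num(diameter_nm, "diameter_nm")
  if (diameter_nm <= 0) stop_invalid("'diameter_nm' must be > 0")
  if (step_nm < 0) stop_invalid("'step_nm' must be >= 0")
  lin <- max(0, 1 - step_nm / diameter_nm)
  r <- diameter_nm / 2
  areal <- if (step_nm >= diameter_nm) 0 else {
    (2 * r^2 * acos(step_nm / (2 * r)) -
       step_nm / 2 * sqrt(4 * r^2 - step_nm^2)) / (pi * r^2)
  }
  structure(lin, areal = areal)
}

#' Dose accounting for a tilt series
#'
#' @param dose_per_tilt dose per tilt (e-/A^2), >= 0
#' @param n_tilts number of tilt angles
#' @return total dose (e-/A^2)
#' @examples
#' total_dose(88, 23)   # 2024
#' @export
total_dose <- function(dose_per_tilt, n_tilts) {
  assert_scalar_num(dose_per_tilt, "dose_per_tilt")
  if (dose_per_tilt < 0 || n_tilts < 0) stop_invalid("dose inputs must be >= 0")
  dose_per_tilt * n_tilts
}

#' Electrons delivered per diffraction pattern
#'
#' N = dose (e-/A^2) x (step in A)^2; one pattern's electron budget when the
#' probe advances by `step_nm` between exposures.
#'
#' @param dose_per_area dose (e-/A^2)
#' @param step_nm scan step (nm)
#' @return electron count
#' @examples
#' electrons_per_pattern(88, 20)   # 3.52e6
#' @export
electrons_per_pattern <- function(dose_per_area, step_nm) {
  assert_scalar_num(dose_per_area, "dose_per_area")
  assert_scalar_num(step_nm, "step_nm")
  if (dose_per_area < 0) stop_invalid("'dose_per_area' must be >= 0")
  if (step_nm <= 0) stop_invalid("'step_nm' must be > 0")
  dose_per_area * (step_nm * 10)^2
}

#' Dose specification for a scan
#'
#' @param dose_per_area dose (e-/A^2)
#' @param step_nm scan step (nm)
#' @return object of class `dose_spec` with derived `electrons_per_pattern`
#' @export
dose_spec <- function(dose_per_area, step_nm) {
  structure(list(dose_per_area = dose_per_area, step_nm = step_nm,
                 electrons_per_pattern =
                   electrons_per_pattern(dose_per_area, step_nm)),
            class = "dose_spec")
}

#' Form a defocused (or focused) probe wave
#'
#' Hard circular aperture of radius \eqn{\alpha/\lambda} in frequency space,
#' aberration phase \eqn{\chi(k)} applied as \eqn{e^{-i\chi}}, inverse
#' transformed and centred in the field, with total intensity normalized
#' to 1.
#'
#' @param grid a [grid2d()]; its Nyquist frequency must exceed
#'   \eqn{\alpha/\lambda} and the geometric probe disc must fit in the field
#' @param optics an [optics_config()]
#' @return a [complex_wave()] centred in the field
#' @export
make_probe <- function(grid, optics) {
  lam <- electron_wavelength(optics$voltage_kv)
  kmax <- optics$alpha_mrad * 1e-3 / lam
  nyq <- 1 / (2 * grid$pixel_size)
  if (kmax >= nyq)
    stop(errorCondition(sprintf(
      "aperture radius %.4g /nm exceeds grid Nyquist %.4g /nm", kmax, nyq),
      class = c("ptychotomo_sampling_error", "error")))
  fov <- min(grid$shape) * grid$pixel_size
  if (probe_geometric_diameter(optics) > fov)
    stop(errorCondition(sprintf(
      "geometric probe diameter %.4g nm exceeds field of view %.4g nm",
      probe_geometric_diameter(optics), fov),
      class = c("ptychotomo_field_of_view_error", "error")))
  k2 <- k2_grid(grid)
  ap <- sqrt(k2) <= kmax
  chi <- aberration_phase(k2, lam, optics$defocus_nm, optics$cs_mm)
  A <- ifelse(ap, exp(-1i * chi), 0 + 0i)
  p <- fftshift(ifft2(A))
  p <- p / sqrt(sum(Mod(p)^2))
  complex_wave(p, grid)
}

#' Free-space (Fresnel) propagation of a wave
#'
#' Angular-spectrum propagation by distance `dz_nm`. The default paraxial
#' kernel multiplies the spectrum by \eqn{\exp(-i\pi\lambda\,dz\,|k|^2)};
#' `exact = TRUE` uses the full square-root kernel
#' \eqn{\exp(-i 2\pi dz (1/\lambda - \sqrt{1/\lambda^2 - |k|^2}))} with
#' evanescent components zeroed. Both are unitary on propagating components.
#'
#' @param wave a [complex_wave()]
#' @param dz_nm propagation distance (nm); sign follows the defocus
#'   convention, so propagating by `-defocus_nm` refocuses a defocused probe
#' @param lambda_nm wavelength (nm)
#' @param exact use the non-paraxial kernel
#' @return propagated [complex_wave()]
#' @export
propagate <- function(wave, dz_nm, lambda_nm, exact = FALSE) {
  assert_scalar_num(dz_nm, "dz_nm")
  assert_scalar_num(lambda_nm, "lambda_nm")
  if (lambda_nm <= 0) stop_invalid("'lambda_nm' must be > 0")
  k2 <- k2_grid(wave$grid)
  H <- if (!exact) {
    exp(-1i * pi * lambda_nm * dz_nm * k2)
  } else {
    arg <- 1 / lambda_nm^2 - k2
    Hk <- ifelse(arg >= 0, exp(-2i * pi * dz_nm * (1 / lambda_nm - sqrt(pmax(arg, 0)))), 0 + 0i)
    Hk
  }
  complex_wave(ifft2(fft2(wave$values) * H), wave$grid)
}

#' Diameter enclosing a given fraction of a wave's intensity
#'
#' Radially integrates |wave|^2 about the field centre and returns twice the
#' radius at which the enclosed energy first reaches `fraction`.
#'
#' @param wave a [complex_wave()]
#' @param fraction enclosed-energy fraction (default 0.9)
#' @return diameter (nm)
#' @export
encircled_energy_diameter <- function(wave, fraction = 0.9) {
  inten <- Mod(wave$values)^2
  inten <- inten / sum(inten)
  r <- centre_radius_grid(wave$grid$shape)
  o <- order(r)
  cum <- cumsum(inten[o])
  i <- which(cum >= fraction)[1L]
  2 * r[o][i] * wave$grid$pixel_size
}
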