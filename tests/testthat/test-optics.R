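# Electron-optical constants, analytic formulas, probe formation,
# propagation.

test_that("relativistic wavelength matches independent hand calculations", {
  # frozen values computed once from the relativistic de Broglie formula
  # with CODATA 2018 constants (h = 6.62607015e-34, m0 = 9.1093837015e-31,
  # e = 1.602176634e-19, c = 2.99792458e8)
  expect_equal(electron_wavelength(60), 0.00486606, tolerance = 1e-5)
  expect_equal(electron_wavelength(300), 0.00196875, tolerance = 1e-5)
  # nonrelativistic limit at 100 V: 1.226/sqrt(V) nm, correction < 1e-4
  expect_equal(electron_wavelength(0.1), 1.22643 / sqrt(100),
               tolerance = 1e-4)
  expect_error(electron_wavelength(0), class = "ptychotomo_invalid_parameter")
  expect_error(electron_wavelength(-60), class = "ptychotomo_invalid_parameter")
})

test_that("wavelength is strictly decreasing in voltage", {
  v <- seq(1, 1000, length.out = 200)
  lam <- vapply(v, electron_wavelength, numeric(1))
  expect_true(all(diff(lam) < 0))
})

test_that("transfer-band resolution lambda/(alpha+beta)", {
  expect_equal(signif(ptycho_resolution(optics_config(60, 1.5)), 3), 1.62)
  # beta defaulted to alpha equals lambda/(2 alpha) identically
  o <- optics_config(60, 1.5)
  expect_identical(ptycho_resolution(o),
                   electron_wavelength(60) / (2 * 1.5e-3))
  expect_equal(ptycho_resolution(optics_config(300, 1.5)),
               electron_wavelength(300) / 3e-3)
  # asymmetric collection
  expect_equal(ptycho_resolution(optics_config(60, 1.5, beta_mrad = 4.5)),
               electron_wavelength(60) / 6e-3)
  expect_error(optics_config(60, 0), class = "ptychotomo_invalid_parameter")
  expect_error(optics_config(60, 1.5, beta_mrad = 1),
               class = "ptychotomo_invalid_parameter")
})

test_that("CTF first zero", {
  expect_equal(signif(ctf_first_zero(optics_config(60, 1.5,
                                                   defocus_nm = -2800)), 3),
               3.69)
  expect_equal(signif(ctf_first_zero(optics_config(60, 1.5,
                                                   defocus_nm = -8900)), 3),
               6.58)
  # closed-form agreement sqrt(lambda |df|)
  for (df in c(-100, -2800, 5000)) {
    expect_equal(ctf_first_zero(optics_config(60, 1.5, defocus_nm = df)),
                 sqrt(electron_wavelength(60) * abs(df)), tolerance = 1e-9)
  }
  # small-defocus limit
  expect_lt(ctf_first_zero(optics_config(60, 1.5, defocus_nm = -1e-3)), 0.1)
  expect_error(ctf_first_zero(optics_config(60, 1.5, defocus_nm = 0)),
               class = "ptychotomo_no_zero_crossing")
  # with Cs > 0 the numeric root satisfies sin(chi) ~ 0
  o <- optics_config(300, 1.5, defocus_nm = -50, cs_mm = 1)
  d <- ctf_first_zero(o)
  lam <- electron_wavelength(300)
  chi <- pi * lam * (-50) * (1 / d)^2 + pi / 2 * 1e6 * lam^3 * (1 / d)^4
  expect_lt(abs(sin(chi)), 1e-6)
})

test_that("geometric probe diameter", {
  expect_equal(probe_geometric_diameter(optics_config(60, 1.5,
                                                      defocus_nm = -40e3)),
               120)
  expect_equal(probe_geometric_diameter(optics_config(60, 1.5,
                                                      defocus_nm = -34e3)),
               102)
  expect_equal(probe_geometric_diameter(optics_config(60, 1.5)), 0)
})

test_that("overlap ratio and dose accounting are exact", {
  ov <- overlap_ratio(20, 120)
  expect_identical(as.numeric(ov) * 6, 5)      # 1 - 20/120 = 5/6 exactly
  expect_equal(round(100 * as.numeric(ov)), 83)
  expect_identical(as.numeric(overlap_ratio(120, 120)), 0)
  expect_identical(as.numeric(overlap_ratio(0, 120)), 1)
  expect_gt(attr(ov, "areal"), as.numeric(ov) - 0.1)  # areal reported too
  expect_error(overlap_ratio(20, 0), class = "ptychotomo_invalid_parameter")

  expect_identical(total_dose(88, 23), 2024)
  expect_identical(total_dose(26, 23), 598)
  expect_identical(total_dose(45, 23), 1035)
  expect_identical(electrons_per_pattern(88, 20), 88 * 200^2)
  expect_equal(electrons_per_pattern(88, 20), 3.52e6)
  expect_error(electrons_per_pattern(88, 0),
               class = "ptychotomo_invalid_parameter")
})

test_that("probe formation: normalization, Airy width, defocused diameter", {
  # normalization
  g <- grid2d(128, 1)
  p <- make_probe(g, optics_config(60, 1.5, defocus_nm = -5000))
  expect_equal(total_intensity(p), 1, tolerance = 1e-10)

  # in-focus probe on a fine grid is an Airy pattern: first radial minimum
  # at 0.61 lambda/alpha within 5%
  gf <- grid2d(256, 0.25)
  pf <- make_probe(gf, optics_config(60, 1.5))
  inten <- Mod(pf$values)^2
  r <- ptychotomo:::centre_radius_grid(gf$shape) * gf$pixel_size
  rb <- floor(r / 0.25)
  prof <- vapply(split(as.vector(inten), as.vector(rb)), mean, numeric(1))
  radii <- as.numeric(names(prof)) * 0.25
  dips <- which(diff(sign(diff(prof))) > 0) + 1
  first_min <- radii[dips[1]]
  expect_equal(first_min, 0.61 * electron_wavelength(60) / 1.5e-3,
               tolerance = 0.05)

  # paper-geometry probe: 90% encircled energy within 10% of 120 nm
  g2 <- grid2d(256, 1.5)
  p2 <- make_probe(g2, optics_config(60, 1.5, defocus_nm = -40e3))
  expect_equal(encircled_energy_diameter(p2, 0.9), 120, tolerance = 0.1)

  # sampling and field-of-view guards
  expect_error(make_probe(grid2d(64, 2), optics_config(300, 20)),
               class = "ptychotomo_sampling_error")
  expect_error(make_probe(grid2d(32, 1), optics_config(60, 1.5,
                                                       defocus_nm = -40e3)),
               class = "ptychotomo_field_of_view_error")
})

test_that("propagation is unitary, invertible, and refocuses the probe", {
  lam <- electron_wavelength(60)
  g <- grid2d(128, 1.5)
  p <- make_probe(g, optics_config(60, 1.5, defocus_nm = -20e3))
  expect_equal(propagate(p, 0, lam)$values, p$values, tolerance = 1e-12)
  back <- propagate(propagate(p, 3000, lam), -3000, lam)
  expect_equal(back$values, p$values, tolerance = 1e-10)
  for (dz in c(-5e3, 1e3, 4e4)) {
    expect_equal(total_intensity(propagate(p, dz, lam)), 1,
                 tolerance = 1e-10)
  }
  # exact kernel agrees with paraxial at these small angles
  ex <- propagate(p, 3000, lam, exact = TRUE)
  pa <- propagate(p, 3000, lam)
  expect_lt(max(Mod(ex$values - pa$values)), 1e-4)

  # sign-convention pin: propagating by -defocus undoes make_probe's
  # defocus term exactly, recovering the in-focus probe
  p0 <- make_probe(g, optics_config(60, 1.5))
  refoc <- propagate(p, 20e3, lam)
  expect_lt(max(Mod(refoc$values - p0$values)), 1e-10)
  # refocused 90% encircled diameter shrinks to the diffraction-limited
  # width (within 2x of the in-focus probe on the same grid)
  expect_lt(encircled_energy_diameter(refoc, 0.9),
            2 * encircled_energy_diameter(p0, 0.9))
})
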