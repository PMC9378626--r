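# ePIE phase retrieval and post-acquisition defocus refinement.

test_that("object initialization: unit amplitude, band-limited phase, seeded", {
  g <- grid2d(128, 1)
  o <- init_object(g, band = 0.035, seed = 3)
  expect_lt(max(abs(Mod(o) - 1)), 1e-12)   # amplitude 1 by construction
  ph <- Arg(o)
  P <- Mod(stats::fft(ph))^2
  k2 <- ptychotomo:::k2_grid(g)
  out_band <- sum(P[k2 > 0.035^2]) / sum(P)
  expect_lt(out_band, 1e-10)
  expect_identical(o, init_object(g, band = 0.035, seed = 3))
  expect_false(identical(o, init_object(g, band = 0.035, seed = 4)))
  expect_error(init_object(g, band = 1), class = "ptychotomo_invalid_parameter")
})

test_that("flat object is a fixed point on vacuum data with the true probe", {
  opt <- optics_config(60, 1.5, defocus_nm = -2000)
  scan <- scan_pattern(c(3, 3), 4, centre_nm = c(31.5, 31.5))
  vac <- simulate_4dstem(matrix(0, 64, 64), 1, opt, scan, dose_spec(88, 4),
                         32, noiseless = TRUE)
  res <- epie_reconstruct(vac, epie_config(n_iterations = 10,
                                           probe_update_start = Inf,
                                           init_phase_sd = 0, seed = 1))
  expect_lt(stats::sd(reference_phase(res)[res$coverage > 0]), 1e-3)
  expect_lt(res$error_trace[1], 1e-20)
})

test_that("noiseless reconstruction converges and is seed-consistent", {
  inst <- epie_instance()
  r1 <- epie_reconstruct(inst$stack, epie_config(n_iterations = 60, seed = 2))
  # strong error reduction
  expect_lt(r1$error_trace[60], 0.01 * r1$error_trace[1])
  # reconstructions from different random initializations agree after
  # removing the global phase offset (multiplicative ambiguity)
  r2 <- epie_reconstruct(inst$stack, epie_config(n_iterations = 60, seed = 77))
  sel <- r1$coverage >= 2
  expect_gt(stats::cor(reference_phase(r1)[sel], reference_phase(r2)[sel]),
            0.98)
  # and both correlate with the generating phantom
  expect_gt(phase_recovery_cor(r1, inst$projection), 0.98)
})

test_that("error trace is non-increasing under stochastic ordering", {
  inst <- epie_instance()
  res <- epie_reconstruct(inst$stack,
                          epie_config(n_iterations = 60, seed = 2,
                                      probe_update_start = Inf))
  last <- res$error_trace[11:60]
  expect_true(all(diff(last) / last[-length(last)] <= 0.01))
})

test_that("degenerate data and config validation", {
  inst <- epie_instance()
  dead <- inst$stack
  dead$intensities[] <- 0
  expect_error(epie_reconstruct(dead), class = "ptychotomo_degenerate_data")
  expect_error(epie_config(n_iterations = 0),
               class = "ptychotomo_invalid_parameter")
  expect_error(epie_config(alpha_object = 0),
               class = "ptychotomo_invalid_parameter")
  expect_error(epie_config(alpha_probe = 1.5),
               class = "ptychotomo_invalid_parameter")
})

test_that("post-focus recovers the acquisition defocus (zero-error case)", {
  opt <- optics_config(60, 1.5, defocus_nm = -8000)   # 24 nm probe
  proj <- matrix(0, 128, 128)
  proj[33:96, 33:96] <- project_phantom(build_phantom(n = 64, seed = 5))
  scan <- scan_pattern(c(3, 3), 8, centre_nm = c(63.5, 63.5))
  stk <- simulate_4dstem(proj, 1, opt, scan, dose_spec(88, 8), 64, seed = 2)
  pf <- post_focus(stk, centre_nm = -8000, half_range_nm = 2000,
                   n_coarse = 5, config = epie_config(n_iterations = 15,
                                                      seed = 3),
                   search_iterations = 6)
  expect_lt(abs(pf$defocus_nm - (-8000)), 500)
  expect_s3_class(pf$result, "ptycho_result")
  # sharpness peaks at the true defocus over the coarse grid
  coarse <- pf$search[1:5, ]
  expect_equal(coarse$defocus_nm[which.max(coarse$score)], -8000)
})

test_that("a flat sharpness profile raises an inconclusive-focus error", {
  opt <- optics_config(60, 1.5, defocus_nm = -2000)
  scan <- scan_pattern(c(2, 2), 4, centre_nm = c(31.5, 31.5))
  vac <- simulate_4dstem(matrix(0, 64, 64), 1, opt, scan, dose_spec(88, 4),
                         32, noiseless = TRUE)
  expect_error(post_focus(vac, centre_nm = -2000, half_range_nm = 1000,
                          n_coarse = 3,
                          config = epie_config(n_iterations = 5, seed = 1,
                                               init_phase_sd = 0),
                          search_iterations = 3),
               class = "ptychotomo_inconclusive_focus")
})
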