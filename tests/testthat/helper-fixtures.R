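# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# small default phantom used across phantom/tomo tests
fixture_phantom <- function() {
  cache_fixture("phantom64", function() build_phantom(n = 64, seed = 11))
}

# Analytic band-limited two-sphere instance: the truth volume and its
# projections are evaluated from the spheres' closed-form Fourier transform
# (hard sphere FT attenuated by a Gaussian of width sigma), so projections
# are exact and the truth is representable on the grid. Serves as the
# independent oracle for the Fourier-iterative reconstruction.
sphere_instance <- function(N = 32, centres = list(c(15.5, 15.5, 10),
                                                   c(15.5, 15.5, 22)),
                            radius = 4, rho = 0.25, sigma = 1,
                            angles = seq(-69, 69, by = 3)) {
  cpix <- floor(N / 2)
  kc <- (seq_len(N) - 1 - cpix) / N
  sphere_ft <- function(k) {
    out <- ifelse(k < 1e-9, 4 / 3 * pi * radius^3,
                  (sin(2 * pi * k * radius) -
                     2 * pi * k * radius * cos(2 * pi * k * radius)) /
                    (2 * pi^2 * k^3))
    rho * out * exp(-2 * pi^2 * sigma^2 * k^2)
  }
  cifft <- function(x) fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / length(x)
  K3 <- sqrt(outer(outer(kc^2, kc^2, `+`), kc^2, `+`))
  F3 <- array(0 + 0i, dim = c(N, N, N))
  for (cen in centres) {
    ph <- exp(-2i * pi * (outer(outer(kc * (cen[1] - cpix),
                                      kc * (cen[2] - cpix), `+`),
                                kc * (cen[3] - cpix), `+`)))
    F3 <- F3 + sphere_ft(K3) * ph
  }
  truth <- Re(cifft(F3))
  orients <- lapply(angles, function(a) orientation(tilt1_deg = a))
  ky <- rep(kc, times = N); kx <- rep(kc, each = N)
  projections <- lapply(orients, function(o) {
    Rm <- ptychotomo:::orientation_matrix(o)
    q <- t(Rm) %*% rbind(ky, kx, 0)
    F2 <- matrix(0 + 0i, N, N)
    for (cen in centres) {
      kk <- sqrt(colSums(q^2))
      cr <- cen - cpix
      ph <- exp(-2i * pi * (q[1, ] * cr[1] + q[2, ] * cr[2] + q[3, ] * cr[3]))
      F2 <- F2 + matrix(sphere_ft(kk) * ph, N, N)
    }
    Re(cifft(F2))
  })
  list(truth = truth, projections = projections, orients = orients,
       centres = do.call(rbind, centres))
}

# standard small ptychographic instance: 128^2 phase canvas holding a
# 64^3 phantom projection, 5x5 scan at ~73% linear overlap, 15 nm probe
epie_instance <- function(noiseless = TRUE, dose = 88, seed = 1) {
  proj <- cache_fixture("epie_proj", function() {
    p <- matrix(0, 128, 128)
    p[33:96, 33:96] <- project_phantom(build_phantom(n = 64, seed = 5))
    p
  })
  opt <- optics_config(60, 1.5, defocus_nm = -5000)
  scan <- scan_pattern(c(5, 5), step_nm = 4, centre_nm = c(63.5, 63.5))
  stack <- simulate_4dstem(proj, 1, opt, scan, dose_spec(dose, 4),
                           window_px = 64, seed = seed,
                           noiseless = noiseless)
  list(projection = proj, stack = stack, optics = opt)
}

# correlation between a reconstruction's phase and the true projection
# over the region covered by >= min_cov probes
phase_recovery_cor <- function(result, projection, min_cov = 2) {
  o <- result$canvas_origin_px
  tp <- projection[o[1] + seq_len(nrow(result$object)),
                   o[2] + seq_len(ncol(result$object))]
  sel <- result$coverage >= min_cov
  stats::cor(reference_phase(result)[sel], tp[sel])
}
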