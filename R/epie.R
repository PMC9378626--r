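# Iterative ptychographic phase retrieval: the extended ptychographic
# iterative engine (ePIE) with the standard object/probe update rules, plus
# post-acquisition defocus refinement by re-running short reconstructions
# over a defocus search grid.
#
# Update rules, per position j (P probe, O object window, a/b update
# strengths):
#   psi  = P * O
#   Psi  = F psi ; Psi' = sqrt(I_j) * Psi/|Psi|   (measured modulus; pixels
#          with zero counts are valid measurements of modulus 0, not masked)
#   dpsi = F^-1 Psi' - psi
#   O <- O + a * Conj(P)/max|P|^2 * dpsi
#   P <- P + b * Conj(O_old)/max|O_old|^2 * dpsi   (from a start iteration)
# Data misfit per iteration: E = sum_j sum_k (sqrt I - |Psi|)^2 / sum I.

#' ePIE configuration
#'
#' @param n_iterations iteration count (default 100)
#' @param alpha_object object update strength in (0, 1] (default 0.5)
#' @param alpha_probe probe update strength in (0, 1] (default 0.5)
#' @param probe_update_start first iteration at which the probe is updated
#'   (default 5); `Inf` disables probe refinement
#' @param seed RNG seed (object initialization and position shuffling)
#' @param init_phase_band maximum spatial frequency of the random initial
#'   phase (1/nm, default 0.035)
#' @param init_phase_sd standard deviation of the random initial phase (rad)
#' @param fixed_order keep raster position order every iteration (for exact
#'   regression tests); default FALSE = reshuffle each iteration, seeded
#' @return object of class `epie_config`
#' @export
epie_config <- function(n_iterations = 100, alpha_object = 0.5,
                        alpha_probe = 0.5, probe_update_start = 5,
                        seed = 1, init_phase_band = 0.035,
                        init_phase_sd = 0.1, fixed_order = FALSE) {
  if (n_iterations < 1) stop_invalid("'n_iterations' must be >= 1")
  if (alpha_object <= 0 || alpha_object > 1)
    stop_invalid("'alpha_object' must be in (0, 1]")
  if (alpha_probe <= 0 || alpha_probe > 1)
    stop_invalid("'alpha_probe' must be in (0, 1]")
  if (init_phase_band < 0) stop_invalid("'init_phase_band' must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 alpha_object = alpha_object, alpha_probe = alpha_probe,
                 probe_update_start = probe_update_start, seed = seed,
                 init_phase_band = init_phase_band,
                 init_phase_sd = init_phase_sd, fixed_order = fixed_order),
            class = "epie_config")
}

#' Initial object guess: unit amplitude, band-limited random phase
#'
#' Amplitude is exactly 1 everywhere; the phase is a random field whose
#' spectrum is confined to frequencies in [0, `band`], scaled to standard
#' deviation `phase_sd`.
#'
#' @param grid a [grid2d()]
#' @param band maximum phase spatial frequency (1/nm); must be below Nyquist
#' @param seed RNG seed
#' @param phase_sd phase standard deviation (rad)
#' @return complex matrix
#' @export
init_object <- function(grid, band = 0.035, seed = 1, phase_sd = 0.1) {
  if (band >= 1 / (2 * grid$pixel_size))
    stop_invalid("'band' must be below the grid Nyquist frequency")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  noise <- matrix(stats::rnorm(prod(grid$shape)), grid$shape[1], grid$shape[2])
  if (band > 0) {
    ky <- fft_freq(grid$shape[1], grid$pixel_size)
    kx <- fft_freq(grid$shape[2], grid$pixel_size)
    keep <- outer(ky^2, kx^2, `+`) <= band^2
    ph <- Re(ifft2(fft2(noise) * keep))
  } else ph <- matrix(0, grid$shape[1], grid$shape[2])
  s <- stats::sd(ph)
  if (s > 0) ph <- ph * (phase_sd / s)
  exp(1i * ph)
}

#' ePIE reconstruction from a 4D diffraction stack
#'
#' @param stack a `diffraction_stack` from [simulate_4dstem()] (or loaded
#'   from disk)
#' @param config an [epie_config()]
#' @param init_probe optional initial probe ([complex_wave()] on the window
#'   grid); by default formed from the stack's optics metadata (convergence
#'   angle and defocus), optionally overridden by `defocus_nm`
#' @param defocus_nm probe defocus override (nm) for the initial probe
#' @param canvas_px object canvas size; default = tight bounding box of all
#'   probe windows
#' @return object of class `ptycho_result`: `object` (complex matrix over
#'   the canvas), `phase` (its argument), `probe`, `error_trace`
#'   (per-iteration misfit), `coverage` (probes covering each canvas pixel),
#'   `canvas_origin_px` (0-based projection pixel of canvas pixel [1,1]),
#'   `config`, `defocus_used_nm`
#' @export
epie_reconstruct <- function(stack, config = epie_config(),
                             init_probe = NULL, defocus_nm = NULL,
                             canvas_px = NULL) {
  I <- stack$intensities
  if (all(I == 0))
    stop(errorCondition("all-zero diffraction stack",
                        class = c("ptychotomo_degenerate_data", "error")))
  n_pos <- dim(I)[1]
  w <- stack$window_px
  half <- w %/% 2
  opt <- stack$optics
  if (!is.null(defocus_nm)) {
    opt$defocus_nm <- defocus_nm
  }
  if (is.null(init_probe)) {
    init_probe <- make_probe(grid2d(w, stack$pixel_size_nm), opt)
  }
  # scale probe to the per-pattern electron budget so |F psi|^2 ~ counts
  ne <- stack$dose$electrons_per_pattern
  P <- init_probe$values * sqrt(max(ne, 1))

  # canvas: bounding box over probe windows
  tl <- cbind(stack$positions_px[, 1] - half, stack$positions_px[, 2] - half)
  origin <- c(min(tl[, 1]), min(tl[, 2]))
  if (is.null(canvas_px)) {
    canvas_px <- c(max(tl[, 1]) - origin[1] + w, max(tl[, 2]) - origin[2] + w)
  }
  ogrid <- grid2d(canvas_px, stack$pixel_size_nm)
  O <- init_object(ogrid, config$init_phase_band, config$seed,
                   config$init_phase_sd)

  # coverage counts probes whose illuminated disc reaches each pixel; the
  # numerical window is much wider than the disc, so footprint = pixels
  # with >= 10% of the peak intensity, which tracks the geometric disc of a
  # defocused probe
  coverage <- matrix(0L, canvas_px[1], canvas_px[2])
  pmask <- Mod(init_probe$values)^2 >= 0.1 * max(Mod(init_probe$values)^2)
  win_rows <- win_cols <- vector("list", n_pos)
  sqrtI <- vector("list", n_pos)
  for (j in seq_len(n_pos)) {
    win_rows[[j]] <- (tl[j, 1] - origin[1] + 1):(tl[j, 1] - origin[1] + w)
    win_cols[[j]] <- (tl[j, 2] - origin[2] + 1):(tl[j, 2] - origin[2] + w)
    coverage[win_rows[[j]], win_cols[[j]]] <-
      coverage[win_rows[[j]], win_cols[[j]]] + pmask
    sqrtI[[j]] <- sqrt(ifftshift(I[j, , ]))   # back to DFT pixel order
  }
  sumI <- sum(I)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(derive_seed(config$seed, 17L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))

  err <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    order_j <- if (config$fixed_order) seq_len(n_pos) else sample.int(n_pos)
    e_it <- 0
    for (j in order_j) {
      ys <- win_rows[[j]]; xs <- win_cols[[j]]
      Ow <- O[ys, xs]
      psi <- P * Ow
      # unitary FFT convention: detector counts integrate |F psi|^2 with
      # total intensity preserved (matches the simulator's scaling)
      Psi <- fft2(psi) / w
      mPsi <- Mod(Psi)
      e_it <- e_it + sum((sqrtI[[j]] - mPsi)^2)
      Psi2 <- sqrtI[[j]] * Psi / pmax(mPsi, 1e-12)
      dpsi <- ifft2(Psi2) * w - psi
      O[ys, xs] <- Ow + config$alpha_object * Conj(P) / max(Mod(P)^2) * dpsi
      if (it >= config$probe_update_start) {
        P <- P + config$alpha_probe * Conj(Ow) / max(Mod(Ow)^2) * dpsi
      }
      if (anyNA(O[ys, xs]) || anyNA(P))
        stop(errorCondition(sprintf("NaN in ePIE update at iteration %d", it),
                            class = c("ptychotomo_numerical_failure", "error")))
    }
    err[it] <- e_it / sumI
  }

  structure(list(object = O, phase = Arg(O),
                 probe = complex_wave(P / sqrt(sum(Mod(P)^2)),
                                      grid2d(w, stack$pixel_size_nm)),
                 error_trace = err, coverage = coverage,
                 canvas_origin_px = origin, config = config,
                 pixel_size_nm = stack$pixel_size_nm,
                 defocus_used_nm = opt$defocus_nm),
            class = "ptycho_result")
}

#' @export
print.ptycho_result <- function(x, ...) {
  cat(sprintf(paste0("<ptycho_result> object %d x %d px (%.3g nm/px), ",
                     "%d iterations, final misfit %.4g, defocus %.4g nm\n"),
              nrow(x$object), ncol(x$object), x$pixel_size_nm,
              length(x$error_trace), x$error_trace[length(x$error_trace)],
              x$defocus_used_nm))
  invisible(x)
}

#' Remove the global phase offset of a reconstruction
#'
#' ePIE determines the object up to a global phase constant. Sets the median
#' phase of `region` (default: every pixel covered by at least one probe) to
#' zero.
#'
#' @param result a `ptycho_result` (or a phase matrix with `region` given)
#' @param region logical matrix naming the background/reference pixels
#' @return phase matrix (radians) with the offset removed
#' @export
reference_phase <- function(result, region = NULL) {
  ph <- if (inherits(result, "ptycho_result")) result$phase else result
  if (is.null(region)) {
    region <- if (inherits(result, "ptycho_result")) result$coverage > 0
              else matrix(TRUE, nrow(ph), ncol(ph))
  }
  ph - stats::median(ph[region])
}

#' Sharpness of a phase image (focus metric)
#'
#' Default metric: variance of the 4-neighbour Laplacian of the phase over
#' `region` (robust at low dose). Alternative `"gradient_entropy"`: negative
#' Shannon entropy of the gradient-magnitude histogram.
#'
#' @param phase phase matrix (radians)
#' @param region logical matrix of pixels to score (default all)
#' @param metric "laplacian_variance" or "gradient_entropy"
#' @return scalar score; larger = sharper
#' @export
phase_sharpness <- function(phase, region = NULL,
                            metric = c("laplacian_variance",
                                       "gradient_entropy")) {
  metric <- match.arg(metric)
  n <- nrow(phase); m <- ncol(phase)
  if (is.null(region)) region <- matrix(TRUE, n, m)
  inner <- 2:(n - 1)
  innc <- 2:(m - 1)
  if (metric == "laplacian_variance") {
    lap <- phase[inner - 1, innc] + phase[inner + 1, innc] +
      phase[inner, innc - 1] + phase[inner, innc + 1] -
      4 * phase[inner, innc]
    stats::var(lap[region[inner, innc]])
  } else {
    gy <- phase[inner + 1, innc] - phase[inner - 1, innc]
    gx <- phase[inner, innc + 1] - phase[inner, innc - 1]
    g <- sqrt(gy^2 + gx^2)[region[inner, innc]]
    h <- graphics::hist(g, breaks = 64, plot = FALSE)$counts
    p <- h[h > 0] / sum(h)
    sum(p * log(p))   # negative entropy
  }
}

#' Post-acquisition defocus refinement
#'
#' Re-runs short ePIE reconstructions with the probe formed at each defocus
#' of a coarse search grid, scores each candidate, refines the best bracket
#' by golden-section search to `tol_nm`, then reconstructs fully at the
#' refined defocus. The probe update is disabled during the search (a
#' refining probe would absorb the defocus error and flatten the score).
#'
#' The default score is the negative final data misfit of the short
#' reconstruction: with the probe pinned at a wrong defocus the
#' measured-modulus constraint cannot be satisfied, so the misfit is
#' unimodal with its minimum at the acquisition defocus. Image-sharpness
#' scores (`"laplacian_variance"`, `"gradient_entropy"`, see
#' [phase_sharpness()]) are available but reward divergence artifacts of
#' badly mis-focused short reconstructions and can therefore be
#' non-monotone far from focus.
#'
#' @param stack a `diffraction_stack`
#' @param centre_nm centre of the defocus search (nm)
#' @param half_range_nm half width of the coarse search (nm)
#' @param n_coarse number of coarse grid points (>= 3)
#' @param config an [epie_config()] for the final reconstruction
#' @param search_iterations ePIE iterations per search evaluation
#' @param tol_nm golden-section tolerance (nm; default 500 = 0.5 um)
#' @param metric "misfit" (default), "laplacian_variance" or
#'   "gradient_entropy"
#' @return list: `defocus_nm` (refined), `result` (full `ptycho_result` at
#'   the refined defocus), `search` (data.frame of evaluated defoci/scores;
#'   larger score = better focus)
#' @export
post_focus <- function(stack, centre_nm, half_range_nm, n_coarse = 5,
                       config = epie_config(), search_iterations = 8,
                       tol_nm = 500, metric = "misfit") {
  if (half_range_nm <= 0) stop_invalid("'half_range_nm' must be > 0")
  short_cfg <- config
  short_cfg$n_iterations <- as.integer(search_iterations)
  short_cfg$probe_update_start <- Inf
  evals <- data.frame(defocus_nm = numeric(0), score = numeric(0))
  score_at <- function(df) {
    res <- epie_reconstruct(stack, short_cfg, defocus_nm = df)
    s <- if (metric == "misfit") {
      -res$error_trace[length(res$error_trace)]
    } else {
      phase_sharpness(reference_phase(res), res$coverage > 0, metric)
    }
    evals <<- rbind(evals, data.frame(defocus_nm = df, score = s))
    s
  }
  grid <- seq(centre_nm - half_range_nm, centre_nm + half_range_nm,
              length.out = n_coarse)
  scores <- vapply(grid, score_at, numeric(1))
  if (max(scores) - min(scores) < 1e-6 * max(abs(scores), 1e-12))
    stop(errorCondition("sharpness profile is flat: focus search inconclusive",
                        class = c("ptychotomo_inconclusive_focus", "error")))
  b <- which.max(scores)
  lo <- grid[max(1, b - 1)]; hi <- grid[min(n_coarse, b + 1)]
  # golden-section maximization on [lo, hi]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- score_at(x1); f2 <- score_at(x2)
  while (hi - lo > tol_nm) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- score_at(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- score_at(x1)
    }
  }
  best <- (lo + hi) / 2
  final <- epie_reconstruct(stack, config, defocus_nm = best)
  list(defocus_nm = best, result = final, search = evals)
}
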