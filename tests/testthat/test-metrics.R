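# Normalization, histogram analysis, contrast ratio, splitting, FRC/FSC.

test_that("normalization maps background to 0 and gold mean to 1", {
  set.seed(4)
  img <- matrix(stats::rnorm(64^2, 0.3, 0.02), 64)
  img[1:16, 1:16] <- stats::rnorm(256, 2.5, 0.05)
  gold <- as.vector(outer(1:16, (1:16 - 1) * 64, `+`))
  bkgd <- as.vector(outer(33:48, (33:48 - 1) * 64, `+`))
  nrm <- normalise(img, bkgd, gold)
  expect_equal(mean(nrm[gold]), 1, tolerance = 1e-9)
  h <- graphics::hist(nrm[bkgd], breaks = 64, plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)]), 2 * diff(h$breaks[1:2]))
  # affine invariance
  nrm2 <- normalise(3.7 * img - 1.2, bkgd, gold)
  expect_equal(as.numeric(nrm2), as.numeric(nrm), tolerance = 1e-9)
  expect_error(normalise(img, bkgd, bkgd), class = "ptychotomo_invalid_parameter")
  expect_error(normalise(matrix(1, 8, 8), 1:4, 5:8),
               class = "ptychotomo_degenerate_normalization")
})

test_that("histogram peaks recover generating means (two-Gaussian oracle)", {
  set.seed(12)
  n <- 1e5
  x <- c(stats::rnorm(n, 0, 0.03), stats::rnorm(n, 0.2, 0.03),
         stats::rnorm(n, 1, 0.05))
  regs <- list(bkgd = 1:n, dna = n + (1:n), gold = 2 * n + (1:n))
  hs <- histogram_peaks(x, regs)
  expect_lt(abs(hs$p_bkgd - 0), 0.01)
  expect_lt(abs(hs$p_dna - 0.2), 0.01)
  expect_equal(hs$p_gold, mean(x[regs$gold]))
  expect_equal(hs$r_dna_gold,
               (hs$p_dna - hs$p_bkgd) / (hs$p_gold - hs$p_bkgd))

  # peaks invariant under voxel order shuffling
  perm <- sample(3 * n)
  inv <- integer(3 * n); inv[perm] <- seq_len(3 * n)
  hs2 <- histogram_peaks(x[perm], lapply(regs, function(r) inv[r]))
  expect_equal(hs2$p_bkgd, hs$p_bkgd)
  expect_equal(hs2$p_dna, hs$p_dna)

  # delta-like region pins its peak to within one bin
  xd <- c(rep(0.37, 100), rep(0, 100), rep(1, 100))
  hd <- histogram_peaks(xd, list(bkgd = 101:200, dna = 1:100,
                                 gold = 201:300))
  expect_lt(abs(hd$p_dna - 0.37), hd$bin_width)

  expect_error(histogram_peaks(x, list(bkgd = 1:10, dna = 1:20,
                                       gold = 1:10)),
               class = "ptychotomo_invalid_parameter")
})

test_that("contrast ratio formula and edge cases", {
  expect_equal(contrast_ratio(0.17, 0, 1), 0.17)
  expect_equal(contrast_ratio(0.5, 0.5, 2), 0)
  expect_equal(contrast_ratio(2, 0.5, 2), 1)
  # affine invariance of R under any rescaling of the underlying data
  a <- 2.3; b <- -0.7
  expect_equal(contrast_ratio(a * 0.24 + b, a * 0 + b, a * 1 + b), 0.24,
               tolerance = 1e-12)
  expect_error(contrast_ratio(0.1, 1, 1),
               class = "ptychotomo_degenerate_normalization")
})

test_that("dataset splitting is disjoint, complete and checkerboarded", {
  proj <- matrix(0.1, 96, 96)
  opt <- optics_config(60, 1.5, defocus_nm = -2000)
  # 9 x 10 raster = 90 patterns, the full-dataset geometry
  scan <- scan_pattern(c(9, 10), 3, centre_nm = c(47.5, 47.5))
  stk <- simulate_4dstem(proj, 1, opt, scan, dose_spec(10, 3), 32,
                         noiseless = TRUE)
  halves <- split_dataset(stk)
  na <- dim(halves$a$intensities)[1]
  nb <- dim(halves$b$intensities)[1]
  expect_equal(na, 45)
  expect_equal(nb, 45)
  pos <- rbind(halves$a$positions_px, halves$b$positions_px)
  expect_equal(nrow(unique(pos)), 90)
  # checkerboard: no two same-half positions adjacent in the raster
  sel <- ((rep(1:9, each = 10) + rep(1:10, times = 9)) %% 2) == 0
  m <- matrix(sel, 9, 10, byrow = TRUE)
  expect_true(all(m[, -1] != m[, -10]))
  expect_true(all(m[-1, ] != m[-9, ]))
  # dose metadata halves, deterministic
  expect_equal(halves$a$dose$dose_per_area, stk$dose$dose_per_area / 2)
  expect_identical(split_dataset(stk)$a$positions_px, halves$a$positions_px)
})

test_that("FRC: identity, symmetry, null statistics, known cutoff", {
  set.seed(3)
  x <- matrix(stats::rnorm(256^2), 256)
  self <- frc(x, x)
  expect_lt(max(abs(self$correlation - 1)), 1e-12)
  expect_true(all(diff(self$frequencies_nm) > 0))

  y <- matrix(stats::rnorm(256^2), 256)
  expect_identical(frc(x, y)$correlation, frc(y, x)$correlation)

  # independent noise: correlations within the 3/sqrt(n) null band
  null <- frc(x, y)
  expect_gte(mean(abs(null$correlation) < 3 / sqrt(null$n_samples)), 0.95)

  # shared band-limited signal + independent noise at SNR 1: half-bit
  # crossing near the signal cutoff
  kc <- 0.25 * 0.5
  ky <- fft_freq(256); keep <- outer(ky^2, ky^2, `+`) <= kc^2
  sig <- Re(stats::fft(stats::fft(matrix(stats::rnorm(256^2), 256)) * keep,
                       inverse = TRUE) / 256^2)
  sig <- sig / stats::sd(sig)
  r <- frc(sig + matrix(stats::rnorm(256^2), 256),
           sig + matrix(stats::rnorm(256^2), 256))
  expect_lt(abs(1 / r$resolution_nm - kc) / kc, 0.15)
  # resolution never finer than two pixels
  expect_gte(r$resolution_nm, 2)
})

test_that("half-bit threshold limit and fixed thresholds", {
  expect_lt(abs(half_bit_threshold(1e8) - 0.1716), 1e-3)
  expect_true(all(diff(half_bit_threshold(10^(1:8))) < 0))
  # fixed-threshold crossings are reported alongside
  set.seed(5)
  kc <- 0.125
  ky <- fft_freq(128); keep <- outer(ky^2, ky^2, `+`) <= kc^2
  sig <- Re(stats::fft(stats::fft(matrix(stats::rnorm(128^2), 128)) * keep,
                       inverse = TRUE) / 128^2)
  sig <- sig / stats::sd(sig)
  r <- frc(sig + matrix(stats::rnorm(128^2), 128),
           sig + matrix(stats::rnorm(128^2), 128))
  expect_false(is.na(r$resolution_fixed_143_nm))
  expect_false(is.na(r$resolution_fixed_500_nm))
  # the 0.5 threshold is stricter than 0.143
  expect_gte(r$resolution_fixed_500_nm, r$resolution_fixed_143_nm)
})

test_that("R is affine-invariant through the full histogram pipeline", {
  set.seed(9)
  n <- 2000
  x <- c(stats::rnorm(n, 0.02, 0.01), stats::rnorm(n, 0.1, 0.02),
         stats::rnorm(n, 0.5, 0.03))
  regs <- list(bkgd = 1:n, dna = n + (1:n), gold = 2 * n + (1:n))
  r_raw <- histogram_peaks(normalise(x, regs$bkgd, regs$gold),
                           regs)$r_dna_gold
  x2 <- 5 * x + 3
  r_scaled <- histogram_peaks(normalise(x2, regs$bkgd, regs$gold),
                              regs)$r_dna_gold
  expect_equal(r_scaled, r_raw, tolerance = 1e-9)
})

test_that("dose series report", {
  set.seed(2)
  img <- matrix(stats::rnorm(48^2, 0.1, 0.02), 48)
  img[1:12, 1:12] <- stats::rnorm(144, 1, 0.05)
  regs <- list(gold = as.vector(outer(1:12, (1:12 - 1) * 48, `+`)),
               bkgd = as.vector(outer(25:36, (25:36 - 1) * 48, `+`)),
               dna = as.vector(outer(25:36, (37:48 - 1) * 48, `+`)))
  entries <- list(list(dose = 88, image = img),
                  list(dose = 45, image = img),
                  list(dose = 26, image = img))
  tab <- dose_series_report(entries, regs)
  expect_equal(nrow(tab), 3)
  expect_length(unique(tab$r), 1)   # identical images give identical R
  csv <- tempfile(fileext = ".csv")
  dose_series_report(entries, regs, csv_path = csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(utils::read.csv(csv)), 3)
  expect_error(dose_series_report(entries[1], regs),
               class = "ptychotomo_invalid_parameter")
})
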