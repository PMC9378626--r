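# Quantification: normalization against gold / background signals,
# histogram peak analysis and the contrast ratio
# R = (P_DNA - P_bkgd) / (P_gold - P_bkgd), half-dataset splitting, and
# Fourier ring/shell correlation with the half-bit information threshold.

#' Axis-aligned box region of an array
#'
#' @param dims array dimensions (length 2 or 3)
#' @param lo,hi inclusive 1-based corner indices (same length as `dims`)
#' @return integer vector of linear indices
#' @export
box_region <- function(dims, lo, hi) {
  if (length(lo) != length(dims) || length(hi) != length(dims))
    stop_invalid("corner indices must match array dimensionality")
  if (any(lo < 1) || any(hi > dims) || any(hi < lo))
    stop_invalid("box exceeds array bounds")
  rng <- mapply(seq.int, lo, hi, SIMPLIFY = FALSE)
  g <- as.matrix(expand.grid(rng))
  mult <- cumprod(c(1, dims[-length(dims)]))
  as.integer((g - 1) %*% mult + 1)
}

#' Histogram peak of a sample (kernel-smoothed argmax)
#'
#' Peak = bin centre of the argmax of the Gaussian-smoothed histogram;
#' argmax ties break toward the lower intensity.
#'
#' @param x numeric values
#' @param breaks histogram break points
#' @param smooth_bins Gaussian kernel sd in bins
#' @return peak position
#' @noRd
hist_peak <- function(x, breaks, smooth_bins = 3) {
  h <- graphics::hist(pmin(pmax(x, breaks[1]), breaks[length(breaks)]),
                      breaks = breaks, plot = FALSE)
  cnt <- h$counts
  if (smooth_bins > 0) {
    halfw <- ceiling(4 * smooth_bins)
    kern <- stats::dnorm(-halfw:halfw, sd = smooth_bins)
    kern <- kern / sum(kern)
    cnt <- stats::filter(c(rep(0, halfw), cnt, rep(0, halfw)), kern,
                         sides = 2)
    cnt <- as.numeric(cnt)[(halfw + 1):(halfw + length(h$counts))]
  }
  h$mids[which.max(cnt)]   # which.max returns the first (lowest) maximum
}

#' Normalize data against gold and background regions
#'
#' Affine map \eqn{x \mapsto (x - P_{bkgd}) / (P_{gold} - P_{bkgd})} where
#' `P_bkgd` is the histogram peak of the background region and `P_gold` the
#' mean of the gold region: background maps to ~0 and the gold mean to
#' exactly 1.
#'
#' @param data numeric array (image or volume)
#' @param bkgd_region,gold_region linear indices (e.g. from [box_region()])
#'   or logical masks; non-empty and disjoint
#' @param bin_count histogram bins for the background peak
#' @param smooth_bins Gaussian smoothing (bins) for peak finding
#' @return normalized array, with attributes `p_bkgd` and `p_gold`
#' @export
normalise <- function(data, bkgd_region, gold_region, bin_count = 128,
                      smooth_bins = 3) {
  bi <- if (is.logical(bkgd_region)) which(bkgd_region) else bkgd_region
  gi <- if (is.logical(gold_region)) which(gold_region) else gold_region
  if (!length(bi) || !length(gi)) stop_invalid("regions must be non-empty")
  if (length(intersect(bi, gi))) stop_invalid("regions must be disjoint")
  bx <- data[bi]
  breaks <- seq(min(bx), max(bx) + 1e-12 * (1 + abs(max(bx))),
                length.out = bin_count + 1)
  p_bkgd <- hist_peak(bx, breaks, smooth_bins)
  p_gold <- mean(data[gi])
  if (abs(p_gold - p_bkgd) < 1e-12 * max(abs(p_gold), 1))
    stop(errorCondition("gold and background levels coincide",
                        class = c("ptychotomo_degenerate_normalization",
                                  "error")))
  out <- (data - p_bkgd) / (p_gold - p_bkgd)
  attr(out, "p_bkgd") <- p_bkgd
  attr(out, "p_gold") <- p_gold
  out
}

#' Histogram peak analysis of background / DNA / gold regions
#'
#' The three regions must contain equal numbers of voxels (enforced).
#' Shared bins span `range` (extended to cover the data if needed); peaks
#' are kernel-smoothed argmaxes, except gold which is summarized by its
#' mean.
#'
#' @param data numeric array, normally already normalized
#' @param regions named list with elements `bkgd`, `dna`, `gold`: linear
#'   indices or logical masks of equal size
#' @param bin_count number of bins (default 128)
#' @param smooth_bins Gaussian kernel sd in bins (default 3)
#' @param range histogram range on normalized data (default c(-0.2, 1.2))
#' @return object of class `histogram_stats`: peak positions `p_bkgd`,
#'   `p_dna`, gold mean `p_gold`, contrast ratio `r_dna_gold`, `bin_width`,
#'   `region_voxel_count`, and the per-region histogram `counts`/`mids`
#' @export
histogram_peaks <- function(data, regions, bin_count = 128, smooth_bins = 3,
                            range = c(-0.2, 1.2)) {
  need <- c("bkgd", "dna", "gold")
  if (!all(need %in% names(regions))) stop_invalid("regions must name bkgd, dna, gold")
  idx <- lapply(regions[need], function(r) if (is.logical(r)) which(r) else r)
  sizes <- lengths(idx)
  if (length(unique(sizes)) != 1L)
    stop_invalid(sprintf("regions must have equal voxel counts (got %s)",
                         paste(sizes, collapse = "/")))
  vals <- lapply(idx, function(i) data[i])
  # fixed bin grid: values outside the range are clamped into the edge
  # bins, so the quantization is identical across datasets being compared
  lo <- range[1]; hi <- range[2]
  breaks <- seq(lo, hi + 1e-12 * (1 + abs(hi)), length.out = bin_count + 1)
  p_bkgd <- hist_peak(vals$bkgd, breaks, smooth_bins)
  p_dna <- hist_peak(vals$dna, breaks, smooth_bins)
  p_gold <- mean(vals$gold)
  hists <- lapply(vals, function(v)
    graphics::hist(pmin(pmax(v, lo), breaks[length(breaks)]),
                   breaks = breaks, plot = FALSE)$counts)
  structure(list(p_bkgd = p_bkgd, p_dna = p_dna, p_gold = p_gold,
                 r_dna_gold = contrast_ratio(p_dna, p_bkgd, p_gold),
                 bin_width = diff(breaks[1:2]),
                 region_voxel_count = sizes[[1]],
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = hists),
            class = "histogram_stats")
}

#' @export
print.histogram_stats <- function(x, ...) {
  cat(sprintf(paste0("<histogram_stats> P_bkgd = %.4g, P_DNA = %.4g, ",
                     "P_gold = %.4g  ->  R = %.4g  (%d voxels/region)\n"),
              x$p_bkgd, x$p_dna, x$p_gold, x$r_dna_gold,
              x$region_voxel_count))
  invisible(x)
}

#' Contrast ratio of a weak feature between background and gold levels
#'
#' \eqn{R = (P_{DNA} - P_{bkgd}) / (P_{gold} - P_{bkgd})}: the normalized
#' offset of the DNA histogram peak above the background peak, on a scale
#' where the gold mean is 1. Larger R means higher visibility of the weak
#' feature. Affine-invariant in the underlying data.
#'
#' @param p_dna,p_bkgd,p_gold peak/mean positions
#' @return R
#' @examples
#' contrast_ratio(0.17, 0, 1)   # 0.17
#' @export
contrast_ratio <- function(p_dna, p_bkgd, p_gold) {
  if (abs(p_gold - p_bkgd) < 1e-300)
    stop(errorCondition("zero denominator in contrast ratio",
                        class = c("ptychotomo_degenerate_normalization",
                                  "error")))
  (p_dna - p_bkgd) / (p_gold - p_bkgd)
}

#' Split a 4D dataset into two independent halves
#'
#' Partitions scan positions into two disjoint sets covering the full scan.
#' The default checkerboard scheme alternates on the raster so no two
#' same-half positions are raster-adjacent; each half carries halved dose
#' metadata.
#'
#' @param stack a `diffraction_stack`
#' @param scheme "checkerboard" or "random" (seeded)
#' @param seed seed for the random scheme
#' @return list of two `diffraction_stack` halves `a` and `b`
#' @export
split_dataset <- function(stack, scheme = c("checkerboard", "random"),
                          seed = 1) {
  scheme <- match.arg(scheme)
  n_pos <- dim(stack$intensities)[1]
  if (n_pos < 2) stop_invalid("need >= 2 patterns to split")
  sel <- if (scheme == "checkerboard") {
    sh <- stack$scan$shape
    rc <- cbind(rep(seq_len(sh[1]), each = sh[2]),
                rep(seq_len(sh[2]), times = sh[1]))
    ((rc[, 1] + rc[, 2]) %% 2) == 0
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    s <- sample(rep(c(TRUE, FALSE), length.out = n_pos))
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    s
  }
  take <- function(keep) {
    h <- stack
    h$intensities <- stack$intensities[keep, , , drop = FALSE]
    h$positions_px <- stack$positions_px[keep, , drop = FALSE]
    h$scan$positions_nm <- stack$scan$positions_nm[keep, , drop = FALSE]
    h$dose <- dose_spec(stack$dose$dose_per_area / 2, stack$dose$step_nm)
    # per-pattern budget is unchanged; halving applies to the area dose
    h$dose$electrons_per_pattern <- stack$dose$electrons_per_pattern
    h
  }
  list(a = take(sel), b = take(!sel))
}

#' Half-bit information threshold for FRC/FSC
#'
#' \eqn{T(n) = (0.2071 + 1.9102/\sqrt{n}) / (1.2071 + 0.9102/\sqrt{n})} with
#' n the number of independent Fourier samples in the shell (asymmetry
#' factor 1). Tends to 0.2071/1.2071 = 0.1716 for large n.
#'
#' @param n_eff Fourier samples per shell
#' @return threshold values
#' @export
half_bit_threshold <- function(n_eff) {
  (0.2071 + 1.9102 / sqrt(n_eff)) / (1.2071 + 0.9102 / sqrt(n_eff))
}

#' Soft-edged circular/spherical mask (cosine taper over the outer 10%)
#' @noRd
soft_mask <- function(dims) {
  if (length(dims) == 2) {
    r <- centre_radius_grid(dims)
  } else {
    cz <- floor(dims / 2) + 1
    axs <- lapply(1:3, function(i) (seq_len(dims[i]) - cz[i])^2)
    r <- sqrt(outer(outer(axs[[1]], axs[[2]], `+`), axs[[3]], `+`))
  }
  rmax <- min(dims) / 2 - 1
  r0 <- 0.9 * rmax
  m <- array(1, dim = dims)
  edge <- r > r0
  m[edge] <- 0.5 * (1 + cos(pi * pmin((r[edge] - r0) / (rmax - r0), 1)))
  m
}

#' Fourier ring / shell correlation between two reconstructions
#'
#' Both inputs are mean-subtracted and multiplied by a soft-edged circular
#' (spherical) mask, Fourier transformed, and correlated per frequency
#' ring/shell: \eqn{C(r) = |\sum F_a \bar F_b| / \sqrt{\sum|F_a|^2 \sum|F_b|^2}}.
#' The resolution is 1/frequency of the first downward crossing of C below
#' the half-bit threshold, located by linear interpolation between
#' bracketing shells; crossings of the fixed 0.143 and 0.5 thresholds are
#' also reported.
#'
#' @param a,b equally sized matrices (FRC) or 3D arrays / `volume3d` (FSC)
#' @param pixel_size_nm sampling (nm); taken from `a` if it is a `volume3d`
#' @param shell_width_px ring/shell width in Fourier pixels
#' @return object of class `frc_result`: `frequencies_nm` (1/nm shell
#'   centres), `correlation`, `threshold` (half-bit), `n_samples`,
#'   `resolution_nm` (NA if no crossing before Nyquist), and
#'   `resolution_fixed_143_nm` / `resolution_fixed_500_nm`
#' @export
frc <- function(a, b, pixel_size_nm = 1, shell_width_px = 1) {
  if (inherits(a, "volume3d")) { pixel_size_nm <- a$voxel_size_nm; a <- a$values }
  if (inherits(b, "volume3d")) b <- b$values
  if (!all(dim(a) == dim(b))) stop_invalid("inputs must share a grid")
  dims <- dim(a)
  m <- soft_mask(dims)
  Fa <- fftshift(stats::fft((a - mean(a)) * m))
  Fb <- fftshift(stats::fft((b - mean(b)) * m))
  if (length(dims) == 2) {
    r <- centre_radius_grid(dims)
  } else {
    cz <- floor(dims / 2) + 1
    axs <- lapply(1:3, function(i) (seq_len(dims[i]) - cz[i])^2)
    r <- sqrt(outer(outer(axs[[1]], axs[[2]], `+`), axs[[3]], `+`))
  }
  n_shell <- floor(min(dims) / 2 / shell_width_px)
  shell <- pmin(floor(r / shell_width_px) + 1, n_shell + 1)
  cross <- Fa * Conj(Fb)
  num <- rowsum(cbind(Re(as.vector(cross)), Im(as.vector(cross)),
                      Mod(as.vector(Fa))^2, Mod(as.vector(Fb))^2,
                      rep(1, length(Fa))), as.vector(shell))
  sh_id <- as.integer(rownames(num))
  keep <- sh_id >= 1 & sh_id <= n_shell
  num <- num[keep, , drop = FALSE]
  corr <- unname(sqrt(num[, 1]^2 + num[, 2]^2) /
                   sqrt(pmax(num[, 3] * num[, 4], 1e-300)))
  n_eff <- unname(num[, 5])
  freq <- (sh_id[keep] - 0.5) * shell_width_px /
    (min(dims) * pixel_size_nm)
  thr <- half_bit_threshold(n_eff)
  res_at <- function(threshold) {
    d <- corr - threshold
    ix <- which(d[-1] < 0 & d[-length(d)] >= 0)
    ix <- ix[ix > 1]   # ignore the DC shell
    if (!length(ix)) return(NA_real_)
    i <- ix[1]
    f <- freq[i] + (freq[i + 1] - freq[i]) * d[i] / (d[i] - d[i + 1])
    1 / f
  }
  structure(list(frequencies_nm = freq, correlation = corr,
                 threshold = thr, n_samples = n_eff,
                 resolution_nm = res_at(thr),
                 resolution_fixed_143_nm = res_at(rep(0.143, length(corr))),
                 resolution_fixed_500_nm = res_at(rep(0.5, length(corr))),
                 pixel_size_nm = pixel_size_nm),
            class = "frc_result")
}

#' @rdname frc
#' @export
fsc <- frc

#' @export
print.frc_result <- function(x, ...) {
  res <- if (is.na(x$resolution_nm)) "not reached before Nyquist"
         else sprintf("%.3g nm", x$resolution_nm)
  cat(sprintf("<frc_result> %d shells, half-bit resolution: %s\n",
              length(x$correlation), res))
  invisible(x)
}

#' Pairwise peak separation of region histograms
#'
#' Quantifies how well the background / DNA / gold populations form
#' distinct modes: for each pair of regions, each region's smoothed
#' histogram is evaluated at its own peak and at the other region's peak
#' position; the separation is the smaller of the two peak-to-crossing
#' ratios. Values well above 1 mean each population's density has clearly
#' dropped by the time the other population peaks.
#'
#' @param stats a `histogram_stats` from [histogram_peaks()]
#' @param smooth_bins Gaussian kernel sd in bins
#' @return named vector of separation ratios (`bkgd_dna`, `dna_gold`,
#'   `bkgd_gold`)
#' @export
peak_separation <- function(stats, smooth_bins = 3) {
  kern <- stats::dnorm(-(4 * smooth_bins):(4 * smooth_bins), sd = smooth_bins)
  kern <- kern / sum(kern)
  p <- length(kern) %/% 2
  sm <- lapply(stats$counts, function(cnt)
    as.numeric(stats::filter(c(rep(0, p), cnt, rep(0, p)), kern,
                             sides = 2))[(p + 1):(p + length(cnt))])
  pk <- vapply(sm, which.max, integer(1))
  pairsep <- function(a, b) {
    ra <- sm[[a]][pk[a]] / max(sm[[a]][pk[b]], 1e-9)
    rb <- sm[[b]][pk[b]] / max(sm[[b]][pk[a]], 1e-9)
    min(ra, rb)
  }
  c(bkgd_dna = pairsep("bkgd", "dna"),
    dna_gold = pairsep("dna", "gold"),
    bkgd_gold = pairsep("bkgd", "gold"))
}

#' Dose-series contrast and resolution report
#'
#' For each dose entry, normalizes the image, extracts histogram peaks and
#' the contrast ratio R, and (when half-dataset pairs are supplied) the FRC
#' resolution of the two halves.
#'
#' @param entries list of entries, each a list with `dose` (e-/A^2), `image`
#'   (matrix), and optionally `half_a`/`half_b` (matrices for FRC)
#' @param regions named list (`bkgd`, `dna`, `gold`) of equally sized
#'   regions valid for every image
#' @param pixel_size_nm image sampling for the FRC frequency axis
#' @param csv_path optional path to write the table as CSV
#' @return data.frame with columns dose, r, frc_resolution_nm
#' @export
dose_series_report <- function(entries, regions, pixel_size_nm = 1,
                               csv_path = NULL) {
  if (length(entries) < 2) stop_invalid("need >= 2 dose entries")
  rows <- lapply(entries, function(e) {
    img <- normalise(e$image, regions$bkgd, regions$gold)
    hs <- histogram_peaks(img, regions)
    fres <- NA_real_
    if (!is.null(e$half_a) && !is.null(e$half_b)) {
      fres <- frc(e$half_a, e$half_b, pixel_size_nm)$resolution_nm
    }
    data.frame(dose = e$dose, r = hs$r_dna_gold, frc_resolution_nm = fres)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}
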