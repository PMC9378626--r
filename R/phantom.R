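# Ground-truth 3D phase phantoms: gold nanoparticles (optionally with a DNA
# shell), random-walk DNA strands, and a textured carbon support slab, on a
# cubic voxel grid; plus projection to 2D phase maps at arbitrary
# orientations.
#
# Geometry conventions:
#  * density[i, j, k]: i = y (row), j = x (col), k = z (beam axis).
#  * Physical coordinates at voxel centres; rotation centre = grid centre.
#  * orientation(tilt1, tilt2, inplane): the sample is rotated intrinsically,
#    first about the y (row) axis by tilt1, then about the x (col) axis by
#    tilt2, then about the beam (z) axis by inplane; projection integrates
#    the rotated density along z.

.material_levels <- c("vacuum", "carbon", "dna", "gold")

#' Specimen orientation
#'
#' @param tilt1_deg rotation about the y (row) axis, degrees
#' @param tilt2_deg rotation about the x (col) axis, degrees (the second,
#'   perpendicular tilt axis of a dual-axis series)
#' @param inplane_deg rotation about the beam axis, degrees
#' @param shift_nm optional in-plane (dy, dx) shift in nm
#' @return object of class `orientation`
#' @export
orientation <- function(tilt1_deg = 0, tilt2_deg = 0, inplane_deg = 0,
                        shift_nm = c(0, 0)) {
  for (v in c(tilt1_deg, tilt2_deg, inplane_deg, shift_nm))
    if (!is.finite(v)) stop_invalid("orientation angles/shifts must be finite")
  structure(list(tilt1_deg = tilt1_deg, tilt2_deg = tilt2_deg,
                 inplane_deg = inplane_deg, shift_nm = shift_nm),
            class = "orientation")
}

#' Rotation matrix of an orientation (sample frame -> lab frame)
#' @noRd
orientation_matrix <- function(o) {
  t1 <- o$tilt1_deg * pi / 180
  t2 <- o$tilt2_deg * pi / 180
  t3 <- o$inplane_deg * pi / 180
  # coordinates ordered (y, x, z)
  Ry <- matrix(c(1, 0, 0,                       # rotation about y (row) axis
                 0, cos(t1), -sin(t1),
                 0, sin(t1), cos(t1)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(cos(t2), 0, sin(t2),           # rotation about x (col) axis
                 0, 1, 0,
                 -sin(t2), 0, cos(t2)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(t3), -sin(t3), 0,          # rotation about beam axis
                 sin(t3), cos(t3), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Rx %*% Ry
}

#' Build a DNA-origami / gold-nanoparticle phase phantom
#'
#' Places gold spheres (default: two, separated along z by `gold_gap_nm`
#' centre to centre), optional DNA shells around each sphere, random-walk
#' DNA strands of tube radius `strand_radius_nm`, and a carbon slab with
#' mild smoothed-noise texture at the bottom of the volume. Densities are in
#' radians of phase shift per nm of thickness; defaults give a gold : DNA
#' voxel ratio of 1 : 0.2 so that volumes normalized to the gold signal put
#' DNA near 0.2, the regime of interest for weak-phase biomolecules beside
#' strong scatterers.
#'
#' @param n voxels per edge (cubic grid), >= 32
#' @param voxel_size_nm voxel edge (nm)
#' @param gold_radius_nm gold sphere radius (nm), >= 2 voxels
#' @param gold_gap_nm centre-to-centre z separation of the two gold spheres
#'   (nm); default 5.5
#' @param n_gold number of gold spheres stacked along z at the volume centre
#' @param shell_nm DNA shell thickness around each gold sphere (nm; 0 = none)
#' @param n_strands number of random-walk DNA strands
#' @param strand_radius_nm strand tube radius (nm), >= 1 voxel
#' @param carbon_nm carbon slab thickness (nm; 0 = none)
#' @param densities named list of phase densities (rad/nm) for gold, dna,
#'   carbon; must satisfy gold > dna > carbon >= 0
#' @param carbon_texture_sd relative sd of the smoothed carbon texture
#' @param seed RNG seed (strand walks and carbon texture)
#' @return object of class `phantom3d` with fields `density` (3D array,
#'   rad/nm), `labels` (integer array: 0 vacuum, 1 carbon, 2 dna, 3 gold),
#'   `voxel_size_nm`, and the generating parameters
#' @export
build_phantom <- function(n = 64, voxel_size_nm = 1,
                          gold_radius_nm = 2.5, gold_gap_nm = 5.5,
                          n_gold = 2, shell_nm = 1.5,
                          n_strands = 3, strand_radius_nm = 1.3,
                          carbon_nm = 4,
                          densities = list(gold = 0.25, dna = 0.05,
                                           carbon = 0.01),
                          carbon_texture_sd = 0.25, seed = 1) {
  n <- as.integer(n)
  if (n < 32L) stop_invalid("'n' must be >= 32")
  if (gold_radius_nm < 2 * voxel_size_nm && n_gold > 0)
    stop_invalid("'gold_radius_nm' must be >= 2 voxels")
  if (n_strands > 0 && strand_radius_nm < voxel_size_nm)
    stop_invalid("'strand_radius_nm' must be >= 1 voxel")
  if (!(densities$gold > densities$dna && densities$dna > densities$carbon &&
        densities$carbon >= 0))
    stop_invalid("densities must satisfy gold > dna > carbon >= 0")

  ctr <- (n - 1) / 2 * voxel_size_nm          # physical centre, nm
  ax <- (seq_len(n) - 1) * voxel_size_nm       # voxel-centre coordinates
  labels <- array(0L, dim = c(n, n, n))

  # carbon slab occupies the lowest z layers
  if (carbon_nm > 0) {
    nz <- min(n, max(1L, round(carbon_nm / voxel_size_nm)))
    labels[, , seq_len(nz)] <- 1L
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  mark_ball <- function(labels, centre, radius, value) {
    # bounding box then exact distance test (vectorized per z-slab)
    rng <- lapply(centre, function(c0) {
      lo <- max(1L, floor((c0 - radius) / voxel_size_nm) + 1L)
      hi <- min(n, ceiling((c0 + radius) / voxel_size_nm) + 1L)
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) stop(errorCondition(
      "phantom geometry exceeds grid bounds",
      class = c("ptychotomo_placement_error", "error")))
    dy2 <- (ax[rng[[1]]] - centre[1])^2
    dx2 <- (ax[rng[[2]]] - centre[2])^2
    dz2 <- (ax[rng[[3]]] - centre[3])^2
    d2 <- outer(outer(dy2, dx2, `+`), dz2, `+`)
    sub <- labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[d2 <= radius^2 & sub < value] <- value
    labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
    labels
  }

  # gold spheres (with optional DNA shell painted first at larger radius)
  if (n_gold > 0) {
    z0 <- ctr - (n_gold - 1) / 2 * gold_gap_nm
    for (g in seq_len(n_gold)) {
      cen <- c(ctr, ctr, z0 + (g - 1) * gold_gap_nm)
      if (any(cen - gold_radius_nm < 0) || any(cen + gold_radius_nm > ax[n]))
        stop(errorCondition("gold sphere exceeds grid bounds",
                            class = c("ptychotomo_placement_error", "error")))
      if (shell_nm > 0)
        labels <- mark_ball(labels, cen, gold_radius_nm + shell_nm, 2L)
      labels <- mark_ball(labels, cen, gold_radius_nm, 3L)
    }
  }

  # random-walk strands: persistent direction with jitter, reflected at walls
  if (n_strands > 0) {
    margin <- strand_radius_nm + voxel_size_nm
    zlow <- if (carbon_nm > 0) carbon_nm + margin else margin
    for (s in seq_len(n_strands)) {
      pos <- c(stats::runif(2, margin, ax[n] - margin),
               stats::runif(1, zlow, min(zlow + 8, ax[n] - margin)))
      dirv <- stats::rnorm(3); dirv[3] <- dirv[3] * 0.2
      dirv <- dirv / sqrt(sum(dirv^2))
      n_steps <- round(1.2 * n)
      step <- voxel_size_nm
      for (t in seq_len(n_steps)) {
        labels <- mark_ball(labels, pos, strand_radius_nm, 2L)
        dirv <- dirv + stats::rnorm(3, sd = 0.25); dirv[3] <- dirv[3] * 0.5
        dirv <- dirv / sqrt(sum(dirv^2))
        pos2 <- pos + dirv * step
        for (d in 1:3) {
          lo <- if (d == 3) zlow else margin
          if (pos2[d] < lo || pos2[d] > ax[n] - margin) {
            dirv[d] <- -dirv[d]; pos2[d] <- pos[d] + dirv[d] * step
          }
        }
        pos <- pmin(pmax(pos2, margin), ax[n] - margin)
      }
    }
  }

  density <- array(0, dim = dim(labels))
  density[labels == 1L] <- densities$carbon
  density[labels == 2L] <- densities$dna
  density[labels == 3L] <- densities$gold
  if (carbon_nm > 0 && carbon_texture_sd > 0) {
    # band-limited noise texture over the slab: keeps background histograms
    # from being a delta function
    tex <- array(stats::rnorm(n^3), dim = c(n, n, n))
    TX <- fftn(tex)
    kc <- 0.25 / voxel_size_nm
    kax <- fft_freq(n, voxel_size_nm)
    K2 <- outer(outer(kax^2, kax^2, `+`), kax^2, `+`)
    tex <- Re(ifftn(TX * exp(-K2 / (2 * kc^2))))
    tex <- tex / stats::sd(tex)
    cmask <- labels == 1L
    density[cmask] <- pmax(0, densities$carbon *
                              (1 + carbon_texture_sd * tex[cmask]))
  }

  structure(list(density = density, labels = labels,
                 voxel_size_nm = voxel_size_nm,
                 densities = densities, seed = seed,
                 params = list(n = n, gold_radius_nm = gold_radius_nm,
                               gold_gap_nm = gold_gap_nm, n_gold = n_gold,
                               shell_nm = shell_nm, n_strands = n_strands,
                               strand_radius_nm = strand_radius_nm,
                               carbon_nm = carbon_nm)),
            class = "phantom3d")
}

#' @export
print.phantom3d <- function(x, ...) {
  tab <- table(factor(.material_levels[x$labels + 1L], levels = .material_levels))
  cat(sprintf("<phantom3d> %d^3 voxels, %.3g nm/voxel\n", dim(x$density)[1],
              x$voxel_size_nm))
  print(tab)
  invisible(x)
}

#' Trilinear sample of a 3D array at fractional 0-based voxel coordinates
#' (out-of-bounds -> 0); coords is a 3 x N matrix ordered (y, x, z)
#' @noRd
trilinear_sample <- function(vol, coords) {
  d <- dim(vol)
  f0 <- floor(coords)
  w <- coords - f0
  out <- numeric(ncol(coords))
  for (dy in 0:1) for (dx in 0:1) for (dz in 0:1) {
    iy <- f0[1, ] + dy; ix <- f0[2, ] + dx; iz <- f0[3, ] + dz
    wt <- (if (dy) w[1, ] else 1 - w[1, ]) *
          (if (dx) w[2, ] else 1 - w[2, ]) *
          (if (dz) w[3, ] else 1 - w[3, ])
    ok <- iy >= 0 & iy < d[1] & ix >= 0 & ix < d[2] & iz >= 0 & iz < d[3] & wt > 0
    if (any(ok)) {
      lin <- iy[ok] + d[1] * (ix[ok] + d[2] * iz[ok]) + 1
      out[ok] <- out[ok] + wt[ok] * vol[lin]
    }
  }
  out
}

#' Rotate a 3D array about its centre (trilinear resampling)
#'
#' @param vol 3D array
#' @param orient an [orientation()]
#' @return rotated array of the same shape; regions rotated in from outside
#'   the original field are 0
#' @export
rotate_volume <- function(vol, orient) {
  d <- dim(vol)
  R <- orientation_matrix(orient)
  ctr <- (d - 1) / 2
  g <- as.matrix(expand.grid(y = seq_len(d[1]) - 1, x = seq_len(d[2]) - 1,
                             z = seq_len(d[3]) - 1))
  src <- t(R) %*% (t(g) - ctr) + ctr   # R^-1 = R^T maps output -> source
  array(trilinear_sample(vol, src), dim = d)
}

#' Project a phantom (or any volume) to a 2D phase image
#'
#' Rotates the density by the orientation and integrates along the beam (z)
#' axis, multiplying by the voxel size: a pure-phase projection in radians.
#'
#' @param phantom a `phantom3d`, or a plain 3D array (then give
#'   `voxel_size_nm`)
#' @param orient an [orientation()]
#' @param voxel_size_nm voxel size when `phantom` is a plain array
#' @return matrix of projected phase (radians)
#' @export
project_phantom <- function(phantom, orient = orientation(),
                            voxel_size_nm = NULL) {
  if (inherits(phantom, "phantom3d")) {
    vol <- phantom$density; vs <- phantom$voxel_size_nm
  } else {
    vol <- phantom
    vs <- if (is.null(voxel_size_nm)) 1 else voxel_size_nm
  }
  rot <- if (all(c(orient$tilt1_deg, orient$tilt2_deg, orient$inplane_deg) == 0))
    vol else rotate_volume(vol, orient)
  img <- apply(rot, c(1, 2), sum) * vs
  if (any(orient$shift_nm != 0)) {
    img <- fourier_shift(img, orient$shift_nm / vs)
  }
  img
}

#' Material regions in a projection's frame
#'
#' Projects the phantom's label field along the beam at an orientation and
#' returns equally sized pixel-index regions for the carbon background, DNA
#' strands and gold particles of the projected image. DNA and gold regions
#' keep only "core" pixels whose projected material thickness reaches
#' `min_thickness_nm` (the analogue of drawing boxes on clearly visible
#' features); the background region excludes any pixel touched by DNA or
#' gold.
#'
#' @param phantom a `phantom3d`
#' @param orient an [orientation()]
#' @param n_pixels pixels per region (capped at the scarcest material)
#' @param min_thickness_nm minimum projected thickness for dna/gold cores
#' @param seed seed for the equal-count subsampling
#' @param dims optional output frame c(rows, cols) with the projection
#'   centred in it (defaults to the projection size)
#' @return named list of linear pixel indices (`bkgd`, `dna`, `gold`)
#' @export
projected_regions <- function(phantom, orient = orientation(),
                              n_pixels = 400, min_thickness_nm = 2,
                              seed = 1, dims = NULL) {
  vs <- phantom$voxel_size_nm
  untilted <- all(c(orient$tilt1_deg, orient$tilt2_deg,
                    orient$inplane_deg) == 0)
  thick <- function(l) {
    m <- phantom$labels == l
    storage.mode(m) <- "double"
    if (!untilted) m <- rotate_volume(m, orient)
    apply(m, c(1, 2), sum) * vs
  }
  tc <- thick(1L); td <- thick(2L); tg <- thick(3L)
  n <- dim(tc)[1]
  if (is.null(dims)) dims <- c(n, n)
  off <- (dims - n) %/% 2
  place <- function(m) {
    out <- matrix(FALSE, dims[1], dims[2])
    out[off[1] + seq_len(n), off[2] + seq_len(n)] <- m
    which(out)
  }
  pools <- list(bkgd = place(tc > 0 & td == 0 & tg == 0),
                dna = place(td >= min_thickness_nm & tg == 0),
                gold = place(tg >= min_thickness_nm))
  if (any(lengths(pools) == 0))
    stop_invalid("a material region is empty at this orientation/threshold")
  k <- min(n_pixels, min(lengths(pools)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  lapply(pools, function(p) sort(sample(p, k)))
}

#' Dual-axis tilt scheme
#'
#' Generates angles from `lo` to `hi` in steps of `increment_deg` for each
#' axis, always including the end point; axis-1 angles are taken about the
#' first tilt axis, axis-2 angles about the perpendicular axis. The default
#' ranges and 10 degree increment give 23 orientations.
#'
#' @param axis1_range c(lo, hi) degrees for the first axis
#' @param axis2_range c(lo, hi) degrees for the second axis; NULL for a
#'   single-axis scheme
#' @param increment_deg tilt increment (degrees), > 0
#' @return list of [orientation()]
#' @export
make_tilt_scheme <- function(axis1_range = c(-49.99, 53.94),
                             axis2_range = c(-53.42, 46.40),
                             increment_deg = 10) {
  if (increment_deg <= 0) stop_invalid("'increment_deg' must be > 0")
  expand <- function(rng) {
    if (any(!is.finite(rng)) || rng[2] < rng[1])
      stop_invalid("tilt range must be finite with hi >= lo")
    a <- seq(rng[1], rng[2], by = increment_deg)
    if (a[length(a)] < rng[2]) a <- c(a, rng[2])
    a
  }
  out <- lapply(expand(axis1_range), function(a) orientation(tilt1_deg = a))
  if (!is.null(axis2_range))
    out <- c(out, lapply(expand(axis2_range),
                         function(a) orientation(tilt2_deg = a)))
  if (!length(out)) stop_invalid("empty tilt scheme")
  out
}
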