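# Phantom construction, projection, tilt schemes.

test_that("empty phantom is vacuum and building is deterministic", {
  p0 <- build_phantom(n = 32, n_gold = 0, n_strands = 0, carbon_nm = 0)
  expect_true(all(p0$density == 0))
  expect_true(all(p0$labels == 0L))

  a <- build_phantom(n = 48, seed = 3)
  b <- build_phantom(n = 48, seed = 3)
  expect_identical(a$density, b$density)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$density, build_phantom(n = 48, seed = 4)$density))
})

test_that("material densities are ordered and consistent with labels", {
  p <- build_phantom(n = 48, seed = 2, carbon_texture_sd = 0)
  expect_true(all(p$density >= 0))
  expect_identical(unique(p$density[p$labels == 3L]), p$densities$gold)
  expect_identical(unique(p$density[p$labels == 2L]), p$densities$dna)
  expect_identical(unique(p$density[p$labels == 1L]), p$densities$carbon)
  expect_gt(min(p$density[p$labels == 3L]), max(p$density[p$labels == 2L]))
  expect_gt(min(p$density[p$labels == 2L]), max(p$density[p$labels == 1L]))
  expect_error(build_phantom(n = 48, densities = list(gold = 0.1, dna = 0.2,
                                                      carbon = 0)),
               class = "ptychotomo_invalid_parameter")
})

test_that("the two gold spheres sit 5.5 nm apart along z in the labels", {
  p <- build_phantom(n = 48, seed = 1, n_strands = 0, carbon_nm = 0,
                     shell_nm = 0)
  d <- dim(p$labels)
  lin <- which(p$labels == 3L) - 1L
  z <- lin %/% (d[1] * d[2])
  lower <- z < stats::median(z)
  gap <- (mean(z[!lower]) - mean(z[lower])) * p$voxel_size_nm
  expect_equal(gap, 5.5, tolerance = 0.15)
  y <- lin %% d[1]; x <- (lin %/% d[1]) %% d[2]
  expect_lt(abs(mean(y[lower]) - mean(y[!lower])), 0.5)
  expect_lt(abs(mean(x[lower]) - mean(x[!lower])), 0.5)
})

test_that("projection of a homogeneous sphere follows the chord length", {
  ax <- 0:63
  d <- sqrt(outer(outer((ax - 31.5)^2, (ax - 31.5)^2, `+`),
                  (ax - 31.5)^2, `+`))
  R <- 10
  v <- 0.3 * pmin(pmax(R - d + 0.5, 0), 1)   # partial-volume sphere
  pr <- project_phantom(v, orientation(), voxel_size_nm = 1)
  r <- sqrt(outer((ax - 31.5)^2, (ax - 31.5)^2, `+`))
  anal <- ifelse(r <= R, 2 * 0.3 * sqrt(pmax(R^2 - r^2, 0)), 0)
  sel <- r <= 0.8 * R   # rim excluded: chord has a sqrt singularity there
  rel_rms <- sqrt(mean((pr[sel] - anal[sel])^2)) / sqrt(mean(anal[sel]^2))
  expect_lt(rel_rms, 0.02)
})

test_that("projection is linear and conserves mass under rotation", {
  p <- fixture_phantom()
  a <- p$density
  b <- array(stats::runif(length(a)), dim = dim(a))
  o <- orientation(17, -23)
  pa <- project_phantom(a, o, 1)
  pb <- project_phantom(b, o, 1)
  pab <- project_phantom(a + b, o, 1)
  expect_equal(pab, pa + pb, tolerance = 1e-9)

  # mass conservation for an object fully inside the field
  ax <- 0:63
  d <- sqrt(outer(outer((ax - 31.5)^2, (ax - 31.5)^2, `+`),
                  (ax - 31.5)^2, `+`))
  v <- 0.3 * pmin(pmax(10 - d + 0.5, 0), 1)
  m0 <- sum(project_phantom(v, orientation(), 1))
  for (o in list(orientation(30), orientation(0, 45), orientation(20, -50, 15))) {
    expect_equal(sum(project_phantom(v, o, 1)), m0, tolerance = 0.01)
  }
})

test_that("crossing strands project to twice a single strand's peak", {
  # two identical perpendicular tubes crossing at the centre
  n <- 48; ax <- 0:(n - 1); rad <- 2
  tube <- function(axis) {
    v <- array(0, dim = c(n, n, n))
    d2 <- outer((ax - 23.5)^2, (ax - 23.5)^2, `+`)  # distance in (other, z)
    m <- d2 <= rad^2
    for (i in seq_len(n)) {
      if (axis == "y") v[i, , ][m] <- 0.05 else v[, i, ][m] <- 0.05
    }
    v
  }
  single <- project_phantom(tube("y"), orientation(), 1)
  crossed <- project_phantom(tube("y") + tube("x"), orientation(), 1)
  expect_equal(max(crossed), 2 * max(single), tolerance = 0.05)
})

test_that("dual-axis tilt scheme reproduces the 23-angle acquisition", {
  sch <- make_tilt_scheme()
  expect_length(sch, 23)
  key <- vapply(sch, function(o) paste(o$tilt1_deg, o$tilt2_deg), "")
  expect_length(unique(key), 23)
  t1 <- vapply(sch, `[[`, numeric(1), "tilt1_deg")
  t2 <- vapply(sch, `[[`, numeric(1), "tilt2_deg")
  expect_equal(range(t1), c(-49.99, 53.94))
  expect_equal(range(t2), c(-53.42, 46.40))
  # each orientation tilts about a single axis
  expect_true(all(t1 == 0 | t2 == 0))

  single <- make_tilt_scheme(c(0, 0), NULL, 10)
  expect_length(single, 1)
  expect_equal(single[[1]]$tilt1_deg, 0)
  expect_error(make_tilt_scheme(c(10, 0), NULL, 10),
               class = "ptychotomo_invalid_parameter")
  expect_error(make_tilt_scheme(c(-50, 50), NULL, 0),
               class = "ptychotomo_invalid_parameter")
})

test_that("projected material regions are equal-sized, disjoint and seeded", {
  p <- fixture_phantom()
  r1 <- projected_regions(p, n_pixels = 100, seed = 3)
  r2 <- projected_regions(p, n_pixels = 100, seed = 3)
  expect_identical(r1, r2)
  expect_length(unique(lengths(r1)), 1L)
  expect_length(Reduce(intersect, r1), 0L)
  # oversized request is capped at the scarcest material
  big <- projected_regions(p, n_pixels = 1e6, seed = 3)
  expect_true(all(lengths(big) == min(lengths(big))))
})
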