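# End-to-end pipeline: phantom -> per-tilt 4D simulation -> ePIE (optional
# post-focus) -> alignment -> Fourier iterative tomography -> normalization,
# histogram contrast and half-dataset FSC. Deterministic: every randomized
# stage draws its seed from the master seed via derive_seed().

#' Desk-scale pipeline configuration
#'
#' Defaults are sized to complete in minutes on one CPU while keeping the
#' acquisition logic of a real dual-axis ptychographic tilt series: a
#' defocused probe with ~73% linear overlap, per-area dose of 88 e-/A^2,
#' and Fourier iterative tomography with positivity.
#'
#' @param phantom named list of [build_phantom()] arguments
#' @param optics named list of [optics_config()] arguments; the defocus sets
#'   the simulation probe
#' @param scan_shape raster shape c(rows, cols)
#' @param step_nm scan step (nm)
#' @param dose_per_area dose per tilt (e-/A^2)
#' @param window_px probe/detector window (pixels)
#' @param tilt1_deg,tilt2_deg tilt angles about the two perpendicular axes
#'   (concatenated dual-axis scheme)
#' @param epie named list of [epie_config()] arguments (seed is derived)
#' @param postfocus NULL to use the nominal defocus, or a named list of
#'   [post_focus()] arguments (centre_nm, half_range_nm, n_coarse, ...)
#' @param genfire named list of [genfire_reconstruct()] arguments
#' @param halves_genfire_iterations iterations for the two half-data volumes
#' @param region_voxels voxels sampled per material region for histograms
#' @param master_seed master RNG seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(phantom = list(n = 64, voxel_size_nm = 1),
                            optics = list(voltage_kv = 60, alpha_mrad = 1.5,
                                          defocus_nm = -20000 / 3),
                            scan_shape = c(8, 8), step_nm = 6,
                            dose_per_area = 88, window_px = 32,
                            tilt1_deg = seq(-60, 60, by = 30),
                            tilt2_deg = c(-45, -15, 15, 45),
                            epie = list(n_iterations = 25),
                            postfocus = NULL,
                            genfire = list(n_iterations = 40),
                            halves_genfire_iterations = 25,
                            region_voxels = 400,
                            master_seed = 1) {
  structure(list(phantom = phantom, optics = optics,
                 scan_shape = scan_shape, step_nm = step_nm,
                 dose_per_area = dose_per_area, window_px = window_px,
                 tilt1_deg = tilt1_deg, tilt2_deg = tilt2_deg,
                 epie = epie, postfocus = postfocus, genfire = genfire,
                 halves_genfire_iterations = halves_genfire_iterations,
                 region_voxels = region_voxels, master_seed = master_seed),
            class = "pipeline_config")
}

#' Sample equally sized material regions from a phantom's label field
#'
#' Draws `n_voxels` voxel indices per material (carbon background, DNA,
#' gold), seeded, for histogram/contrast analysis of a reconstructed volume
#' on the same grid.
#'
#' @param phantom a `phantom3d`
#' @param n_voxels voxels per region (capped at the scarcest material)
#' @param seed RNG seed
#' @return named list of index vectors (`bkgd`, `dna`, `gold`)
#' @export
label_regions <- function(phantom, n_voxels = 400, seed = 1) {
  pools <- list(bkgd = which(phantom$labels == 1L),
                dna = which(phantom$labels == 2L),
                gold = which(phantom$labels == 3L))
  if (any(lengths(pools) == 0))
    stop_invalid("phantom lacks one of the carbon/dna/gold materials")
  n <- min(n_voxels, min(lengths(pools)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  lapply(pools, function(p) sort(sample(p, n)))
}

#' Embed a reconstructed phase map into the projection frame
#'
#' Places the referenced (background-zeroed) phase onto the full projection
#' canvas at the reconstruction's origin; pixels never covered by a probe
#' are set to 0.
#'
#' @param result a `ptycho_result`
#' @param dims projection dimensions c(rows, cols)
#' @param min_coverage minimum probe coverage for a pixel to be kept
#' @return phase matrix of size `dims`
#' @export
embed_phase <- function(result, dims, min_coverage = 1) {
  ph <- reference_phase(result, result$coverage >= min_coverage)
  ph[result$coverage < min_coverage] <- 0
  out <- matrix(0, dims[1], dims[2])
  o <- result$canvas_origin_px
  out[o[1] + seq_len(nrow(ph)), o[2] + seq_len(ncol(ph))] <- ph
  out
}

#' Run the full synthetic ptychographic-tomography pipeline
#'
#' Stages: build phantom; project at each tilt; simulate the 4D dataset;
#' reconstruct each tilt by ePIE (optionally with post-acquisition defocus
#' refinement); align the phase tilt series; reconstruct the volume;
#' normalize against label-derived gold/background regions and compute
#' histogram contrast; split every tilt dataset in half, rebuild both half
#' volumes and measure the FSC. Returns a machine-readable report.
#'
#' @param config a [pipeline_config()]
#' @param outdir optional output directory for MRC/CSV/JSON artifacts
#' @param verbose print stage progress
#' @return report list (also written to `outdir/report.json` when `outdir`
#'   is given)
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = FALSE) {
  t_all <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- list(phantom = derive_seed(config$master_seed, 1),
                simulate = derive_seed(config$master_seed, 2),
                epie = derive_seed(config$master_seed, 3),
                regions = derive_seed(config$master_seed, 4))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e)
      stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c("ptychotomo_stage_error", "error"))))
    timings[[name]] <<- round(proc.time()[3] - t0, 3)
    say("stage %-10s %8.2f s", name, timings[[name]])
    r
  }

  phantom <- stage("phantom", do.call(build_phantom,
                                      c(config$phantom,
                                        list(seed = seeds$phantom))))
  n <- dim(phantom$density)[1]
  optics <- do.call(optics_config, config$optics)
  orients <- c(lapply(config$tilt1_deg, function(a) orientation(tilt1_deg = a)),
               lapply(config$tilt2_deg, function(a) orientation(tilt2_deg = a)))
  n_tilt <- length(orients)
  # vacuum margin so edge scan windows stay inside the field
  pad <- config$window_px %/% 2
  np <- n + 2L * pad
  vs <- phantom$voxel_size_nm
  scan <- scan_pattern(config$scan_shape, config$step_nm,
                       centre_nm = rep((np - 1) / 2 * vs, 2))
  dose <- dose_spec(config$dose_per_area, config$step_nm)

  projections <- stage("project", lapply(orients, function(o) {
    p <- matrix(0, np, np)
    p[pad + seq_len(n), pad + seq_len(n)] <- project_phantom(phantom, o)
    p
  }))

  stacks <- stage("simulate", lapply(seq_len(n_tilt), function(i)
    simulate_4dstem(projections[[i]], vs, optics, scan,
                    dose, config$window_px,
                    seed = derive_seed(seeds$simulate, i))))

  run_epie <- function(stk, i) {
    cfg <- do.call(epie_config, c(config$epie,
                                  list(seed = derive_seed(seeds$epie, i))))
    if (is.null(config$postfocus)) {
      list(res = epie_reconstruct(stk, cfg), defocus = optics$defocus_nm)
    } else {
      pf <- do.call(post_focus, c(list(stack = stk), config$postfocus,
                                  list(config = cfg)))
      list(res = pf$result, defocus = pf$defocus_nm)
    }
  }
  recons <- stage("epie", lapply(seq_len(n_tilt), function(i)
    run_epie(stacks[[i]], i)))
  phases <- lapply(recons, function(r)
    embed_phase(r$res, c(np, np))[pad + seq_len(n), pad + seq_len(n)])
  defoci <- vapply(recons, `[[`, numeric(1), "defocus")

  series <- tilt_series(phases, orients, phantom$voxel_size_nm, defoci)
  series <- stage("align", align_projections(series))
  volume <- stage("genfire", do.call(genfire_reconstruct,
                                     c(list(series = series),
                                       config$genfire)))

  regions <- label_regions(phantom, config$region_voxels, seeds$regions)
  norm_vol <- stage("normalise", normalise(volume$values, regions$bkgd,
                                           regions$gold))
  hstats <- stage("histogram", histogram_peaks(norm_vol, regions))

  half_fsc <- stage("fsc", {
    build_half <- function(which_half) {
      ph <- lapply(seq_len(n_tilt), function(i) {
        h <- split_dataset(stacks[[i]])[[which_half]]
        cfg <- do.call(epie_config,
                       c(config$epie,
                         list(seed = derive_seed(seeds$epie, 1000 + i))))
        embed_phase(epie_reconstruct(h, cfg),
                    c(np, np))[pad + seq_len(n), pad + seq_len(n)]
      })
      s <- align_projections(tilt_series(ph, orients, phantom$voxel_size_nm,
                                         defoci))
      gf <- config$genfire
      gf$n_iterations <- config$halves_genfire_iterations
      do.call(genfire_reconstruct, c(list(series = s), gf))
    }
    va <- build_half("a"); vb <- build_half("b")
    fsc(va, vb)
  })

  report <- list(
    package = "ptychotomo",
    master_seed = config$master_seed, seeds = seeds,
    phantom = list(n = n, voxel_size_nm = phantom$voxel_size_nm,
                   materials = as.list(table(phantom$labels))),
    optics = unclass(optics),
    probe_diameter_nm = probe_geometric_diameter(optics),
    overlap_linear = as.numeric(overlap_ratio(config$step_nm,
                                              probe_geometric_diameter(optics))),
    n_tilts = n_tilt,
    dose_per_tilt = config$dose_per_area,
    total_dose = total_dose(config$dose_per_area, n_tilt),
    electrons_per_pattern = dose$electrons_per_pattern,
    defocus_used_nm = defoci,
    epie_final_error = vapply(recons, function(r)
      r$res$error_trace[length(r$res$error_trace)], numeric(1)),
    alignment_shifts_px = unname(series$shifts_px),
    histogram = list(p_bkgd = hstats$p_bkgd, p_dna = hstats$p_dna,
                     p_gold = hstats$p_gold, r_dna_gold = hstats$r_dna_gold),
    fsc_resolution_nm = half_fsc$resolution_nm,
    timings_s = timings,
    elapsed_s = round(proc.time()[3] - t_all, 3))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_mrc(volume$values, file.path(outdir, "volume.mrc"),
              volume$voxel_size_nm)
    write_mrc(aperm(series$projections, c(2, 3, 1)),
              file.path(outdir, "aligned_projections.mrc"),
              series$pixel_size_nm)
    write_angle_table(orients, defoci, file.path(outdir, "angles.txt"),
                      series$shifts_px)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
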