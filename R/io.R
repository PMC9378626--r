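# File I/O: MRC2014 volumes/stacks (minimal subset, little-endian float32),
# 4D diffraction stacks as MRC + JSON sidecar, and plain-text angle/defocus
# tables.
#
# The MRC reader/writer is intentionally minimal: mode 2 (float32) data,
# voxel size carried in the cell dimensions, no extended header. The first
# array index is written as the MRC x (fastest) axis.

#' Write a 2D/3D array as an MRC file
#'
#' @param data numeric matrix or 3D array
#' @param path output path
#' @param voxel_size_nm sampling (nm); stored in the MRC cell (angstrom)
#' @return invisibly, `path`
#' @export
write_mrc <- function(data, path, voxel_size_nm = 1) {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(2, 3)))
    stop_invalid("data must be a matrix or 3D array")
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2 = float32
  wi(c(0, 0, 0))              # nxstart
  wi(d)                       # mx my mz
  wf(d * voxel_size_nm * 10)  # cella (angstrom)
  wf(c(90, 90, 90))           # cellb
  wi(c(1, 2, 3))              # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(if (dim(data)[length(dim(data))] > 1 && length(dim(data)) == 3) 1 else 0) # ispg
  wi(0)                       # nsymbt
  wi(rep(0, 25))              # extra (words 26-50)
  wf(c(0, 0, 0))              # origin (words 50-52 per MRC2014)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  wf(stats::sd(data))         # rms
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC file written by [write_mrc()] (mode 2)
#'
#' @param path MRC file
#' @return array with attribute `voxel_size_nm`; matrices are returned as
#'   2D when nz = 1
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2)
    stop(errorCondition(sprintf("unsupported MRC mode %d (field 'mode')", mode),
                        class = c("ptychotomo_parse_error", "error")))
  ri(3)                        # nxstart
  mx <- ri(3)
  cella <- rf(3)
  if (any(d < 1) || any(mx < 1))
    stop(errorCondition("malformed MRC header (field 'nx/ny/nz' or 'mx/my/mz')",
                        class = c("ptychotomo_parse_error", "error")))
  seek(con, 208)
  map <- readBin(con, "raw", 4)
  if (!identical(map, charToRaw("MAP ")))
    stop(errorCondition("malformed MRC header (field 'MAP' signature)",
                        class = c("ptychotomo_parse_error", "error")))
  seek(con, 1024)
  vals <- rf(prod(d))
  if (length(vals) != prod(d))
    stop(errorCondition("truncated MRC data section",
                        class = c("ptychotomo_parse_error", "error")))
  out <- array(vals, dim = d)
  if (d[3] == 1L) out <- out[, , 1]
  attr(out, "voxel_size_nm") <- cella[1] / mx[1] / 10
  out
}

#' Save / load a 4D diffraction stack (MRC + JSON sidecar)
#'
#' `path_prefix.mrc` holds the patterns (one MRC section per scan position);
#' `path_prefix.json` holds scan positions, optics, dose, window geometry
#' and seeds, so the stack reloads without side channels.
#'
#' @param stack a `diffraction_stack`
#' @param path_prefix path without extension
#' @return invisibly, the two file paths
#' @export
write_stack <- function(stack, path_prefix) {
  n_pos <- dim(stack$intensities)[1]
  w <- stack$window_px
  arr <- array(0, dim = c(w, w, n_pos))
  for (j in seq_len(n_pos)) arr[, , j] <- stack$intensities[j, , ]
  write_mrc(arr, paste0(path_prefix, ".mrc"), stack$pixel_size_nm)
  meta <- list(
    positions_px = unname(stack$positions_px),
    scan = list(shape = stack$scan$shape, step_nm = stack$scan$step_nm,
                positions_nm = unname(stack$scan$positions_nm)),
    optics = unclass(stack$optics),
    dose = unclass(stack$dose),
    pixel_size_nm = stack$pixel_size_nm, window_px = stack$window_px,
    bf_radius_px = stack$bf_radius_px, seed = stack$seed,
    noiseless = stack$noiseless,
    cropped_radius_factor = stack$cropped_radius_factor,
    threshold = stack$threshold)
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(path_prefix, ".mrc"), paste0(path_prefix, ".json")))
}

#' @rdname write_stack
#' @param path_prefix path without extension
#' @return for `read_stack`, the reconstructed `diffraction_stack`
#' @export
read_stack <- function(path_prefix) {
  arr <- read_mrc(paste0(path_prefix, ".mrc"))
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  n_pos <- dim(arr)[3]
  inten <- array(0, dim = c(n_pos, dim(arr)[1], dim(arr)[2]))
  for (j in seq_len(n_pos)) inten[j, , ] <- arr[, , j]
  optics <- do.call(optics_config, meta$optics)
  scan <- structure(list(positions_nm = as.matrix(meta$scan$positions_nm),
                         step_nm = meta$scan$step_nm,
                         shape = as.integer(meta$scan$shape)),
                    class = "scan_pattern")
  structure(list(intensities = inten,
                 positions_px = as.matrix(meta$positions_px),
                 scan = scan, optics = optics,
                 dose = dose_spec(meta$dose$dose_per_area, meta$dose$step_nm),
                 pixel_size_nm = meta$pixel_size_nm,
                 window_px = meta$window_px,
                 bf_radius_px = meta$bf_radius_px,
                 probe = make_probe(grid2d(meta$window_px,
                                           meta$pixel_size_nm), optics),
                 seed = meta$seed, noiseless = meta$noiseless,
                 cropped_radius_factor = meta$cropped_radius_factor,
                 threshold = meta$threshold),
            class = "diffraction_stack")
}

#' Write / read a plain-text tilt-angle table
#'
#' Tab-separated columns: tilt1_deg, tilt2_deg, defocus_nm, shift_y_px,
#' shift_x_px; one row per tilt.
#'
#' @param orientations list of [orientation()]
#' @param defocus_nm per-tilt defocus (recycled if length 1)
#' @param shifts_px n x 2 matrix of alignment shifts (optional)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_angle_table <- function(orientations, defocus_nm, path,
                              shifts_px = NULL) {
  n <- length(orientations)
  if (length(defocus_nm) == 1) defocus_nm <- rep(defocus_nm, n)
  if (is.null(shifts_px)) shifts_px <- matrix(0, n, 2)
  df <- data.frame(
    tilt1_deg = vapply(orientations, `[[`, numeric(1), "tilt1_deg"),
    tilt2_deg = vapply(orientations, `[[`, numeric(1), "tilt2_deg"),
    defocus_nm = defocus_nm,
    shift_y_px = shifts_px[, 1], shift_x_px = shifts_px[, 2])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_angle_table
#' @return for `read_angle_table`, a list with `orientations`, `defocus_nm`
#'   and `shifts_px`
#' @export
read_angle_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("tilt1_deg", "tilt2_deg", "defocus_nm", "shift_y_px",
            "shift_x_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(errorCondition(sprintf("angle table missing column(s): %s",
                                paste(miss, collapse = ", ")),
                        class = c("ptychotomo_parse_error", "error")))
  list(orientations = lapply(seq_len(nrow(df)), function(i)
         orientation(df$tilt1_deg[i], df$tilt2_deg[i])),
       defocus_nm = df$defocus_nm,
       shifts_px = as.matrix(df[, c("shift_y_px", "shift_x_px")]))
}
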