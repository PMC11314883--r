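#' Write the outputs of a fusion run
#'
#' Writes into `out_dir`:
#' \itemize{
#'   \item `fused.tif` — fused image at the working bit depth (8- or 16-bit,
#'     values rounded to integers after smoothing);
#'   \item `index.tif` — per-pixel source index as 16-bit TIFF; 1-based frame
#'     indices, 0 reserved for void pixels;
#'   \item `depth.tif` — physical depth as 32-bit float TIFF, stored
#'     normalized by `depth_scale` (recorded in the sidecar) with void = 0;
#'     written only when z metadata is present, otherwise a warning is
#'     emitted;
#'   \item `run.json` — parameters, stage counts and the depth scale.
#' }
#' Re-reading `index.tif` with [read_index_map] reproduces the in-memory map
#' exactly; [read_depth_map] restores depths to single precision.
#'
#' @param result a `fused_result` from [fuse].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "fused_result"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  written <- character()

  bits <- if (result$max_value > 255) 16L else 8L
  f_fused <- file.path(out_dir, "fused.tif")
  img <- clip01(round(result$fused), 0, result$max_value) / result$max_value
  tiff::writeTIFF(img, f_fused, bits.per.sample = bits, compression = "none")
  written <- c(written, f_fused)

  f_index <- file.path(out_dir, "index.tif")
  idx <- result$pix
  idx[is.na(idx)] <- 0L
  tiff::writeTIFF(idx / 65535, f_index, bits.per.sample = 16L,
                  compression = "none")
  written <- c(written, f_index)

  depth_scale <- NULL
  if (!is.null(result$depth_um)) {
    f_depth <- file.path(out_dir, "depth.tif")
    depth_scale <- max(result$depth_um, 1)
    tiff::writeTIFF(clip01(result$depth_um, 0, depth_scale) / depth_scale,
                    f_depth, bits.per.sample = 32L, compression = "none")
    written <- c(written, f_depth)
  } else {
    warning("no z metadata: depth raster not written", call. = FALSE)
  }

  f_json <- file.path(out_dir, "run.json")
  jsonlite::write_json(
    list(params = unclass(result$params), criterion = result$criterion,
         max_value = result$max_value, depth_scale = depth_scale,
         z0 = result$z0, z_step = result$z_step,
         pixel_pitch = result$pixel_pitch, log = result$log),
    f_json, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(c(written, f_json))
}

#' Read back a written index map
#'
#' @param path `index.tif` written by [write_outputs].
#' @return Integer matrix of 1-based frame indices, `NA` for void pixels.
#' @export
read_index_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  m[m == 0L] <- NA_integer_
  m
}

#' Read back a written depth raster
#'
#' @param path `depth.tif` written by [write_outputs].
#' @param run_json the matching `run.json` sidecar (defaults to the one next
#'   to `path`) holding the normalization scale.
#' @return Numeric matrix of depths in micrometers (void = 0).
#' @export
read_depth_map <- function(path, run_json = file.path(dirname(path), "run.json")) {
  meta <- jsonlite::read_json(run_json, simplifyVector = TRUE)
  if (is.null(meta$depth_scale))
    stop("run.json has no depth_scale; was a depth raster written?", call. = FALSE)
  tiff::readTIFF(path) * meta$depth_scale
}

#' Export a depth raster as an ASCII PLY point cloud
#'
#' One vertex per non-void masked pixel, with x = (col-1) * pixel_pitch,
#' y = (row-1) * pixel_pitch and z = depth, all in micrometers. Void pixels
#' (depth `NA`) are excluded. An empty selection still produces a valid PLY
#' header (with a warning).
#'
#' @param depth_map numeric matrix of depths in micrometers; `NA` marks void
#'   pixels.
#' @param pixel_pitch lateral pixel size in micrometers (> 0).
#' @param path output `.ply` file.
#' @param mask optional logical matrix restricting the export region.
#' @return Invisibly, the number of vertices written.
#' @export
export_point_cloud <- function(depth_map, pixel_pitch, path, mask = NULL) {
  if (is.null(pixel_pitch) || pixel_pitch <= 0)
    stop("pixel_pitch must be > 0", call. = FALSE)
  keep <- !is.na(depth_map)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(depth_map)))
    keep <- keep & mask
  }
  ij <- which(keep, arr.ind = TRUE)
  n <- nrow(ij)
  if (n == 0L) warning("empty point cloud: no non-void masked pixels", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  if (n > 0L) {
    verts <- sprintf("%g %g %g",
                     (ij[, 2] - 1L) * pixel_pitch,
                     (ij[, 1] - 1L) * pixel_pitch,
                     depth_map[keep])
    writeLines(verts, con)
  }
  invisible(n)
}
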