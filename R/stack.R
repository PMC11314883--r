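#' Construct a focus stack
#'
#' A focus stack holds N co-registered grayscale frames of one visible area,
#' acquired at successive focal planes, together with optional z metadata.
#' Frames are stored as numeric matrices in their native integer intensity
#' range (e.g. 0..255 for 8-bit data); the working maximum is recorded in
#' `max_value` because the pipeline's intensity thresholds are expressed in
#' these raw units and scale with bit depth.
#'
#' Frame order corresponds to monotonically increasing object distance unless
#' `descending = TRUE`, in which case frames are reversed on construction so
#' that index 1 is always the shallowest plane.
#'
#' @param frames list of numeric matrices, all the same dimensions, values >= 0.
#' @param z0 object distance of frame 1 in micrometers (optional).
#' @param z_step spacing between consecutive focal planes in micrometers
#'   (optional).
#' @param pixel_pitch lateral size of one pixel in micrometers (optional).
#' @param max_value top of the working intensity range; inferred from the data
#'   (255 or 65535) when `NULL`.
#' @param descending set to `TRUE` if the supplied frames run from deep to
#'   shallow.
#' @return An object of class `focus_stack`.
#' @export
focus_stack <- function(frames, z0 = NULL, z_step = NULL, pixel_pitch = NULL,
                        max_value = NULL, descending = FALSE) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical dimensions", call. = FALSE)
  lo <- min(vapply(frames, min, numeric(1)))
  if (lo < 0) stop("frame intensities must be >= 0", call. = FALSE)
  if (descending) frames <- rev(frames)
  if (is.null(max_value)) {
    hi <- max(vapply(frames, max, numeric(1)))
    max_value <- if (hi <= 255) 255 else 65535
  }
  structure(
    list(frames = frames, n_frames = length(frames),
         H = dims[1, 1], W = dims[2, 1],
         z0 = z0, z_step = z_step, pixel_pitch = pixel_pitch,
         max_value = max_value),
    class = "focus_stack")
}

#' @export
print.focus_stack <- function(x, ...) {
  cat(sprintf("focus_stack: %d frames of %d x %d, working range [0, %g]\n",
              x$n_frames, x$H, x$W, x$max_value))
  if (!is.null(x$z_step))
    cat(sprintf("  z: z0 = %g um, step = %g um\n",
                if (is.null(x$z0)) 0 else x$z0, x$z_step))
  invisible(x)
}

# Read one single-page image file as a grayscale matrix in native integer
# units. RGB is collapsed to luminance with the fixed Rec.601 weighting
# 0.299 R + 0.587 G + 0.114 B.
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    # PNG readers return [0,1]; rescale to 8-bit units.
    round(png::readPNG(path) * 255)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  to_gray(img, path)
}

to_gray <- function(img, path = "<frame>") {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  if (!is.matrix(img)) stop("could not read a 2-D raster from ", path, call. = FALSE)
  storage.mode(img) <- "double"
  img
}

#' Read a z-stack from disk
#'
#' Accepts either a multi-page TIFF file or a directory of equally sized
#' single-page TIFF/PNG images. Within a directory, lexicographic file order
#' defines z order unless `order_file` (a text file listing one filename per
#' line) is given. Intensities are kept in their native integer range.
#'
#' @param path multi-page TIFF file or directory of frames.
#' @param order_file optional text file fixing frame order explicitly.
#' @inheritParams focus_stack
#' @return A [focus_stack].
#' @export
read_stack <- function(path, z0 = NULL, z_step = NULL, pixel_pitch = NULL,
                       order_file = NULL, descending = FALSE) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
    if (!is.null(order_file)) {
      files <- readLines(order_file, warn = FALSE)
      files <- files[nzchar(trimws(files))]
    } else {
      files <- sort(files, method = "radix")
    }
    if (length(files) < 2L)
      stop("a stack needs at least 2 frames; found ", length(files),
           " in ", path, call. = FALSE)
    frames <- vector("list", length(files))
    for (i in seq_along(files)) {
      fp <- file.path(path, files[i])
      if (!file.exists(fp)) stop("cannot read frame file: ", fp, call. = FALSE)
      frames[[i]] <- read_frame(fp)
      if (i > 1L && !identical(dim(frames[[i]]), dim(frames[[1]])))
        stop(sprintf("frame dimension mismatch: %s is %dx%d, expected %dx%d",
                     files[i], nrow(frames[[i]]), ncol(frames[[i]]),
                     nrow(frames[[1]]), ncol(frames[[1]])), call. = FALSE)
    }
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) < 2L)
      stop("a stack needs at least 2 frames; multi-page TIFF has ",
           length(pages), call. = FALSE)
    frames <- lapply(pages, to_gray, path = path)
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  focus_stack(frames, z0 = z0, z_step = z_step, pixel_pitch = pixel_pitch,
              descending = descending)
}

#' Fusion parameters
#'
#' Bundles the tunable parameters of the pipeline. All intensity thresholds
#' (`threshold0`, `threshold4`) are in raw intensity units and therefore scale
#' with the stack's bit depth; index thresholds (`threshold1`, `threshold3`)
#' are in frame-index units. Defaults are the reference settings for 8-bit
#' pollen stacks.
#'
#' @param block_h,block_w block size in pixels (rows, columns).
#' @param threshold0 confidence cut: a block is confident when the maximum
#'   pixel value of its selected patch strictly exceeds this.
#' @param threshold1 index difference beyond which a neighbour counts as a
#'   disagreeing vote during depth adjustment.
#' @param threshold2 minimum number of confident voters required before a
#'   block's depth may be replaced.
#' @param ratio fraction of disagreeing votes (of all confident votes) that
#'   triggers replacement, in [0, 1].
#' @param threshold3 block-index gap above which an adjacent block pair enters
#'   information filling.
#' @param threshold4 intensity ceiling: a pixel already at least this bright in
#'   its current source frame is never reassigned.
#' @param kernel voting window radius in blocks; the window is
#'   (2*kernel+1) squared, clipped at the grid border.
#' @param smoothing_sigma Gaussian sigma (pixels) for seam smoothing; 0
#'   disables smoothing.
#' @param by_objects run the optional per-object pipeline.
#' @param size_ladder,divisor,min_block block-size selection rule for the
#'   per-object pipeline (see [choose_block_size]).
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(block_h = 15, block_w = 15,
                          threshold0 = 60, threshold1 = 40, threshold2 = 4,
                          threshold3 = 10, threshold4 = 80,
                          kernel = 2, ratio = 0.5, smoothing_sigma = 1,
                          by_objects = FALSE,
                          size_ladder = c(5, 10, 15, 20, 25),
                          divisor = 10, min_block = 5) {
  p <- list(block_h = block_h, block_w = block_w,
            threshold0 = threshold0, threshold1 = threshold1,
            threshold2 = threshold2, threshold3 = threshold3,
            threshold4 = threshold4, kernel = kernel, ratio = ratio,
            smoothing_sigma = smoothing_sigma, by_objects = by_objects,
            size_ladder = sort(size_ladder), divisor = divisor,
            min_block = min_block)
  validate_params(p)
  structure(p, class = "fusion_params")
}

validate_params <- function(p) {
  if (p$block_h < 2 || p$block_w < 2)
    stop("block size must be at least 2x2", call. = FALSE)
  if (p$kernel < 1) stop("kernel radius must be >= 1", call. = FALSE)
  if (p$ratio < 0 || p$ratio > 1) stop("ratio must lie in [0, 1]", call. = FALSE)
  thr <- c(p$threshold0, p$threshold1, p$threshold2, p$threshold3, p$threshold4)
  if (any(thr < 0)) stop("thresholds must be >= 0", call. = FALSE)
  if (p$smoothing_sigma < 0) stop("smoothing_sigma must be >= 0", call. = FALSE)
  invisible(p)
}

#' Read fusion parameters from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys mirror the [fusion_params]
#' arguments; missing keys fall back to the defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `fusion_params` object.
#' @export
read_fusion_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("parameter file must be YAML or JSON: ", path, call. = FALSE)
  }
  known <- names(formals(fusion_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown parameter keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(fusion_params, vals[intersect(names(vals), known)])
}

#' @export
print.fusion_params <- function(x, ...) {
  cat(sprintf(
    "fusion_params: block %gx%g | t0=%g t1=%g t2=%g t3=%g t4=%g | kernel=%g ratio=%g sigma=%g\n",
    x$block_h, x$block_w, x$threshold0, x$threshold1, x$threshold2,
    x$threshold3, x$threshold4, x$kernel, x$ratio, x$smoothing_sigma))
  invisible(x)
}
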