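#' Initialize the per-pixel index map from block depths
#'
#' Every pixel inherits the (possibly void) frame index of the block that
#' contains it.
#'
#' @param depth finalized `block_depth` map.
#' @param grid the matching [block_grid].
#' @return H x W integer matrix (`NA` = void).
#' @export
init_pixel_index <- function(depth, grid) {
  stopifnot(inherits(grid, "block_grid"))
  m <- depth[grid_row_of(grid), grid_col_of(grid), drop = FALSE]
  m <- matrix(as.integer(m), grid$H, grid$W)
  m
}

# Adjacent block pairs in raster order: horizontal (j,k)-(j,k+1) first, then
# vertical (j,k)-(j+1,k). 4-connectivity only.
block_pairs <- function(J, K) {
  pairs <- list()
  for (j in seq_len(J)) for (k in seq_len(K - 1L))
    pairs[[length(pairs) + 1L]] <- c(j, k, j, k + 1L)
  for (j in seq_len(J - 1L)) for (k in seq_len(K))
    pairs[[length(pairs) + 1L]] <- c(j, k, j + 1L, k)
  pairs
}

#' Information filling across block seams
#'
#' Assigning one depth per block leaves blocking artifacts wherever an object
#' boundary crosses a block: some of the block's pixels really belong to the
#' depth of the neighbouring block. For every 4-adjacent block pair whose
#' indices differ by more than `threshold3` and of which at least one member
#' is confident, each pixel in either block may switch to the other block's
#' index `x`: it does so iff its value in its current source frame `d` is
#' below `threshold4` (it is not convincingly in focus where it is) and
#' dimmer than its value in frame `x`. Pairs are processed in raster order
#' (horizontal then vertical) and updates are immediate, so a pixel may be
#' revised by successive pairs; `d` is always the pixel's current index.
#'
#' @param stack a [focus_stack].
#' @param pix pixel index map from [init_pixel_index].
#' @param depth finalized `block_depth` map (block-level indices drive the
#'   pair tests and the target index `x`).
#' @param conf matching [confidence_map].
#' @param params a [fusion_params] (uses `threshold3`, `threshold4`).
#' @param grid the matching [block_grid].
#' @return Updated pixel index map with attribute `n_refilled` (pixel
#'   reassignments, counting multiplicity).
#' @export
information_filling <- function(stack, pix, depth, conf, params, grid) {
  n_changed <- 0L
  frames <- stack$frames
  fill_side <- function(rows, cols, x) {
    sub <- pix[rows, cols, drop = FALSE]
    vx <- frames[[x]][rows, cols, drop = FALSE]
    for (d in unique(sub[!is.na(sub) & sub != x])) {
      sel <- !is.na(sub) & sub == d
      vd <- frames[[d]][rows, cols, drop = FALSE]
      sw <- sel & vd < params$threshold4 & vd < vx
      if (any(sw)) {
        sub[sw] <- x
        n_changed <<- n_changed + sum(sw)
      }
    }
    pix[rows, cols] <<- sub
  }
  for (pr in block_pairs(grid$J, grid$K)) {
    i1 <- depth[pr[1], pr[2]]; i2 <- depth[pr[3], pr[4]]
    if (is.na(i1) || is.na(i2)) next
    if (conf[pr[1], pr[2]] == 0L && conf[pr[3], pr[4]] == 0L) next
    if (abs(i1 - i2) <= params$threshold3) next
    fill_side(grid$row0[pr[1]]:grid$row1[pr[1]],
              grid$col0[pr[2]]:grid$col1[pr[2]], i2)
    fill_side(grid$row0[pr[3]]:grid$row1[pr[3]],
              grid$col0[pr[4]]:grid$col1[pr[4]], i1)
  }
  attr(pix, "n_refilled") <- n_changed
  pix
}

#' Assemble the fused image
#'
#' `fused[p] = frames[[pix[p]]][p]`; void pixels render as 0. Before any
#' smoothing, every non-void fused pixel is a bit-copy of the corresponding
#' pixel of exactly one source frame.
#'
#' @param stack a [focus_stack].
#' @param pix finalized pixel index map.
#' @return H x W numeric matrix.
#' @export
assemble_fused <- function(stack, pix) {
  fused <- matrix(0, stack$H, stack$W)
  for (i in sort(unique(pix[!is.na(pix)]))) {
    sel <- !is.na(pix) & pix == i
    fused[sel] <- stack$frames[[i]][sel]
  }
  fused
}

# Band of +/-2 px around block boundaries where the pixel index changes
# across the boundary (both sides non-void).
seam_band <- function(pix, grid, halfwidth = 2L) {
  band <- matrix(FALSE, grid$H, grid$W)
  for (j in seq_len(grid$J - 1L)) {
    r <- grid$row1[j]
    diffp <- !is.na(pix[r, ]) & !is.na(pix[r + 1L, ]) & pix[r, ] != pix[r + 1L, ]
    band[r, diffp] <- TRUE
    band[r + 1L, diffp] <- TRUE
  }
  for (k in seq_len(grid$K - 1L)) {
    cc <- grid$col1[k]
    diffp <- !is.na(pix[, cc]) & !is.na(pix[, cc + 1L]) & pix[, cc] != pix[, cc + 1L]
    band[diffp, cc] <- TRUE
    band[diffp, cc + 1L] <- TRUE
  }
  if (any(band)) band <- dilate_cheb(band, halfwidth)
  band
}

#' Smooth block seams in the fused image and depth raster
#'
#' Gaussian smoothing of width `sigma` applied only inside a band of +/-2
#' pixels around block boundaries where the pixel index changes; the rest of
#' the image is untouched, preserving pixel provenance away from seams.
#' Smoothing acts on the fused intensities and on the physical depth raster
#' (never on the integer index map, which would invent source indices).
#' `sigma = 0` is the identity.
#'
#' @param fused assembled fused image.
#' @param pix finalized pixel index map (defines the seams).
#' @param grid the matching [block_grid].
#' @param sigma Gaussian sigma in pixels.
#' @param depth_raster optional physical depth raster smoothed with the same
#'   band.
#' @return `list(fused, depth, band)`.
#' @export
smooth_edges <- function(fused, pix, grid, sigma, depth_raster = NULL) {
  if (sigma <= 0)
    return(list(fused = fused, depth = depth_raster,
                band = matrix(FALSE, nrow(fused), ncol(fused))))
  band <- seam_band(pix, grid)
  out_f <- fused
  out_d <- depth_raster
  if (any(band)) {
    bf <- gauss_blur(fused, sigma)
    out_f[band] <- bf[band]
    if (!is.null(depth_raster)) {
      bd <- gauss_blur(depth_raster, sigma)
      out_d[band] <- bd[band]
    }
  }
  list(fused = out_f, depth = out_d, band = band)
}

#' Convert a pixel index map to physical depth
#'
#' `depth[p] = z0 + (pix[p] - 1) * z_step` micrometers for non-void pixels;
#' void pixels are exported as depth 0.
#'
#' @param pix pixel index map (1-based frame indices, `NA` = void).
#' @param z0 object distance of frame 1 (micrometers).
#' @param z_step focal-plane spacing (micrometers).
#' @return H x W numeric matrix in micrometers.
#' @export
index_to_depth <- function(pix, z0, z_step) {
  if (is.null(z0) || is.null(z_step))
    stop("z metadata (z0, z_step) required to convert indices to depth",
         call. = FALSE)
  d <- z0 + (pix - 1) * z_step
  d[is.na(pix)] <- 0
  matrix(as.numeric(d), nrow(pix), ncol(pix))
}

#' Run the full fusion pipeline
#'
#' Orchestrates block segmentation, sharpness evaluation, rough depth,
#' confidence, voting adjustment, unconfident-block filling, per-pixel
#' information filling, image assembly, seam smoothing and depth conversion.
#'
#' @param stack a [focus_stack].
#' @param params a [fusion_params].
#' @param criterion sharpness measure (default the proposed
#'   luminosity x variance measure).
#' @return A `fused_result` with elements `fused` (smoothed), `fused_raw`
#'   (pre-smoothing), `pix` (per-pixel source indices, `NA` = void),
#'   `depth_um`/`depth_um_raw` (if z metadata present), `block_depth`, `conf`,
#'   `grid`, `params`, and `log` (per-stage counts).
#' @export
fuse <- function(stack, params = fusion_params(), criterion = "proposed") {
  stopifnot(inherits(stack, "focus_stack"))
  validate_params(params)
  grid <- segment_blocks(stack$H, stack$W, params$block_h, params$block_w)
  s <- sharpness_tensor(stack, grid, criterion)
  depth0 <- rough_depth(s)
  conf <- confidence_map(stack, grid, depth0, params$threshold0)
  depth1 <- adjust_depth(depth0, conf, params)
  depth2 <- fill_unconfident(depth1, conf, params$kernel)
  pix0 <- init_pixel_index(depth2, grid)
  pix <- information_filling(stack, pix0, depth2, conf, params, grid)
  fused_raw <- assemble_fused(stack, pix)
  has_z <- !is.null(stack$z_step)
  depth_raw <- if (has_z) {
    z0 <- if (is.null(stack$z0)) 0 else stack$z0
    index_to_depth(pix, z0, stack$z_step)
  }
  sm <- smooth_edges(fused_raw, pix, grid, params$smoothing_sigma, depth_raw)
  log <- list(
    n_blocks = grid$J * grid$K,
    n_confident = sum(conf == 1L),
    n_adjusted = attr(depth1, "n_adjusted"),
    n_filled = attr(depth2, "n_filled"),
    n_void = attr(depth2, "n_void"),
    n_refilled = attr(pix, "n_refilled"),
    n_smoothed = sum(sm$band))
  structure(
    list(fused = sm$fused, fused_raw = fused_raw,
         pix = pix, depth_um = sm$depth, depth_um_raw = depth_raw,
         block_depth = depth2, conf = conf, grid = grid,
         params = params, criterion = attr(s, "criterion"),
         max_value = stack$max_value,
         z0 = stack$z0, z_step = stack$z_step, pixel_pitch = stack$pixel_pitch,
         log = log),
    class = "fused_result")
}

#' @export
print.fused_result <- function(x, ...) {
  cat(sprintf("fused_result: %d x %d image, criterion = %s\n",
              nrow(x$fused), ncol(x$fused), x$criterion))
  with(x$log, cat(sprintf(
    "  blocks: %d (%d confident, %d adjusted, %d filled, %d void)\n  pixels: %d refilled, %d in smoothing band\n",
    n_blocks, n_confident, n_adjusted, n_filled, n_void, n_refilled, n_smoothed)))
  if (!is.null(x$depth_um)) cat("  depth raster: micrometers\n")
  invisible(x)
}

#' Display a fused result
#'
#' @param x a `fused_result`.
#' @param which `"fused"` or `"depth"`.
#' @param ... passed to [graphics::image].
#' @export
plot.fused_result <- function(x, which = c("fused", "depth"), ...) {
  which <- match.arg(which)
  m <- if (which == "fused") x$fused else x$depth_um
  if (is.null(m)) stop("no depth raster in this result", call. = FALSE)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  invisible(x)
}
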