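# Optional per-object pipeline: detect separable objects, pick a block size
# per object scale, fuse each class under its mask, composite the results.

# DBSCAN over integer pixel coordinates with a grid-hashed neighbour search.
# Points are processed in (row, col) order; labels are assigned in discovery
# order, so the result is deterministic. min_samples = 1 degenerates to
# friends-of-friends linking with linking length eps.
dbscan_pixels <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  ord <- order(coords[, 1], coords[, 2])
  coords <- coords[ord, , drop = FALSE]
  cell <- floor(coords / eps)
  key <- paste(cell[, 1], cell[, 2])
  buckets <- split(seq_len(n), key)
  neighbours <- function(p) {
    cand <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(cell[p, 1] + dr, cell[p, 2] + dc)
      cand <- c(cand, buckets[[k]])
    }
    d2 <- (coords[cand, 1] - coords[p, 1])^2 + (coords[cand, 2] - coords[p, 2])^2
    cand[d2 <= eps^2]
  }
  labels <- integer(n)          # 0 = unvisited/noise
  visited <- logical(n)
  next_label <- 0L
  for (p in seq_len(n)) {
    if (visited[p]) next
    visited[p] <- TRUE
    nb <- neighbours(p)
    if (length(nb) < min_samples) next   # noise (may be claimed later)
    next_label <- next_label + 1L
    labels[p] <- next_label
    queue <- setdiff(nb, p)
    while (length(queue)) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- neighbours(q)
        if (length(nbq) >= min_samples)
          queue <- c(queue, setdiff(nbq, which(labels > 0L | visited)))
      }
      if (labels[q] == 0L) labels[q] <- next_label
    }
  }
  out <- integer(n)
  out[ord] <- labels
  out
}

# 4-connected components of a logical mask via the adjacency graph.
# Components are renumbered by their first pixel in column-major order.
connected_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nrow(mask), ncol(mask)))
  H <- nrow(mask)
  pos <- matrix(0L, nrow(mask), ncol(mask))
  pos[idx] <- seq_along(idx)
  ij <- which(mask, arr.ind = TRUE)
  edges <- integer(0)
  for (shift in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- ij[, 1] + shift[1]; c2 <- ij[, 2] + shift[2]
    ok <- r2 <= H & c2 <= ncol(mask)
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- c(edges, rbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  comp <- match(comp, comp[!duplicated(comp)])  # renumber by first pixel
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[idx] <- comp
  lab
}

#' Detect separable objects in a stack
#'
#' Clusters the bright pixels of the maximum projection (the brightest
#' evidence across depth) into objects. Pixels above `luminosity_threshold`
#' are clustered spatially with DBSCAN (or its friends-of-friends linking
#' preset, or plain 4-connected components); pixels below threshold stay
#' unlabeled (label 0) until [complete_partition].
#'
#' @param stack a [focus_stack].
#' @param luminosity_threshold intensity cut on the max projection, raw units.
#' @param method `"dbscan"`, `"fof"` (DBSCAN with `min_samples = 1`), or
#'   `"connected_components"`.
#' @param eps DBSCAN neighbourhood radius in pixels.
#' @param min_samples DBSCAN core-point minimum (ignored by the other
#'   methods).
#' @return An `object_partition`: `labels` (H x W integer, 0 = unassigned),
#'   per-label `stats` (bbox, pixel count), and empty `block_size` slots.
#' @export
detect_objects <- function(stack, luminosity_threshold,
                           method = c("dbscan", "fof", "connected_components"),
                           eps = 5, min_samples = 5) {
  stopifnot(inherits(stack, "focus_stack"))
  method <- match.arg(method)
  proj <- max_projection(stack)
  bright <- proj > luminosity_threshold
  labels <- matrix(0L, stack$H, stack$W)
  if (!any(bright)) {
    warning("no pixels above luminosity threshold: empty partition",
            call. = FALSE)
  } else if (method == "connected_components") {
    labels <- connected_components(bright)
  } else {
    if (method == "fof") min_samples <- 1L
    coords <- which(bright, arr.ind = TRUE)
    lab <- dbscan_pixels(coords, eps, min_samples)
    labels[coords] <- lab
  }
  new_partition(labels)
}

new_partition <- function(labels, block_size = NULL) {
  n_lab <- max(labels)
  stats <- lapply(seq_len(n_lab), function(l) {
    ij <- which(labels == l, arr.ind = TRUE)
    list(label = l, n_pixels = nrow(ij),
         bbox_h = if (nrow(ij)) diff(range(ij[, 1])) + 1L else 0L,
         bbox_w = if (nrow(ij)) diff(range(ij[, 2])) + 1L else 0L)
  })
  structure(list(labels = labels, n_labels = n_lab, stats = stats,
                 block_size = block_size),
            class = "object_partition")
}

#' @export
print.object_partition <- function(x, ...) {
  cat(sprintf("object_partition: %d objects over %d x %d (%d px unassigned)\n",
              x$n_labels, nrow(x$labels), ncol(x$labels), sum(x$labels == 0L)))
  invisible(x)
}

#' Choose a block size for an object's scale
#'
#' Deterministic rule mapping object extent to a fusion block size: the
#' target edge is `max(min_block, min(bbox_h, bbox_w) / divisor)` and the
#' chosen size is the largest ladder entry not exceeding it (the smallest
#' ladder entry if none fits). Doubling an object's bounding box never
#' decreases the chosen size.
#'
#' @param bbox_h,bbox_w object bounding-box height and width in pixels.
#' @param size_ladder ordered candidate block edges in pixels.
#' @param divisor how many blocks should span the object's smaller extent.
#' @param min_block lower clamp on the target edge.
#' @return Length-2 integer vector `c(m, n)` (square blocks).
#' @export
choose_block_size <- function(bbox_h, bbox_w,
                              size_ladder = c(5, 10, 15, 20, 25),
                              divisor = 10, min_block = 5) {
  ladder <- sort(size_ladder)
  target <- max(min_block, min(bbox_h, bbox_w) / divisor)
  fit <- ladder[ladder <= target]
  sz <- if (length(fit)) max(fit) else min(ladder)
  as.integer(c(sz, sz))
}

#' Complete a partition to cover every pixel
#'
#' Assigns each unlabeled pixel the label of its nearest labeled pixel
#' (exact Euclidean distance, ties to the smaller label). Labels already
#' assigned are never changed, and the completed assignment is exclusive and
#' total.
#'
#' @param partition an `object_partition` with at least one label.
#' @return The completed `object_partition`.
#' @export
complete_partition <- function(partition) {
  stopifnot(inherits(partition, "object_partition"))
  if (partition$n_labels < 1L)
    stop("cannot complete a partition with no labels", call. = FALSE)
  labels <- partition$labels
  if (!any(labels == 0L)) return(partition)
  best_d <- matrix(Inf, nrow(labels), ncol(labels))
  assign <- labels
  for (l in seq_len(partition$n_labels)) {
    d2 <- edt_squared(labels == l)
    upd <- labels == 0L & d2 < best_d   # strict: ties keep the smaller label
    assign[upd] <- l
    best_d[upd] <- d2[upd]
  }
  out <- new_partition(assign, partition$block_size)
  out
}

#' Per-object fusion
#'
#' Runs the full fusion pipeline once per class of objects. Classes are
#' labels sharing a block size (chosen per object with [choose_block_size]
#' unless `partition$block_size` is preset); for each class the source frames
#' are masked (pixels outside the class mask set to 0) and the pipeline is
#' rerun at the class's block size; the fused images, index maps and depth
#' rasters are then composited through the masks, each output pixel written
#' by exactly the class that owns it.
#'
#' @param stack a [focus_stack].
#' @param params a [fusion_params]; `size_ladder`, `divisor` and `min_block`
#'   drive the per-object block-size choice.
#' @param partition a completed [object_partition] (completed automatically
#'   if unassigned pixels remain).
#' @return A `fused_result` covering the whole image; `log$classes` records
#'   the block size and labels of each class.
#' @export
fuse_by_objects <- function(stack, params = fusion_params(), partition) {
  stopifnot(inherits(stack, "focus_stack"),
            inherits(partition, "object_partition"))
  if (any(partition$labels == 0L)) partition <- complete_partition(partition)
  sizes <- partition$block_size
  if (is.null(sizes)) {
    sizes <- vapply(partition$stats, function(s) {
      choose_block_size(s$bbox_h, s$bbox_w, params$size_ladder,
                        params$divisor, params$min_block)[1]
    }, integer(1))
  }
  classes <- split(seq_len(partition$n_labels), sizes)
  fused <- matrix(0, stack$H, stack$W)
  fused_raw <- matrix(0, stack$H, stack$W)
  pix <- matrix(NA_integer_, stack$H, stack$W)
  has_z <- !is.null(stack$z_step)
  depth_um <- if (has_z) matrix(0, stack$H, stack$W)
  depth_raw <- if (has_z) matrix(0, stack$H, stack$W)
  class_log <- list()
  for (cl in names(classes)) {
    sz <- as.integer(cl)
    mask <- matrix(partition$labels %in% classes[[cl]],
                   stack$H, stack$W)
    masked <- stack
    masked$frames <- lapply(stack$frames, function(f) { f[!mask] <- 0; f })
    p_cl <- params
    p_cl$block_h <- sz
    p_cl$block_w <- sz
    res <- fuse(masked, p_cl)
    fused[mask] <- res$fused[mask]
    fused_raw[mask] <- res$fused_raw[mask]
    pix[mask] <- res$pix[mask]
    if (has_z) {
      depth_um[mask] <- res$depth_um[mask]
      depth_raw[mask] <- res$depth_um_raw[mask]
    }
    class_log[[cl]] <- list(block_size = sz, labels = classes[[cl]],
                            n_pixels = sum(mask), log = res$log)
  }
  structure(
    list(fused = fused, fused_raw = fused_raw, pix = pix,
         depth_um = depth_um, depth_um_raw = depth_raw,
         block_depth = NULL, conf = NULL,
         grid = segment_blocks(stack$H, stack$W, params$block_h, params$block_w),
         params = params, criterion = "proposed",
         max_value = stack$max_value,
         z0 = stack$z0, z_step = stack$z_step, pixel_pitch = stack$pixel_pitch,
         log = list(n_blocks = NA_integer_, n_confident = NA_integer_,
                    n_adjusted = NA_integer_, n_filled = NA_integer_,
                    n_void = NA_integer_, n_refilled = NA_integer_,
                    n_smoothed = NA_integer_, classes = class_log)),
    class = "fused_result")
}
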