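#' Partition an image into rectangular blocks
#'
#' Tiles the H x W visible area with nonoverlapping blocks of nominal size
#' m x n pixels. Interior blocks are exactly m x n; the last row/column of
#' blocks may be smaller so the grid covers every pixel exactly once (no
#' padding — statistics on boundary patches use their actual pixel count).
#'
#' @param H,W image height and width in pixels.
#' @param m,n block height and width in pixels.
#' @return A `block_grid`: grid dimensions J x K plus 1-based inclusive pixel
#'   spans `row0`/`row1` (length J) and `col0`/`col1` (length K).
#' @export
segment_blocks <- function(H, W, m, n) {
  if (m <= 0 || n <= 0 || m > H || n > W)
    stop("block size must satisfy 0 < m <= H and 0 < n <= W", call. = FALSE)
  J <- as.integer(ceiling(H / m))
  K <- as.integer(ceiling(W / n))
  row0 <- as.integer((seq_len(J) - 1L) * m + 1L)
  row1 <- as.integer(pmin(seq_len(J) * m, H))
  col0 <- as.integer((seq_len(K) - 1L) * n + 1L)
  col1 <- as.integer(pmin(seq_len(K) * n, W))
  structure(list(H = as.integer(H), W = as.integer(W),
                 m = as.integer(m), n = as.integer(n),
                 J = J, K = K,
                 row0 = row0, row1 = row1, col0 = col0, col1 = col1),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("block_grid: %d x %d blocks of %d x %d px over %d x %d image\n",
              x$J, x$K, x$m, x$n, x$H, x$W))
  invisible(x)
}

# Block row/col membership of every pixel row/column.
grid_row_of <- function(grid) rep.int(seq_len(grid$J), grid$row1 - grid$row0 + 1L)
grid_col_of <- function(grid) rep.int(seq_len(grid$K), grid$col1 - grid$col0 + 1L)

#' Population variance of a patch
#'
#' Mean squared deviation from the patch mean, dividing by the pixel count
#' (not count - 1). This is the variance term of the sharpness measure.
#'
#' @param patch numeric matrix (or vector) of intensities.
#' @return Nonnegative scalar.
#' @export
patch_variance <- function(patch) {
  if (length(patch) == 0L) stop("empty patch", call. = FALSE)
  mu <- mean(patch)
  mean((patch - mu)^2)
}

#' Proposed fluorescence sharpness measure
#'
#' Sharpness of a patch as (maximum pixel value) x (population variance).
#' The maximum-luminosity factor exploits the property of fluorescence optics
#' that in-focus structures are also the brightest; the variance factor
#' rewards resolved texture. The product scales as a^3 when intensities are
#' scaled by a.
#'
#' @inheritParams patch_variance
#' @return Nonnegative scalar.
#' @export
sharpness_proposed <- function(patch) {
  if (length(patch) == 0L) stop("empty patch", call. = FALSE)
  max(patch) * patch_variance(patch)
}

#' Classical comparison sharpness measures
#'
#' Alternative per-patch focus measures used as baselines: `variance`
#' (population variance), `normalized_variance` (variance / mean, defined as 0
#' for an all-dark patch with mean 0), `laplacian` (mean absolute response of
#' the 4-neighbour Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]` with
#' replicated borders), and `local_max` (maximum pixel value).
#'
#' @inheritParams patch_variance
#' @param criterion one of `"variance"`, `"normalized_variance"`,
#'   `"laplacian"`, `"local_max"`.
#' @return Nonnegative scalar.
#' @export
sharpness_alt <- function(patch,
                          criterion = c("variance", "normalized_variance",
                                        "laplacian", "local_max")) {
  criterion <- match.arg(criterion)
  if (length(patch) == 0L) stop("empty patch", call. = FALSE)
  switch(criterion,
    variance = patch_variance(patch),
    normalized_variance = {
      mu <- mean(patch)
      if (mu == 0) 0 else patch_variance(patch) / mu
    },
    laplacian = patch_laplacian(patch),
    local_max = max(patch))
}

# Mean |4-neighbour Laplacian| over a patch, borders replicated.
patch_laplacian <- function(patch) {
  if (!is.matrix(patch)) patch <- matrix(patch, nrow = 1L)
  h <- nrow(patch); w <- ncol(patch)
  up    <- patch[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- patch[c(seq_len(h)[-1L], h), , drop = FALSE]
  left  <- patch[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- patch[, c(seq_len(w)[-1L], w), drop = FALSE]
  mean(abs(up + down + left + right - 4 * patch))
}

sharpness_criteria <- c("proposed", "variance", "normalized_variance",
                        "laplacian", "local_max")

# Dispatch a patch to the named measure.
patch_sharpness <- function(patch, criterion) {
  if (criterion == "proposed") sharpness_proposed(patch)
  else sharpness_alt(patch, criterion)
}

#' Sharpness of every patch in a stack
#'
#' Evaluates the chosen sharpness measure on every image x block patch,
#' yielding the tensor `s[i, j, k]` (frame i, block row j, block column k)
#' from which the block depth map is derived.
#'
#' @param stack a [focus_stack].
#' @param grid a [block_grid] built for the stack's dimensions.
#' @param criterion `"proposed"` or one of the [sharpness_alt] baselines.
#' @return A numeric array of dimension `c(n_frames, J, K)` with attributes
#'   `criterion` and class `sharpness_tensor`.
#' @export
sharpness_tensor <- function(stack, grid, criterion = "proposed") {
  stopifnot(inherits(stack, "focus_stack"), inherits(grid, "block_grid"))
  criterion <- match.arg(criterion, sharpness_criteria)
  if (grid$H != stack$H || grid$W != stack$W)
    stop("grid was built for a different image size", call. = FALSE)
  N <- stack$n_frames
  s <- array(0, dim = c(N, grid$J, grid$K))
  for (i in seq_len(N)) {
    fr <- stack$frames[[i]]
    for (j in seq_len(grid$J)) {
      rows <- grid$row0[j]:grid$row1[j]
      for (k in seq_len(grid$K)) {
        s[i, j, k] <- patch_sharpness(
          fr[rows, grid$col0[k]:grid$col1[k], drop = FALSE], criterion)
      }
    }
  }
  structure(s, criterion = criterion, class = c("sharpness_tensor", "array"))
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum across all frames: the fusion rule used for confocal
#' stacks, where a pinhole rejects out-of-focus light. For widefield
#' fluorescence it serves as the baseline that out-of-focus contamination
#' defeats.
#'
#' @param stack a [focus_stack].
#' @return H x W numeric matrix.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "focus_stack"))
  Reduce(pmax, stack$frames)
}

# Per-pixel argmax across frames (first frame wins ties); the per-pixel
# analogue of rough_depth for the confocal-style baseline.
argmax_projection <- function(stack) {
  idx <- matrix(1L, stack$H, stack$W)
  best <- stack$frames[[1]]
  for (i in seq_len(stack$n_frames)[-1L]) {
    upd <- stack$frames[[i]] > best
    idx[upd] <- i
    best[upd] <- stack$frames[[i]][upd]
  }
  idx
}
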