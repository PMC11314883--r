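#' Rough block depth map
#'
#' For every block, the index of the frame in which it is sharpest:
#' `index[j, k] = argmax_i s[i, j, k]`, with ties broken toward the smallest
#' frame index (deterministic, order-stable). Because frames are ordered by
#' object distance, this index is the block's depth in frame units.
#'
#' @param tensor a [sharpness_tensor].
#' @return A `block_depth` integer matrix (J x K) with attribute `n_frames`;
#'   void blocks (none at this stage) are `NA`.
#' @export
rough_depth <- function(tensor) {
  stopifnot(inherits(tensor, "sharpness_tensor"))
  d <- dim(tensor)
  idx <- matrix(NA_integer_, d[2], d[3])
  for (j in seq_len(d[2]))
    for (k in seq_len(d[3]))
      idx[j, k] <- which.max(tensor[, j, k])
  structure(idx, n_frames = d[1], class = c("block_depth", "matrix"))
}

block_depth_map <- function(idx, n_frames) {
  structure(idx, n_frames = n_frames, class = c("block_depth", "matrix"))
}

#' Block confidence map
#'
#' A block's depth estimate is trusted only if the block is luminous enough
#' when in focus: `C[j, k] = 1` iff the maximum pixel value of the selected
#' patch (the block's pixels in its winning frame) strictly exceeds
#' `threshold0`, else 0. Dim blocks are vulnerable to out-of-focus
#' fluorescence from brighter structures and are handled by voting/filling
#' instead.
#'
#' @param stack a [focus_stack].
#' @param grid the [block_grid] used for `depth`.
#' @param depth a `block_depth` map from [rough_depth].
#' @param threshold0 intensity cut in raw units.
#' @return Integer 0/1 matrix (J x K) with attribute `threshold0`.
#' @export
confidence_map <- function(stack, grid, depth, threshold0) {
  stopifnot(inherits(stack, "focus_stack"), inherits(grid, "block_grid"))
  C <- matrix(0L, grid$J, grid$K)
  for (j in seq_len(grid$J)) {
    rows <- grid$row0[j]:grid$row1[j]
    for (k in seq_len(grid$K)) {
      i <- depth[j, k]
      if (is.na(i)) next
      mjk <- max(stack$frames[[i]][rows, grid$col0[k]:grid$col1[k]])
      if (mjk > threshold0) C[j, k] <- 1L
    }
  }
  attr(C, "threshold0") <- threshold0
  C
}

# Clipped voting window around (j, k).
window_span <- function(j, k, J, K, kernel) {
  list(rows = max(1L, j - kernel):min(J, j + kernel),
       cols = max(1L, k - kernel):min(K, k + kernel))
}

#' Confidence-gated depth adjustment
#'
#' Tissue surfaces are continuous, so the depth of a block should rarely jump
#' far from its neighbourhood. For each block, the confident blocks of its
#' (2*kernel+1)^2 window vote: `vote_num` counts them, `pos_vote` counts those
#' whose index differs from the centre by more than `threshold1`. When
#' `pos_vote > ratio * vote_num` and `vote_num > threshold2`, the centre index
#' is replaced by the rounded mean index of the disagreeing confident voters
#' (the evidence that outvoted it; the centre itself never votes against
#' itself). All windows read the input map — the update is synchronous, so the
#' result does not depend on block scan order, and a single pass is made.
#'
#' @param depth a `block_depth` map.
#' @param conf matching [confidence_map].
#' @param params a [fusion_params] (uses `kernel`, `threshold1`, `threshold2`,
#'   `ratio`).
#' @return Adjusted `block_depth` map with attribute `n_adjusted`.
#' @export
adjust_depth <- function(depth, conf, params) {
  J <- nrow(depth); K <- ncol(depth)
  out <- depth
  n_adj <- 0L
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      centre <- depth[j, k]
      if (is.na(centre)) next
      w <- window_span(j, k, J, K, params$kernel)
      idx_w <- depth[w$rows, w$cols]
      conf_w <- conf[w$rows, w$cols]
      voters <- idx_w[conf_w == 1L & !is.na(idx_w)]
      vote_num <- length(voters)
      disagree <- voters[abs(voters - centre) > params$threshold1]
      pos_vote <- length(disagree)
      if (pos_vote > params$ratio * vote_num && vote_num > params$threshold2) {
        out[j, k] <- as.integer(round_half_up(mean(disagree)))
        n_adj <- n_adj + 1L
      }
    }
  }
  attr(out, "n_adjusted") <- n_adj
  out
}

#' Fill unconfident blocks from confident neighbours
#'
#' After adjustment, every block with `C = 0` borrows the rounded mean index
#' of the confident blocks in its (2*kernel+1)^2 window. An unconfident block
#' with no confident neighbour is marked void (`NA`): nothing in the stack
#' supports a depth there. Synchronous update, like [adjust_depth].
#'
#' @inheritParams adjust_depth
#' @param kernel window radius in blocks.
#' @return `block_depth` map with attributes `n_filled` and `n_void`.
#' @export
fill_unconfident <- function(depth, conf, kernel) {
  J <- nrow(depth); K <- ncol(depth)
  out <- depth
  n_fill <- 0L; n_void <- 0L
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      if (conf[j, k] == 1L) next
      w <- window_span(j, k, J, K, kernel)
      idx_w <- depth[w$rows, w$cols]
      conf_w <- conf[w$rows, w$cols]
      support <- idx_w[conf_w == 1L & !is.na(idx_w)]
      if (length(support)) {
        out[j, k] <- as.integer(round_half_up(mean(support)))
        n_fill <- n_fill + 1L
      } else {
        out[j, k] <- NA_integer_
        n_void <- n_void + 1L
      }
    }
  }
  attr(out, "n_filled") <- n_fill
  attr(out, "n_void") <- n_void
  out
}
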