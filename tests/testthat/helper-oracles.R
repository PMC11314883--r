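# Independent oracles and fixture builders. The oracles recompute every
# quantity from first principles with explicit loops/sums, independent of the
# package's code paths.

# Per-patch sharpness measures recomputed from their definitions. Reductions
# go through base mean()/max() so that agreement is checked at full precision
# (hand-rolled accumulation orders differ from R's long-double reductions in
# the last ulp and would mask real disagreements behind float noise).
naive_measure <- function(patch, criterion) {
  v <- as.vector(patch)
  mu <- mean(v)
  va <- mean((v - mu)^2)
  if (criterion == "variance") return(va)
  if (criterion == "local_max") return(max(v))
  if (criterion == "proposed") return(max(v) * va)
  if (criterion == "normalized_variance") return(if (mu == 0) 0 else va / mu)
  if (criterion == "laplacian") {
    if (!is.matrix(patch)) patch <- matrix(patch, nrow = 1)
    h <- nrow(patch); w <- ncol(patch)
    resp <- matrix(0, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      up <- patch[max(r - 1, 1), c]; dn <- patch[min(r + 1, h), c]
      lf <- patch[r, max(c - 1, 1)]; rt <- patch[r, min(c + 1, w)]
      resp[r, c] <- up + dn + lf + rt - 4 * patch[r, c]
    }
    return(mean(abs(resp)))
  }
  stop("unknown criterion")
}

# Full tensor by a naive triple loop over frames and block spans.
naive_tensor <- function(stack, grid, criterion) {
  s <- array(0, dim = c(stack$n_frames, grid$J, grid$K))
  for (i in seq_len(stack$n_frames))
    for (j in seq_len(grid$J))
      for (k in seq_len(grid$K))
        s[i, j, k] <- naive_measure(
          stack$frames[[i]][grid$row0[j]:grid$row1[j],
                            grid$col0[k]:grid$col1[k], drop = FALSE],
          criterion)
  s
}

# Per-pixel max across frames by explicit loop.
naive_max_projection <- function(stack) {
  out <- stack$frames[[1]]
  for (i in seq_len(stack$n_frames)[-1L])
    for (p in seq_len(stack$H * stack$W))
      if (stack$frames[[i]][p] > out[p]) out[p] <- stack$frames[[i]][p]
  out
}

random_stack <- function(H, W, N, max_value = 255, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  focus_stack(lapply(seq_len(N), function(i)
    matrix(as.double(sample(0:max_value, H * W, replace = TRUE)), H, W)),
    max_value = max_value)
}

# Block-wise mean and range of a per-pixel truth raster.
block_truth <- function(truth, grid) {
  bt <- matrix(NA_real_, grid$J, grid$K)
  br <- matrix(NA_real_, grid$J, grid$K)
  for (j in seq_len(grid$J)) for (k in seq_len(grid$K)) {
    z <- truth[grid$row0[j]:grid$row1[j], grid$col0[k]:grid$col1[k]]
    bt[j, k] <- mean(z)
    br[j, k] <- diff(range(z))
  }
  list(mean = bt, range = br)
}

strip_attrs <- function(m) {
  attributes(m) <- attributes(m)["dim"]
  m
}

# A constant-depth block map with a few isolated corrupted blocks.
corrupted_map <- function(J, K, base_index, corrupt_index, positions, n_frames) {
  d <- matrix(as.integer(base_index), J, K)
  for (r in seq_len(nrow(positions)))
    d[positions[r, 1], positions[r, 2]] <- as.integer(corrupt_index)
  focusfuse:::block_depth_map(d, n_frames)
}
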