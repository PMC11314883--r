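# Small numeric primitives shared across the pipeline.

# Round half away from zero (for nonnegative x: half-up). base::round() rounds
# half to even, which would make voting averages depend on parity.
round_half_up <- function(x) floor(x + 0.5)

# Fold arbitrary (possibly out-of-range) indices into [1, n] by symmetric
# reflection with edge repetition: ... 2 1 | 1 2 ... n | n n-1 ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j >= n, 2L * n - 1L - j, j) + 1L)
}

# Separable Gaussian blur of a numeric matrix. Kernel truncated at 3*sigma,
# renormalized; borders handled by symmetric reflection. sigma <= 0 is the
# identity.
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_cols <- function(m) {
    H <- nrow(m)
    pad <- m[reflect_index(seq.int(1L - r, H + r), H), , drop = FALSE]
    f <- stats::filter(pad, k, sides = 2)
    matrix(as.numeric(f[(r + 1L):(r + H), ]), nrow = H)
  }
  t(blur_cols(t(blur_cols(mat))))
}

# Exact 1-D squared Euclidean distance transform (lower envelope of parabolas).
# f: vector of initial squared costs (0 at sites, Inf elsewhere).
edt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)           # parabola sites
  z <- numeric(n + 1L)      # envelope breakpoints
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      if (is.infinite(f[p])) { # only possible for the initial placeholder
        v[k] <- q
        z[k + 1L] <- Inf
        break
      }
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
      if (s <= z[k]) {
        k <- k - 1L
        next
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
      break
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- if (is.infinite(f[p])) Inf else (q - p)^2 + f[p]
  }
  d
}

# Exact squared Euclidean distance map to the TRUE pixels of a logical matrix.
edt_squared <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  f <- ifelse(mask, 0, Inf)
  H <- nrow(f); W <- ncol(f)
  for (k in seq_len(W)) f[, k] <- edt_1d(f[, k])    # within each column
  for (r in seq_len(H)) f[r, ] <- edt_1d(f[r, ])    # within each row
  f
}

# Dilate a logical mask by Chebyshev radius r (square structuring element).
dilate_cheb <- function(mask, r) {
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (dr in seq.int(-r, r)) {
    rs <- pmin(pmax(seq_len(H) + dr, 1L), H)
    for (dc in seq.int(-r, r)) {
      cs <- pmin(pmax(seq_len(W) + dc, 1L), W)
      out <- out | mask[rs, cs, drop = FALSE]
    }
  }
  out
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)
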