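two_disc_stack <- function(H = 60, W = 160, centres = list(c(30, 30), c(30, 130)),
                           radius = 8, level = 250) {
  m <- matrix(0, H, W)
  for (ctr in centres)
    m[(row(m) - ctr[1])^2 + (col(m) - ctr[2])^2 <= radius^2] <- level
  focus_stack(list(m, m * 0.5))
}

test_that("object detection separates well-spaced bright components", {
  stk <- two_disc_stack()
  for (meth in c("dbscan", "connected_components", "fof")) {
    part <- detect_objects(stk, 100, method = meth, eps = 5, min_samples = 3)
    expect_equal(part$n_labels, 2L, label = meth)
  }
  one <- two_disc_stack(centres = list(c(30, 80)))
  expect_equal(detect_objects(one, 100, eps = 5, min_samples = 3)$n_labels, 1L)
  expect_warning(empty <- detect_objects(one, 260), "no pixels above")
  expect_equal(empty$n_labels, 0L)
})

test_that("dbscan labels agree with connected components on blocky masks", {
  stk <- two_disc_stack(centres = list(c(20, 20), c(45, 120), c(15, 90)),
                        radius = 6)
  a <- detect_objects(stk, 100, method = "dbscan", eps = 1.5, min_samples = 1)
  b <- detect_objects(stk, 100, method = "connected_components")
  expect_equal(a$n_labels, b$n_labels)
  # same partition up to label names
  expect_equal(length(unique(paste(a$labels, b$labels))[
    unique(paste(a$labels, b$labels)) != "0 0"]), a$n_labels)
})

test_that("block size follows the ladder rule and is monotone in scale", {
  expect_equal(choose_block_size(300, 300, c(5, 10, 15, 20, 25), 10, 5),
               c(25L, 25L))
  expect_equal(choose_block_size(60, 40, c(5, 10, 15, 20, 25), 10, 5),
               c(5L, 5L))
  for (h in seq(20, 400, by = 20)) {
    s1 <- choose_block_size(h, h)[1]
    s2 <- choose_block_size(2 * h, 2 * h)[1]
    expect_gte(s2, s1)
  }
})

test_that("completion assigns every pixel to its nearest label exactly", {
  # single label absorbs everything
  lab <- matrix(0L, 8, 8); lab[4, 4] <- 1L
  done <- complete_partition(focusfuse:::new_partition(lab))
  expect_true(all(done$labels == 1L))

  # two point seeds: split at the midline, tie to the smaller label
  lab2 <- matrix(0L, 1, 11); lab2[1, 1] <- 1L; lab2[1, 11] <- 2L
  done2 <- complete_partition(focusfuse:::new_partition(lab2))
  expect_equal(as.vector(done2$labels), c(rep(1L, 6), rep(2L, 5)))

  # brute-force nearest-seed oracle on random seeds
  set.seed(14)
  lab3 <- matrix(0L, 20, 25)
  seeds <- cbind(sample(20, 5), sample(25, 5))
  for (s in 1:5) lab3[seeds[s, 1], seeds[s, 2]] <- s
  done3 <- complete_partition(focusfuse:::new_partition(lab3))
  for (r in seq_len(20)) for (c in seq_len(25)) {
    d2 <- (seeds[, 1] - r)^2 + (seeds[, 2] - c)^2
    expect_identical(done3$labels[r, c],
                     as.integer(which(d2 == min(d2))[1]))
  }

  # an already-total partition is unchanged
  expect_identical(complete_partition(done3)$labels, done3$labels)
})

test_that("masked-out regions contribute zero sharpness", {
  sc <- make_scene("two_plane", H = 60, W = 60, N = 6, seed = 9)
  rs <- render_stack(sc)
  mask <- matrix(FALSE, 60, 60); mask[, 1:30] <- TRUE
  masked <- rs$stack
  masked$frames <- lapply(masked$frames, function(f) { f[!mask] <- 0; f })
  g <- segment_blocks(60, 60, 15, 15)
  s <- sharpness_tensor(masked, g, "proposed")
  expect_true(all(s[, , 3:4] == 0))   # fully masked block columns
})

test_that("a single all-image class reproduces the plain pipeline bit-exactly", {
  sc <- make_scene("two_plane", H = 75, W = 75, N = 8, seed = 4)
  rs <- render_stack(sc)
  params <- fusion_params()
  base <- fuse(rs$stack, params)
  part <- focusfuse:::new_partition(matrix(1L, 75, 75), block_size = 15L)
  obj <- fuse_by_objects(rs$stack, params, part)
  expect_identical(obj$fused_raw, base$fused_raw)
  expect_identical(strip_attrs(obj$pix), strip_attrs(base$pix))
  expect_identical(obj$depth_um_raw, base$depth_um_raw)
})

test_that("two objects at different depths are recovered independently", {
  # discs at opposite depths, each bright; background dark
  H <- 90; W <- 180; N <- 10
  Z <- matrix(3, H, W)
  d1 <- (row(Z) - 45)^2 + (col(Z) - 45)^2 <= 28^2
  d2 <- (row(Z) - 45)^2 + (col(Z) - 135)^2 <= 28^2
  Z[d2] <- 8
  set.seed(33)
  E <- matrix(5, H, W)
  E[d1 | d2] <- runif(sum(d1 | d2), 120, 240)
  scene <- structure(list(kind = "two_plane", H = H, W = W, N = N, Z = Z,
                          E = E, blur_rate = 1, atten_rate = 0.05,
                          noise_sd = 0, max_value = 255, seed = 33,
                          regions = list()), class = "synthetic_scene")
  rs <- render_stack(scene)
  part <- detect_objects(rs$stack, 100, method = "connected_components")
  expect_equal(part$n_labels, 2L)
  res <- fuse_by_objects(rs$stack, fusion_params(), part)
  # interior of each disc recovers its own plane
  core1 <- (row(Z) - 45)^2 + (col(Z) - 45)^2 <= 18^2
  core2 <- (row(Z) - 45)^2 + (col(Z) - 135)^2 <= 18^2
  expect_true(mean(res$pix[core1] == 3, na.rm = TRUE) > 0.95)
  expect_true(mean(res$pix[core2] == 8, na.rm = TRUE) > 0.95)
  # compositing is a partition: classes wrote disjoint, covering regions
  expect_equal(nrow(res$fused), H)
  expect_equal(sum(vapply(res$log$classes, function(cl) cl$n_pixels,
                          numeric(1))), H * W)
})
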