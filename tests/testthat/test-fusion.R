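test_that("pixel index initialization broadcasts block indices", {
  g <- segment_blocks(4, 4, 2, 2)
  d <- focusfuse:::block_depth_map(matrix(c(1L, 5L, 3L, 7L), 2, 2), 8)
  pix <- init_pixel_index(d, g)
  expect_equal(pix, matrix(c(1L, 1L, 5L, 5L,
                             1L, 1L, 5L, 5L,
                             3L, 3L, 7L, 7L,
                             3L, 3L, 7L, 7L), 4, 4))
  # void propagation
  d[2, 1] <- NA_integer_
  expect_true(all(is.na(init_pixel_index(d, g)[3:4, 1:2])))
  # per-pixel lookup oracle on a random map
  set.seed(6)
  g2 <- segment_blocks(23, 17, 5, 4)
  d2 <- focusfuse:::block_depth_map(
    matrix(sample(1:9, g2$J * g2$K, replace = TRUE), g2$J, g2$K), 9)
  pix2 <- init_pixel_index(d2, g2)
  for (r in seq_len(23)) for (c in seq_len(17))
    expect_identical(pix2[r, c], d2[ceiling(r / 5), ceiling(c / 4)])
})

# Two 4x4 blocks side by side with controllable frame values; frame indices
# deliberately far apart so the pair guard is exercised with the defaults.
filling_fixture <- function(v_lo = 50, v_hi = 120, i1 = 1L, i2 = 21L) {
  frames <- lapply(1:21, function(i) matrix(0, 4, 8))
  frames[[i1]] <- matrix(v_lo, 4, 8)
  frames[[i2]] <- matrix(v_hi, 4, 8)
  stack <- focus_stack(frames)
  grid <- segment_blocks(4, 8, 4, 4)
  depth <- focusfuse:::block_depth_map(matrix(c(i1, i2), 1, 2), 21)
  conf <- matrix(1L, 1, 2)
  list(stack = stack, grid = grid, depth = depth, conf = conf,
       pix = init_pixel_index(depth, grid))
}

test_that("information filling reassigns dim pixels to the brighter side", {
  f <- filling_fixture(v_lo = 50, v_hi = 120)
  out <- information_filling(f$stack, f$pix, f$depth, f$conf,
                             fusion_params(), f$grid)
  expect_true(all(out[, 1:4] == 21L))        # 50 < 80 and 50 < 120: switch
  expect_true(all(out[, 5:8] == 21L))        # 120 >= threshold4: stays
  expect_equal(attr(out, "n_refilled"), 16L)
})

test_that("information filling honours the brightness guard and pair guard", {
  # current-source value at threshold4: never reassigned
  f <- filling_fixture(v_lo = 90, v_hi = 200)
  out <- information_filling(f$stack, f$pix, f$depth, f$conf,
                             fusion_params(), f$grid)
  expect_identical(strip_attrs(out), strip_attrs(f$pix))
  # index gap at threshold3: pair skipped entirely
  f2 <- filling_fixture(v_lo = 10, v_hi = 200, i1 = 6L, i2 = 11L)
  out2 <- information_filling(f2$stack, f2$pix, f2$depth, f2$conf,
                              fusion_params(), f2$grid)
  expect_identical(strip_attrs(out2), strip_attrs(f2$pix))
})

test_that("filling never touches a pixel at or above threshold4", {
  # strong attenuation so misassigned pixels are dim in their wrong frame
  sc <- make_scene("two_plane", H = 105, W = 105, N = 24, seed = 13,
                   align = 7, atten_rate = 0.2)
  rs <- render_stack(sc)
  p <- fusion_params()
  g <- segment_blocks(105, 105, 15, 15)
  depth <- rough_depth(sharpness_tensor(rs$stack, g))
  conf <- confidence_map(rs$stack, g, depth, p$threshold0)
  pix0 <- init_pixel_index(depth, g)
  pix1 <- information_filling(rs$stack, pix0, depth, conf, p, g)
  changed <- which(pix0 != pix1)
  expect_gt(length(changed), 0)
  for (q in changed)   # value in the frame it LEFT must have been below t4
    expect_lt(rs$stack$frames[[pix0[q]]][q], p$threshold4)
})

test_that("filling does not increase disagreement with per-pixel truth", {
  # object boundary inside a block: depth step at a non-multiple of 15
  sc <- make_scene("two_plane", H = 105, W = 105, N = 24, seed = 17,
                   align = 7, atten_rate = 0.2)
  rs <- render_stack(sc)
  g <- segment_blocks(105, 105, 15, 15)
  depth <- rough_depth(sharpness_tensor(rs$stack, g))
  conf <- confidence_map(rs$stack, g, depth, 60)
  pix0 <- init_pixel_index(depth, g)
  pix1 <- information_filling(rs$stack, pix0, depth, conf, fusion_params(), g)
  expect_lte(sum(pix1 != sc$Z), sum(pix0 != sc$Z))
})

test_that("fused image copies pixels from the indexed frames", {
  one <- focus_stack(list(matrix(runif(64, 0, 255), 8)))
  pix1 <- matrix(1L, 8, 8)
  expect_equal(assemble_fused(one, pix1), one$frames[[1]])

  stk <- random_stack(8, 8, 2, seed = 21)
  chk <- matrix(rep_len(c(1L, 2L), 64), 8, 8)
  fused <- assemble_fused(stk, chk)
  for (p in seq_len(64))
    expect_identical(fused[p], stk$frames[[chk[p]]][p])

  expect_equal(assemble_fused(stk, matrix(NA_integer_, 8, 8)), matrix(0, 8, 8))
})

test_that("seam smoothing is the identity for sigma 0 or uniform maps", {
  stk <- random_stack(30, 30, 3, seed = 23)
  g <- segment_blocks(30, 30, 10, 10)
  pix <- init_pixel_index(
    focusfuse:::block_depth_map(matrix(sample(1:3, 9, TRUE), 3, 3), 3), g)
  fused <- assemble_fused(stk, pix)
  s0 <- smooth_edges(fused, pix, g, sigma = 0)
  expect_identical(s0$fused, fused)
  uni <- matrix(2L, 30, 30)
  s1 <- smooth_edges(stk$frames[[2]], uni, g, sigma = 1.5)
  expect_identical(s1$fused, stk$frames[[2]])
  expect_false(any(s1$band))
})

test_that("smoothing pulls seam values strictly between the two levels", {
  lo <- 40; hi <- 200
  stk <- focus_stack(list(matrix(lo, 20, 20), matrix(hi, 20, 20)))
  g <- segment_blocks(20, 20, 10, 10)
  pix <- init_pixel_index(
    focusfuse:::block_depth_map(matrix(c(1L, 1L, 2L, 2L), 2, 2), 2), g)
  fused <- assemble_fused(stk, pix)
  sm <- smooth_edges(fused, pix, g, sigma = 1)
  band <- sm$band
  expect_true(any(band))
  expect_true(all(sm$fused[band] > lo & sm$fused[band] < hi))
  expect_identical(sm$fused[!band], fused[!band])
})

test_that("index-to-depth is the affine plane spacing map with void at 0", {
  pix <- matrix(4L, 2, 2)   # 4th frame = 3 steps above z0
  expect_equal(index_to_depth(pix, z0 = 10, z_step = 2), matrix(16, 2, 2))
  pix[1, 1] <- NA_integer_
  d <- index_to_depth(pix, 10, 2)
  expect_equal(d[1, 1], 0)
  expect_equal(index_to_depth(pix, 7, 0)[2, 2], 7)
  expect_error(index_to_depth(pix, NULL, NULL), "z metadata")
})

test_that("a stack of identical frames fuses to that frame", {
  fr <- matrix(runif(900, 61, 255), 30)
  stk <- focus_stack(list(fr, fr, fr))
  res <- fuse(stk, fusion_params(block_h = 10, block_w = 10))
  expect_equal(res$fused_raw, fr)
  expect_equal(res$fused[!is.na(res$pix)], fr[!is.na(res$pix)])
  expect_true(all(res$pix == 1L))   # indistinguishable planes: first frame
})

test_that("an all-blocking confidence threshold yields an all-void result", {
  stk <- random_stack(20, 20, 3, max_value = 255, seed = 31)
  res <- fuse(stk, fusion_params(block_h = 10, block_w = 10,
                                 threshold0 = 255))
  expect_true(all(is.na(res$pix)))
  expect_equal(res$fused, matrix(0, 20, 20))
  expect_equal(res$log$n_void, 4L)
})

test_that("pre-smoothing pixels are bit-copies of their source frames", {
  sc <- make_scene("staircase", H = 60, W = 60, N = 8, seed = 19)
  rs <- render_stack(sc)
  res <- fuse(rs$stack, fusion_params(block_h = 10, block_w = 10))
  idx <- which(!is.na(res$pix))
  expect_gt(length(idx), 0)
  for (q in idx)
    expect_identical(res$fused_raw[q], rs$stack$frames[[res$pix[q]]][q])
})
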