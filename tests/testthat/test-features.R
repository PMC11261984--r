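test_that("encode_view stacks one feature map per slice", {
  v <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  t <- tomogram(v)
  enc <- mock_encoder(stride = 4L)
  ev <- encode_view(t, "z", enc)
  expect_identical(dim(ev$feats), c(4L, 2L, 2L, enc$n_channels))

  const <- encode_view(tomogram(array(1, c(4, 8, 8))), "z", enc)
  expect_true(all(const$feats == 0))
})

test_that("align-corners bilinear upsampling matches hand-computed values", {
  # 2x2 map [[0,1],[0,1]] to 2x4: rows become 0, 1/3, 2/3, 1
  view <- list(feats = array(0, c(2, 2, 2, 1)), stride = 2L, axis = "z")
  view$feats[1, , , 1] <- matrix(c(0, 0, 1, 1), 2, 2)   # rows (0, 1)
  view$feats[2, , , 1] <- matrix(c(0, 0, 1, 1), 2, 2)
  up <- upsample_view(view, c(2L, 2L, 4L))
  expect_equal(up[1, 1, , 1], c(0, 1 / 3, 2 / 3, 1))
  expect_equal(up[1, 2, , 1], c(0, 1 / 3, 2 / 3, 1))

  # identity when feature resolution equals the target
  view2 <- list(feats = array(rnorm(3 * 5 * 6), c(3, 5, 6, 1)),
                stride = 1L, axis = "z")
  expect_equal(upsample_view(view2, c(3L, 5L, 6L)), view2$feats)

  # constant maps stay constant
  view3 <- list(feats = array(2.5, c(3, 2, 2, 1)), stride = 4L, axis = "z")
  expect_true(all(abs(upsample_view(view3, c(3L, 7L, 9L)) - 2.5) < 1e-12))

  # stacking-axis mismatch is an error
  expect_error(upsample_view(view3, c(4L, 7L, 9L)), "stacking axis")
})

test_that("build_feature_volume concatenates [Z, Y, X] at aligned voxels", {
  d <- c(3L, 4L, 5L)
  za <- array(1, c(d, 2L)); ya <- array(2, c(d, 2L)); xa <- array(3, c(d, 2L))
  fv <- build_feature_volume(za, ya, xa)
  expect_identical(dim(fv$feats), c(d, 6L))
  expect_equal(fv$feats[2, 3, 4, ], c(1, 1, 2, 2, 3, 3))
  expect_equal(fv$block_channels, 2L)
  expect_error(build_feature_volume(za, ya, array(0, c(d, 3L))), "mismatch")

  # single-channel blocks give a 3-channel volume
  fv1 <- build_feature_volume(array(1, c(d, 1L)), array(2, c(d, 1L)),
                              array(3, c(d, 1L)))
  expect_identical(dim(fv1$feats)[4], 3L)
})

test_that("tri-view alignment: each view's feature lands at the same voxel", {
  # volume with one hot voxel; encode with stride 1 (features = pixels)
  v <- array(0, c(6, 6, 6)); v[2, 3, 4] <- 1
  enc <- mock_encoder(stride = 1L, lags = integer(0),
                      channel_weights = c(1, 1, 1))
  fv <- encode_feature_volume(tomogram(v), enc,
                              normalize_percentiles = c(0, 100))
  # the mean channel of every view block must peak at voxel (2,3,4)
  for (block in 0:2) {
    ch <- fv$feats[, , , block * 3 + 1]
    expect_identical(which(ch == max(ch), arr.ind = TRUE)[1, ],
                     c(dim1 = 2L, dim2 = 3L, dim3 = 4L))
  }
})

test_that("pyramid pooling equals the explicit block-mean oracle", {
  set.seed(11)
  feats <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  fv <- structure(list(feats = feats, block_channels = 2L),
                  class = "feature_volume")
  lv <- build_pyramid(fv, ratios = 2L)[[1]]
  expect_equal(lv$feats, oracle_block_mean(feats, 2L))

  # ragged extents: partial edge cells average their actual extent
  feats2 <- array(rnorm(7 * 9 * 5 * 2), c(7, 9, 5, 2))
  fv2 <- structure(list(feats = feats2, block_channels = 2L),
                   class = "feature_volume")
  lv2 <- build_pyramid(fv2, ratios = 4L)[[1]]
  expect_identical(dim(lv2$feats), c(2L, 3L, 2L, 2L))
  expect_equal(lv2$feats, oracle_block_mean(feats2, 4L))
})

test_that("single hot cell pools to its exact block average", {
  feats <- array(0, c(4, 4, 4, 1)); feats[1, 1, 1, 1] <- 64
  fv <- structure(list(feats = feats, block_channels = 1L),
                  class = "feature_volume")
  lv <- build_pyramid(fv, ratios = 4L)[[1]]
  expect_equal(as.vector(lv$feats), 1.0)
})

test_that("pooling conserves the volume-weighted mean feature at every level", {
  set.seed(5)
  feats <- array(rnorm(12 * 10 * 8 * 3), c(12, 10, 8, 3))
  fv <- structure(list(feats = feats, block_channels = 3L),
                  class = "feature_volume")
  full_mean <- apply(feats, 4, mean)
  for (lv in build_pyramid(fv, ratios = c(4L, 2L))) {
    d <- dim(lv$feats)
    # cell volume = product of actual extents covered by the cell
    w <- outer(outer(tabulate(ceiling(seq_len(12) / lv$ratio)),
                     tabulate(ceiling(seq_len(10) / lv$ratio))),
               tabulate(ceiling(seq_len(8) / lv$ratio)))
    for (ch in 1:3) {
      expect_equal(sum(lv$feats[, , , ch] * w) / sum(w), full_mean[ch])
    }
  }
})

test_that("constant volumes give constant pyramids and ratio validation holds", {
  fv <- structure(list(feats = array(3, c(8, 8, 8, 2)), block_channels = 2L),
                  class = "feature_volume")
  for (lv in build_pyramid(fv, ratios = c(4L, 2L))) {
    expect_true(all(lv$feats == 3))
  }
  expect_error(build_pyramid(fv, ratios = c(2L, 4L)), "strictly decreasing")
  expect_error(build_pyramid(fv, ratios = integer(0)), "positive")
})

test_that("axis permutation of the volume permutes the feature volume consistently", {
  set.seed(9)
  v <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  enc <- mock_encoder(stride = 2L)
  f1 <- encode_feature_volume(tomogram(v), enc)
  f2 <- encode_feature_volume(tomogram(aperm(v, c(2, 1, 3))), enc)
  C <- enc$n_channels
  # swapping z and y swaps the roles of the Z and Y view blocks
  z1 <- f1$feats[, , , 1:C]; y1 <- f1$feats[, , , (C + 1):(2 * C)]
  x1 <- f1$feats[, , , (2 * C + 1):(3 * C)]
  z2 <- f2$feats[, , , 1:C]; y2 <- f2$feats[, , , (C + 1):(2 * C)]
  x2 <- f2$feats[, , , (2 * C + 1):(3 * C)]
  expect_equal(z2, aperm(y1, c(2, 1, 3, 4)))
  expect_equal(y2, aperm(z1, c(2, 1, 3, 4)))
  expect_equal(x2, aperm(x1, c(2, 1, 3, 4)))
})

test_that("cell centers map into the volume and land mid-block", {
  expect_equal(cell_center(1L, 16L, 96L), 9L)
  expect_equal(cell_center(6L, 16L, 96L), 89L)
  expect_equal(cell_center(3L, 4L, 10L), 10L)   # clipped partial edge cell
  expect_true(all(cell_center(1:24, 4L, 96L) <= 96L))
})
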