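random_feature_volume <- function(d, channels = 6L) {
  structure(list(feats = array(rnorm(prod(d) * channels), c(d, channels)),
                 block_channels = channels / 3L),
            class = "feature_volume")
}

test_that("masked average pooling matches analytic examples", {
  d <- c(4L, 4L, 4L)
  fv <- random_feature_volume(d, 2L)

  m <- array(FALSE, d); m[2, 3, 1] <- TRUE
  q <- masked_average_pool(fv, list(m))
  expect_equal(q$vector, fv$feats[2, 3, 1, ])
  expect_equal(q$n_voxels, 1L)

  # constant field: any masks pool to the constant
  fvc <- structure(list(feats = array(rep(c(2, -1), each = prod(d)),
                                      c(d, 2L)), block_channels = 1L),
                   class = "feature_volume")
  m2 <- array(runif(prod(d)) > 0.5, d); m2[1, 1, 1] <- TRUE
  expect_equal(masked_average_pool(fvc, list(m2))$vector, c(2, -1))

  # two single-voxel masks over orthogonal features average to the midpoint
  fv2 <- structure(list(feats = array(0, c(2, 1, 1, 2)), block_channels = 1L),
                   class = "feature_volume")
  fv2$feats[1, 1, 1, ] <- c(1, 0); fv2$feats[2, 1, 1, ] <- c(0, 1)
  ma <- array(c(TRUE, FALSE), c(2, 1, 1)); mb <- array(c(FALSE, TRUE), c(2, 1, 1))
  q2 <- masked_average_pool(fv2, list(ma, mb))
  expect_equal(q2$vector, c(0.5, 0.5))
  expect_equal(q2$n_voxels, 2L)

  # per the MAP formula, a voxel in several masks counts once per mask
  q3 <- masked_average_pool(fv2, list(ma, ma, mb))
  expect_equal(q3$vector, c(2, 1) / 3)

  expect_error(masked_average_pool(fv, list(array(FALSE, d))), "empty")
})

test_that("cosine similarity matches analytic values and conventions", {
  lv <- structure(list(ratio = 1L,
                       feats = array(0, c(3, 1, 1, 2)),
                       full_dim = c(3L, 1L, 1L)),
                  class = "feature_pyramid_level")
  lv$feats[1, 1, 1, ] <- c(1, 1)      # equal to query
  lv$feats[2, 1, 1, ] <- c(0, 0)      # zero feature: scores 0 by convention
  lv$feats[3, 1, 1, ] <- c(1, 0)      # 45 degrees
  s <- cosine_similarity_level(c(1, 1), lv)
  expect_equal(as.vector(s$scores), c(1, 0, 1 / sqrt(2)))
  expect_equal(s$n_evaluated, 3L)

  # orthogonal feature scores 0
  lv$feats[3, 1, 1, ] <- c(1, -1)
  expect_equal(cosine_similarity_level(c(1, 1), lv)$scores[3, 1, 1], 0)

  expect_error(cosine_similarity_level(c(0, 0), lv), "zero query")

  # evaluation restricted by a mask leaves the rest unevaluated
  em <- array(c(TRUE, FALSE, FALSE), c(3, 1, 1))
  s2 <- cosine_similarity_level(c(1, 1), lv, em)
  expect_equal(s2$n_evaluated, 1L)
  expect_true(is.na(s2$scores[2, 1, 1]))
})

test_that("keep-mask propagation follows nearest-neighbor block parentage", {
  keep <- array(TRUE, c(2, 2, 2))
  expect_true(all(propagate_keep_mask(keep, 16L, 8L, c(4L, 4L, 4L))))

  keep <- array(FALSE, c(2, 2, 2)); keep[1, 2, 1] <- TRUE
  ev <- propagate_keep_mask(keep, 16L, 8L, c(4L, 4L, 4L))
  expect_equal(sum(ev), 8L)
  expect_true(all(ev[1:2, 3:4, 1:2]))

  expect_false(any(propagate_keep_mask(array(FALSE, c(2, 2, 2)), 16L, 8L,
                                       c(4L, 4L, 4L))))
  expect_error(propagate_keep_mask(keep, 16L, 5L, c(4L, 4L, 4L)),
               "ratio mismatch")
})

test_that("hierarchical matching with filtering disabled equals full evaluation", {
  set.seed(21)
  for (rep in 1:3) {
    d <- sample(8:24, 3, replace = TRUE)
    fv <- random_feature_volume(d)
    pyr <- build_pyramid(fv, ratios = c(8L, 4L, 2L))
    q <- structure(list(vector = rnorm(6), n_voxels = 1L),
                   class = "query_feature")
    hm <- hierarchical_match(pyr, q, tau_sim = -1)
    full <- cosine_similarity_level(q, pyr[[3]])
    expect_equal(hm$similarity$scores, full$scores)
    expect_equal(hm$n_evaluations,
                 sum(vapply(pyr, function(l) prod(dim(l$feats)[1:3]),
                            numeric(1))))
  }
})

test_that("hierarchical matching at ratio 1 reproduces naive matching", {
  set.seed(22)
  d <- c(10L, 9L, 8L)
  fv <- random_feature_volume(d)
  q <- structure(list(vector = rnorm(6), n_voxels = 1L),
                 class = "query_feature")
  pyr <- build_pyramid(fv, ratios = 1L)
  hm <- hierarchical_match(pyr, q, tau_sim = -1)
  expect_equal(hm$similarity$scores, naive_match(fv, q))
  # and both agree with the explicit-loop oracle
  expect_equal(naive_match(fv, q), oracle_full_cosine(fv$feats, q$vector))
})

test_that("naive matching: constant field scores 1, single match is the argmax", {
  d <- c(5L, 5L, 5L)
  q <- c(1, 2, 3)
  feats <- array(rep(q, each = prod(d)), c(d, 3L))
  fv <- structure(list(feats = feats, block_channels = 1L),
                  class = "feature_volume")
  expect_true(all(abs(naive_match(fv, q) - 1) < 1e-12))

  feats2 <- array(0, c(d, 3L))
  feats2[, , , 1] <- 1                        # orthogonal background
  feats2[3, 4, 2, ] <- c(0, 1, 1)             # the planted match
  fv2 <- structure(list(feats = feats2, block_channels = 1L),
                   class = "feature_volume")
  s <- naive_match(fv2, c(0, 1, 1))
  expect_identical(which(s == max(s), arr.ind = TRUE)[1, ],
                   c(dim1 = 3L, dim2 = 4L, dim3 = 2L))
  expect_error(naive_match(fv2, c(0, 0, 0)), "zero query")
})

test_that("a planted matching block is found through the coarse-to-fine filter", {
  set.seed(23)
  d <- c(32L, 32L, 32L)
  q <- c(0, -1, 2, 0.5, -2, 1)    # orthogonal to the background direction
  feats <- array(rnorm(prod(d) * 6, 0, 0.05), c(d, 6L))
  feats[, , , 1] <- feats[, , , 1] + 1        # near-orthogonal background
  block <- list(9:16, 17:24, 9:16)
  for (ch in 1:6) {
    feats[block[[1]], block[[2]], block[[3]], ch] <- q[ch]
  }
  fv <- structure(list(feats = feats, block_channels = 2L),
                  class = "feature_volume")
  pyr <- build_pyramid(fv, ratios = c(8L, 4L, 2L))
  hm <- hierarchical_match(pyr, q, tau_sim = 0.5)
  sc <- hm$similarity$scores
  best <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  centers <- vapply(1:3, function(a) cell_center(best[a], 2L, d[a]), integer(1))
  for (a in 1:3) expect_true(centers[a] %in% block[[a]])
  # the full-evaluation oracle agrees on the argmax cell's score
  full <- oracle_full_cosine(pyr[[3]]$feats, q)
  expect_equal(max(sc, na.rm = TRUE), max(full))
  # and filtering did substantially fewer evaluations than full evaluation
  expect_lt(hm$n_evaluations, 0.5 * prod(dim(pyr[[3]]$feats)[1:3]))
})

test_that("an empty coarsest keep-mask falls back to the best cell", {
  d <- c(8L, 8L, 8L)
  feats <- array(0, c(d, 3L)); feats[, , , 1] <- 1
  fv <- structure(list(feats = feats, block_channels = 1L),
                  class = "feature_volume")
  pyr <- build_pyramid(fv, ratios = c(4L, 2L))
  w <- capture_warnings(hm <- hierarchical_match(pyr, c(0, 1, 0),
                                                 tau_sim = 0.5))
  expect_true(length(w) >= 1 && all(grepl("falling back", w)))
  expect_gte(sum(!is.na(hm$similarity$scores)), 1L)
})

test_that("NMS keeps the stronger of two close cells and respects K", {
  sim <- structure(list(
    scores = array(NA_real_, c(1, 1, 5)), evaluated = array(FALSE, c(1, 1, 5)),
    ratio = 1L, full_dim = c(1L, 1L, 5L),
    keep = array(FALSE, c(1, 1, 5))), class = "similarity_level")
  sim$scores[1, 1, 2] <- 0.9; sim$scores[1, 1, 3] <- 0.8
  sim$keep[1, 1, 2:3] <- TRUE
  out <- nms_top_k(sim, radius = 2, k = 10L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$x, 2L)
  expect_equal(out$score, 0.9)

  # K caps the number of proposals
  sim$keep[1, 1, ] <- TRUE
  sim$scores[1, 1, ] <- c(0.5, 0.9, 0.8, 0.7, 0.6)
  out2 <- nms_top_k(sim, radius = 0.5, k = 2L)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$score, c(0.9, 0.8))

  # empty candidate set gives an empty proposal set
  sim$keep[1, 1, ] <- FALSE
  expect_equal(nrow(nms_top_k(sim, radius = 1, k = 5L)), 0L)
})

test_that("NMS on a 5x5 score grid matches the exhaustive suppression oracle", {
  set.seed(31)
  scores <- array(NA_real_, c(1, 5, 5))
  scores[1, , ] <- matrix(round(runif(25), 3), 5, 5)
  sim <- structure(list(scores = scores, evaluated = array(TRUE, c(1, 5, 5)),
                        ratio = 1L, full_dim = c(1L, 5L, 5L),
                        keep = array(TRUE, c(1, 5, 5))),
                   class = "similarity_level")
  out <- nms_top_k(sim, radius = 2, k = 3L)

  coords <- which(sim$keep, arr.ind = TRUE)
  oracle <- oracle_nms(coords, scores[sim$keep], radius = 2, k = 3L)
  expect_equal(nrow(out), nrow(oracle))
  expect_equal(cbind(out$z, out$y, out$x), unname(oracle[, 1:3, drop = FALSE]))
  expect_equal(out$score, unname(oracle[, 4]))
})

test_that("NMS proposals always satisfy the pairwise distance invariant", {
  set.seed(32)
  for (rep in 1:10) {
    d <- sample(4:10, 3, replace = TRUE)
    scores <- array(runif(prod(d)), d)
    keep <- array(runif(prod(d)) > 0.4, d)
    sim <- structure(list(scores = scores, evaluated = array(TRUE, d),
                          ratio = 2L, full_dim = 2L * d, keep = keep),
                     class = "similarity_level")
    radius <- runif(1, 1, 6)
    out <- nms_top_k(sim, radius, k = 7L)
    expect_lte(nrow(out), 7L)
    if (nrow(out) > 1) {
      dm <- as.matrix(stats::dist(cbind(out$z, out$y, out$x)))
      expect_true(all(dm[upper.tri(dm)] >= radius))
    }
    expect_true(all(diff(out$score) <= 0))
  }
})
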