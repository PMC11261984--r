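# Fixtures built in code, plus slow independent oracles used by the
# [DERIVED] example tests. Oracles are deliberately naive (explicit loops,
# queues, exhaustive enumeration) and never share code with the package
# internals they check.

render_disk <- function(nr, nc, center, radius, value = 1, background = 0) {
  img <- matrix(background, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) img[r, c] <- value
    }
  }
  img
}

disk_pixel_count <- function(nr, nc, center, radius) {
  sum(render_disk(nr, nc, center, radius) > 0)
}

# Noiseless single-sphere scene (smooth profile, hard support at `radius`).
sphere_scene <- function(radius = 8, dim = 48L, seed = 1L) {
  generate_scene(scene_params(
    dim = rep(as.integer(dim), 3L),
    classes = data.frame(label = "S", count = 1L, r_min = radius,
                         r_max = radius, contrast = 3,
                         texture_period = 0, texture_amp = 0),
    noise_sigma = 0, min_separation = 1), seed = seed)
}

dense_mask <- function(scene, i) cryoprompt:::scene_mask_volume(scene, i)

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Queue-based flood fill, 4-connectivity: the oracle for mock_segment.
oracle_flood_fill <- function(support, seed) {
  out <- matrix(FALSE, nrow(support), ncol(support))
  if (!support[seed[1], seed[2]]) return(out)
  queue <- list(seed)
  out[seed[1], seed[2]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(support) && q[2] >= 1 &&
          q[2] <= ncol(support) && support[q[1], q[2]] && !out[q[1], q[2]]) {
        out[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  out
}

# Explicit-loop cosine similarity over every cell of a feature array.
oracle_full_cosine <- function(feats, q) {
  d <- dim(feats)
  out <- array(NA_real_, d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    f <- feats[i, j, k, ]
    nf <- sqrt(sum(f^2))
    out[i, j, k] <- if (nf == 0) 0 else
      sum(f * q) / (nf * sqrt(sum(q^2)))
  }
  out
}

# Explicit-loop block-mean pooling oracle.
oracle_block_mean <- function(feats, r) {
  d <- dim(feats)
  g <- ceiling(d[1:3] / r)
  out <- array(0, c(g, d[4]))
  for (i in seq_len(g[1])) for (j in seq_len(g[2])) for (k in seq_len(g[3])) {
    zz <- ((i - 1) * r + 1):min(i * r, d[1])
    yy <- ((j - 1) * r + 1):min(j * r, d[2])
    xx <- ((k - 1) * r + 1):min(k * r, d[3])
    for (ch in seq_len(d[4])) {
      out[i, j, k, ch] <- mean(feats[zz, yy, xx, ch])
    }
  }
  out
}

# Greedy suppression oracle: repeatedly take the global max among remaining
# candidates, discard everything within `radius` of it.
oracle_nms <- function(coords, scores, radius, k) {
  taken <- NULL
  remaining <- order(-scores, coords[, 1], coords[, 2], coords[, 3])
  while (length(remaining) > 0 && (is.null(taken) || nrow(taken) < k)) {
    i <- remaining[1]
    taken <- rbind(taken, c(coords[i, ], scores[i]))
    d2 <- (coords[remaining, 1] - coords[i, 1])^2 +
      (coords[remaining, 2] - coords[i, 2])^2 +
      (coords[remaining, 3] - coords[i, 3])^2
    remaining <- remaining[d2 >= radius^2]
  }
  taken
}

# Exhaustive optimal one-to-one assignment: maximum number of pred-truth
# pairs within tolerance (brute force over all injective assignments).
oracle_max_matching <- function(pred, truth, tol) {
  np <- nrow(pred); nt <- nrow(truth)
  within <- matrix(FALSE, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    within[i, j] <- sqrt(sum((unlist(pred[i, c("z", "y", "x")]) -
                              unlist(truth[j, c("z", "y", "x")]))^2)) <= tol
  }
  best <- 0
  recurse <- function(i, used) {
    if (i > np) return(0)
    res <- recurse(i + 1, used)          # leave pred i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && within[i, j]) {
        used2 <- used; used2[j] <- TRUE
        res <- max(res, 1 + recurse(i + 1, used2))
      }
    }
    res
  }
  if (nt == 0) return(0)
  recurse(1, rep(FALSE, nt))
}

# Small cached standard-preset scene shared by the heavier tests.
standard_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_scene(scene_preset("standard"),
                                                 seed = 0L)
    cache
  }
})
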