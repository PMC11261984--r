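# Promptable-segmenter and slice-encoder backends.
#
# The pipeline only ever talks to two operations: promptable_segment() and
# encode_slice(). The mock backends below implement them as deterministic
# pure functions so every algorithmic stage is testable without
# foundation-model weights; foundation_segmenter()/foundation_encoder() are
# adapter slots for a promptable-segmentation model and a self-supervised
# ViT encoder, selected by name but never exercised in the test suite.

# ---- 2D morphology primitives (4-connectivity) -----------------------------

shift_pad <- function(m, dr, dc) {
  # shift logical matrix by (dr, dc), padding FALSE
  n <- nrow(m); k <- ncol(m)
  out <- matrix(FALSE, n, k)
  rs <- seq_len(n) - dr; cs <- seq_len(k) - dc
  ok_r <- rs >= 1L & rs <= n; ok_c <- cs >= 1L & cs <= k
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate4 <- function(m) {
  m | shift_pad(m, 1L, 0L) | shift_pad(m, -1L, 0L) |
    shift_pad(m, 0L, 1L) | shift_pad(m, 0L, -1L)
}

erode4 <- function(m) {
  m & shift_pad(m, 1L, 0L) & shift_pad(m, -1L, 0L) &
    shift_pad(m, 0L, 1L) & shift_pad(m, 0L, -1L)
}

# Pixel-wise median of a 3x3 neighborhood (replicated borders), via a
# 19-comparator median network on the 9 shifted copies; edge-preserving
# noise reduction for the mock segmenter's support.
median_filter3 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  rr <- function(dr) pmin(pmax(seq_len(n) + dr, 1L), n)
  cc <- function(dc) pmin(pmax(seq_len(m) + dc, 1L), m)
  v <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    v[[k]] <- img[rr(dr), cc(dc), drop = FALSE]
  }
  cmp <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # Paeth's median-of-9 sorting network; the median ends in v[[5]]
  cmp(2,3); cmp(5,6); cmp(8,9); cmp(1,2); cmp(4,5); cmp(7,8)
  cmp(2,3); cmp(5,6); cmp(8,9); cmp(1,4); cmp(6,9); cmp(5,8)
  cmp(4,7); cmp(2,5); cmp(3,6); cmp(5,8); cmp(3,5); cmp(7,5); cmp(3,5)
  v[[5]]
}

# Above-threshold support: robust threshold on the raw slice unioned with a
# robust threshold on its 3x3 median-filtered version. On noiseless input the
# filtered branch adds nothing (median filtering preserves flat regions and
# straight edges); on noisy input it restores the connectivity that
# pixel-wise thresholding destroys.
segment_support <- function(img, k_mad) {
  noise_scale <- stats::mad(img)
  sup <- img > stats::median(img) + k_mad * noise_scale
  if (noise_scale == 0) return(sup)   # clean slice: pixel threshold is exact
  f <- median_filter3(img)
  sup | (f > stats::median(f) + k_mad * stats::mad(f))
}

# Grow the 4-connected component of `support` containing `seed` (r, c).
flood_fill4 <- function(support, seed) {
  comp <- matrix(FALSE, nrow(support), ncol(support))
  if (!support[seed[1], seed[2]]) return(comp)
  comp[seed[1], seed[2]] <- TRUE
  n_prev <- 1L
  repeat {
    comp <- dilate4(comp) & support
    n <- sum(comp)
    if (n == n_prev) return(comp)
    n_prev <- n
  }
}

# 4-connected distance-to-boundary (in erosion steps); 0 outside the mask.
boundary_distance <- function(mask) {
  d <- matrix(0, nrow(mask), ncol(mask))
  cur <- mask
  k <- 0
  while (any(cur)) {
    k <- k + 1
    d[cur] <- k
    cur <- erode4(cur)
  }
  d
}

# Lexicographic argmax: smallest row, then smallest column, among maxima.
peak_coordinate <- function(conf) {
  idx <- which(conf == max(conf), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  as.integer(idx[1, ])
}

segmentation_result <- function(mask2d, confidence) {
  structure(list(mask2d = mask2d, confidence = confidence,
                 peak = peak_coordinate(confidence)),
            class = "segmentation_result")
}

# ---- segmenter backends ----------------------------------------------------

#' Mock promptable segmenter
#'
#' A deterministic stand-in for a promptable 2D segmentation model. Its
#' above-threshold support is the union of a robust threshold
#' (median + `k_mad` * MAD) on the raw slice and the same robust threshold on
#' its 3x3 median-filtered version; the filtered branch is a no-op on clean
#' input but restores the connectivity that pixel-wise thresholding loses on
#' noisy slices. The mask is region-grown (4-connectivity) from the point
#' prompt within the support, and the confidence map is the normalized
#' distance-to-boundary inside the mask (0 outside). When only a mask prompt
#' is given, the seed is the mask centroid snapped to the nearest support
#' pixel, and only a grown component that overlaps the mask prompt is
#' retained.
#'
#' @param k_mad threshold offset in MAD units above the slice median.
#' @return A segmenter backend usable with [promptable_segment()].
#' @export
mock_segmenter <- function(k_mad = 3) {
  structure(list(k_mad = k_mad), class = c("mock_segmenter", "segmenter"))
}

#' Adapter slot for a foundation promptable-segmentation model
#'
#' Placeholder constructor mirroring the interface of [mock_segmenter()];
#' plugging in actual model weights is out of scope here, so calling
#' [promptable_segment()] on it signals an error describing the adapter
#' contract.
#'
#' @param checkpoint path to model weights (never bundled).
#' @export
foundation_segmenter <- function(checkpoint = NULL) {
  structure(list(checkpoint = checkpoint),
            class = c("foundation_segmenter", "segmenter"))
}

#' Segment a slice from a point and/or mask prompt
#'
#' @param backend a segmenter backend ([mock_segmenter()] or an adapter).
#' @param img numeric matrix (a normalized slice).
#' @param point optional pixel coordinate `c(row, col)`, 1-based.
#' @param mask_prompt optional logical matrix, same shape as `img`.
#' @return A `segmentation_result` with elements `mask2d` (logical matrix),
#'   `confidence` (numeric matrix, finite everywhere) and `peak` (the
#'   confidence argmax; ties broken by smallest row then column). An all-zero
#'   mask is a legal "nothing found" outcome.
#' @export
promptable_segment <- function(backend, img, point = NULL, mask_prompt = NULL) {
  if (is.null(point) && is.null(mask_prompt)) {
    stop("promptable_segment needs a point and/or a mask prompt",
         call. = FALSE)
  }
  if (!is.null(mask_prompt) && !identical(dim(mask_prompt), dim(img))) {
    stop("mask_prompt shape does not match image", call. = FALSE)
  }
  if (!is.null(point) &&
      (point[1] < 1 || point[1] > nrow(img) ||
       point[2] < 1 || point[2] > ncol(img))) {
    stop("point prompt outside image", call. = FALSE)
  }
  UseMethod("promptable_segment")
}

#' @export
promptable_segment.mock_segmenter <- function(backend, img, point = NULL,
                                              mask_prompt = NULL) {
  support <- segment_support(img, backend$k_mad)
  empty <- function() {
    segmentation_result(matrix(FALSE, nrow(img), ncol(img)),
                        matrix(0, nrow(img), ncol(img)))
  }
  if (!any(support)) return(empty())

  if (!is.null(point)) {
    seed <- as.integer(round(point))
    if (!support[seed[1], seed[2]]) return(empty())
    comp <- flood_fill4(support, seed)
  } else {
    if (!any(mask_prompt)) return(empty())
    idx <- which(mask_prompt, arr.ind = TRUE)
    cen <- colMeans(idx)
    sup_idx <- which(support, arr.ind = TRUE)
    d2 <- (sup_idx[, 1] - cen[1])^2 + (sup_idx[, 2] - cen[2])^2
    seed <- as.integer(sup_idx[which.min(d2), ])
    comp <- flood_fill4(support, seed)
    if (!any(comp & mask_prompt)) return(empty())
  }
  if (!any(comp)) return(empty())
  d <- boundary_distance(comp)
  segmentation_result(comp, d / max(d))
}

#' @export
promptable_segment.foundation_segmenter <- function(backend, img, point = NULL,
                                                    mask_prompt = NULL) {
  stop("foundation segmenter adapter: supply a model integration that maps ",
       "(image, point, mask) prompts to a (mask, confidence) pair; no ",
       "weights are bundled with this package", call. = FALSE)
}

# ---- encoder backends ------------------------------------------------------

#' Mock slice encoder
#'
#' A deterministic patch-statistics encoder standing in for a pretrained 2D
#' feature extractor. Each stride x stride patch yields one feature cell with
#' channels: patch mean, patch standard deviation, mean gradient magnitude,
#' and a small fixed band-pass bank. The bank is realized patch-locally:
#' lag-`d` absolute-difference responses (band-pass difference filters) are
#' averaged inside the patch for each configured lag, and the bank channels
#' are the signed contrasts between each band and the last (coarsest) band.
#' On white noise all bands respond equally, so the contrasts are centred at
#' zero; fine and coarse textures push them in opposite directions. Every
#' channel is then robust z-scored across the image's cells (median/MAD), so
#' featureless background patches map to near-zero vectors, and scaled by
#' fixed channel weights that keep the amplitude channels (shared by all
#' bright particles) from dominating the texture channels (which carry the
#' class identity) - cosine matching discriminates by feature direction.
#'
#' @param stride patch size in pixels (feature stride).
#' @param lags increasing integer lags of the band-pass bank (all < `stride`);
#'   the bank contributes `length(lags) - 1` contrast channels.
#' @param channel_weights fixed per-channel weights, length
#'   `3 + length(lags) - 1`.
#' @return An encoder backend usable with [encode_slice()].
#' @export
mock_encoder <- function(stride = 4L,
                         lags = seq_len(min(3L, stride - 1L)),
                         channel_weights = c(0.25, 0.5, 0.5,
                                             rep(2, max(length(lags) - 1L, 0L)))) {
  if (is.null(lags)) lags <- integer(0)
  n_contrast <- max(length(lags) - 1L, 0L)
  stopifnot(stride >= 1L, all(lags >= 1L), all(lags < stride),
            !is.unsorted(lags, strictly = TRUE),
            length(channel_weights) == 3L + n_contrast)
  structure(list(stride = as.integer(stride), lags = as.integer(lags),
                 channel_weights = channel_weights,
                 n_channels = 3L + n_contrast),
            class = c("mock_encoder", "encoder"))
}

#' Adapter slot for a foundation 2D feature encoder
#'
#' @param checkpoint path to encoder weights (never bundled).
#' @param stride the encoder's pixel-to-feature-cell stride.
#' @export
foundation_encoder <- function(checkpoint = NULL, stride = 14L) {
  structure(list(checkpoint = checkpoint, stride = as.integer(stride),
                 n_channels = NA_integer_),
            class = c("foundation_encoder", "encoder"))
}

# Per-patch sum of a pixel statistic, with partial edge patches.
# Returns list(sum = h x w matrix, count = h x w matrix).
patch_sums <- function(x, stride) {
  rg <- ceiling(seq_len(nrow(x)) / stride)
  cg <- ceiling(seq_len(ncol(x)) / stride)
  s <- rowsum(t(rowsum(x, rg)), cg)           # w x h
  cr <- tabulate(rg); cc <- tabulate(cg)
  list(sum = t(s), count = outer(cr, cc))
}

patch_mean_of <- function(x, stride) {
  ps <- patch_sums(x, stride)
  ps$sum / ps$count
}

# Mean absolute lag-d difference inside each patch (horizontal + vertical
# pairs pooled together); strictly patch-local.
patch_lag_absdiff <- function(img, stride, lag) {
  n <- nrow(img); m <- ncol(img)
  acc_s <- NULL; acc_n <- NULL
  add <- function(s, cnt) {
    if (is.null(acc_s)) { acc_s <<- s; acc_n <<- cnt }
    else { acc_s <<- acc_s + s; acc_n <<- acc_n + cnt }
  }
  # vertical pairs (i, i+lag) within the same row-patch
  if (n > lag) {
    i <- seq_len(n - lag)
    same <- ceiling(i / stride) == ceiling((i + lag) / stride)
    if (any(same)) {
      dv <- abs(img[i[same] + lag, , drop = FALSE] -
                img[i[same], , drop = FALSE])
      # attribute each pair to its patch row
      rg <- ceiling(i[same] / stride)
      cg <- ceiling(seq_len(m) / stride)
      s <- t(rowsum(t(rowsum(dv, rg)), cg))
      cnt <- outer(tabulate(rg, nbins = ceiling(n / stride)),
                   tabulate(cg))
      # rowsum() drops empty groups; re-expand to full patch grid
      full <- matrix(0, ceiling(n / stride), ceiling(m / stride))
      full[sort(unique(rg)), ] <- s
      add(full, cnt)
    }
  }
  # horizontal pairs
  if (m > lag) {
    j <- seq_len(m - lag)
    same <- ceiling(j / stride) == ceiling((j + lag) / stride)
    if (any(same)) {
      dh <- abs(img[, j[same] + lag, drop = FALSE] -
                img[, j[same], drop = FALSE])
      rg <- ceiling(seq_len(n) / stride)
      cg <- ceiling(j[same] / stride)
      s <- t(rowsum(t(rowsum(dh, rg)), cg))
      cnt <- outer(tabulate(rg),
                   tabulate(cg, nbins = ceiling(m / stride)))
      full <- matrix(0, ceiling(n / stride), ceiling(m / stride))
      full[, sort(unique(cg))] <- s
      add(full, cnt)
    }
  }
  if (is.null(acc_s)) {
    return(matrix(0, ceiling(n / stride), ceiling(m / stride)))
  }
  out <- acc_s
  out[acc_n > 0] <- acc_s[acc_n > 0] / acc_n[acc_n > 0]
  out
}

# Gradient magnitude by central differences (one-sided at borders).
gradient_magnitude <- function(img) {
  n <- nrow(img); m <- ncol(img)
  gr <- img * 0; gc <- img * 0
  if (n > 1) {
    gr[2:(n - 1), ] <- (img[3:n, , drop = FALSE] -
                        img[1:(n - 2), , drop = FALSE]) / 2
    gr[1, ] <- img[2, ] - img[1, ]
    gr[n, ] <- img[n, ] - img[n - 1, ]
  }
  if (m > 1) {
    gc[, 2:(m - 1)] <- (img[, 3:m, drop = FALSE] -
                        img[, 1:(m - 2), drop = FALSE]) / 2
    gc[, 1] <- img[, 2] - img[, 1]
    gc[, m] <- img[, m] - img[, m - 1]
  }
  sqrt(gr^2 + gc^2)
}

robust_zscore <- function(ch) {
  med <- stats::median(ch)
  sc <- stats::mad(ch)
  (ch - med) / (sc + 1e-8)
}

#' Encode a slice into a 2D feature map
#'
#' @param backend an encoder backend ([mock_encoder()] or an adapter).
#' @param img numeric matrix, expected normalized to `[0, 1]`
#'   (see [normalize_slice()]).
#' @return A `feature_map2d`: list with `feats` (h x w x C array, where
#'   h = ceiling(rows/stride), w = ceiling(cols/stride)) and `stride`.
#' @export
encode_slice <- function(backend, img) UseMethod("encode_slice")

#' @export
encode_slice.mock_encoder <- function(backend, img) {
  p <- backend$stride
  m1 <- patch_mean_of(img, p)
  m2 <- patch_mean_of(img^2, p)
  ch_mean <- m1
  ch_sd <- sqrt(pmax(m2 - m1^2, 0))
  ch_grad <- patch_mean_of(gradient_magnitude(img), p)
  contrasts <- list()
  if (length(backend$lags) > 1L) {
    bands <- lapply(backend$lags, function(l) patch_lag_absdiff(img, p, l))
    ref <- bands[[length(bands)]]
    contrasts <- lapply(bands[-length(bands)], function(b) b - ref)
  }
  chans <- c(list(ch_mean, ch_sd, ch_grad), contrasts)
  feats <- array(0, c(nrow(m1), ncol(m1), backend$n_channels))
  for (k in seq_along(chans)) {
    feats[, , k] <- backend$channel_weights[k] * robust_zscore(chans[[k]])
  }
  structure(list(feats = feats, stride = p), class = "feature_map2d")
}

#' @export
encode_slice.foundation_encoder <- function(backend, img) {
  stop("foundation encoder adapter: supply a model integration that maps a ",
       "normalized slice to an h x w x C feature grid at the reported ",
       "stride; no weights are bundled with this package", call. = FALSE)
}

# Backend registries: construct a backend from a config name + options.
make_segmenter <- function(name, options = list()) {
  switch(name,
         mock = do.call(mock_segmenter, options),
         foundation = do.call(foundation_segmenter, options),
         stop("unknown segmenter backend: ", name, call. = FALSE))
}

make_encoder <- function(name, options = list()) {
  switch(name,
         mock = do.call(mock_encoder, options),
         foundation = do.call(foundation_encoder, options),
         stop("unknown encoder backend: ", name, call. = FALSE))
}
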