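# Tri-view feature volume and its multi-resolution pyramid.
#
# Every slice along each of the three axes is encoded to a 2D feature map,
# bilinearly upsampled (align-corners) back to its slice's pixel grid, and
# the three stacked view blocks are concatenated channel-wise into the
# full-resolution feature volume F (D x H x W x 3C). Pyramid levels are
# r^3 block averages of F.

#' Encode every slice along one axis
#'
#' Applies [normalize_slice()] then [encode_slice()] to each slice along
#' `axis` and stacks the resulting feature maps. Slices are normalized on a
#' common volume-wide percentile scale (not per slice): per-slice percentile
#' bounds depend on how much bright content a slice happens to contain, which
#' saturates sparse-bright slices (e.g. through a particle near the volume
#' boundary) and makes feature magnitudes incomparable across slices.
#'
#' @param t a [tomogram()].
#' @param axis slicing axis.
#' @param encoder an encoder backend.
#' @param normalize_percentiles percentile pair defining the volume-wide
#'   clip range.
#' @return List with `feats` (n_slices x h x w x C array), `stride`, `axis`.
#' @export
encode_view <- function(t, axis, encoder, normalize_percentiles = c(1, 99)) {
  d <- dim(t$voxels)
  extent <- switch(axis, z = d[1], y = d[2], x = d[3])
  bounds <- stats::quantile(t$voxels, normalize_percentiles / 100,
                            names = FALSE)
  first <- NULL
  out <- NULL
  for (i in seq_len(extent)) {
    img <- normalize_slice(extract_slice(t, axis, i),
                           normalize_percentiles[1], normalize_percentiles[2],
                           bounds = bounds)
    fm <- encode_slice(encoder, img)
    if (is.null(out)) {
      first <- dim(fm$feats)
      out <- array(0, c(extent, first))
    }
    out[i, , , ] <- fm$feats
  }
  list(feats = out, stride = encoder$stride, axis = axis)
}

# Align-corners linear interpolation matrix from n source to m target samples.
interp_matrix <- function(n, m) {
  W <- matrix(0, m, n)
  if (n == 1L) {
    W[, 1] <- 1
    return(W)
  }
  pos <- if (m == 1L) 0 else (seq_len(m) - 1) * (n - 1) / (m - 1)
  j0 <- pmin(floor(pos), n - 2)
  fr <- pos - j0
  for (i in seq_len(m)) {
    W[i, j0[i] + 1] <- 1 - fr[i]
    W[i, j0[i] + 2] <- W[i, j0[i] + 2] + fr[i]
  }
  W
}

#' Bilinearly upsample a stacked view to full resolution
#'
#' Each slice's h x w feature map is interpolated in-plane (align-corners
#' bilinear) to the slice's pixel extent; no interpolation happens across the
#' stacking axis, which must already equal its target extent.
#'
#' @param view output of [encode_view()].
#' @param target_dim full volume dimension `c(D, H, W)`.
#' @return Array `n_slices x R x C x C_feat` where (R, C) are the in-plane
#'   target extents for the view's axis.
#' @export
upsample_view <- function(view, target_dim) {
  d <- dim(view$feats)      # (slices, h, w, C)
  n_slices <- d[1]
  inplane <- switch(view$axis,
                    z = target_dim[2:3],
                    y = target_dim[c(1, 3)],
                    x = target_dim[1:2])
  stack_target <- switch(view$axis, z = target_dim[1], y = target_dim[2],
                         x = target_dim[3])
  if (n_slices != stack_target) {
    stop("stacking axis extent ", n_slices, " does not match target ",
         stack_target, call. = FALSE)
  }
  Wr <- interp_matrix(d[2], inplane[1])
  Wc <- interp_matrix(d[3], inplane[2])
  out <- array(0, c(n_slices, inplane, d[4]))
  for (i in seq_len(n_slices)) {
    for (ch in seq_len(d[4])) {
      out[i, , , ch] <- Wr %*% view$feats[i, , , ch] %*% t(Wc)
    }
  }
  out
}

# Upsampled view block arranged into (z, y, x, C) voxel order.
view_block <- function(view, target_dim) {
  up <- upsample_view(view, target_dim)
  switch(view$axis,
         z = up,
         y = aperm(up, c(2, 1, 3, 4)),
         x = aperm(up, c(2, 3, 1, 4)))
}

#' Build the concatenated tri-view feature volume
#'
#' @param z_block,y_block,x_block D x H x W x C arrays in (z, y, x) voxel
#'   order (see [encode_feature_volume()] for the one-call path).
#' @return A `feature_volume`: list with `feats` (D x H x W x 3C), and
#'   `block_channels` recording the per-view channel count.
#' @export
build_feature_volume <- function(z_block, y_block, x_block) {
  dz <- dim(z_block)
  if (!identical(dz, dim(y_block)) || !identical(dz, dim(x_block))) {
    stop("view blocks have mismatched shapes", call. = FALSE)
  }
  feats <- array(c(z_block, y_block, x_block),
                 dim = c(dz[1:3], 3L * dz[4]))
  structure(list(feats = feats, block_channels = dz[4]),
            class = "feature_volume")
}

#' Encode a tomogram into its full-resolution feature volume
#'
#' Convenience composition: [encode_view()] on all three axes,
#' [upsample_view()], axis permutation into voxel order, concatenation.
#'
#' @inheritParams encode_view
#' @return A `feature_volume`.
#' @export
encode_feature_volume <- function(t, encoder, normalize_percentiles = c(1, 99)) {
  d <- dim(t$voxels)
  blocks <- lapply(c("z", "y", "x"), function(ax) {
    view_block(encode_view(t, ax, encoder, normalize_percentiles), d)
  })
  build_feature_volume(blocks[[1]], blocks[[2]], blocks[[3]])
}

# Mean-pool a 4D array (D,H,W,C) along one spatial axis with window r
# (partial edge windows average their actual extent).
pool_axis <- function(arr, axis, r) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_len(4L), axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  m <- matrix(x, nrow = dp[1])
  g <- ceiling(seq_len(dp[1]) / r)
  pooled <- rowsum(m, g) / as.vector(tabulate(g))
  out <- array(pooled, c(nrow(pooled), dp[-1]))
  aperm(out, order(perm))
}

#' Build the multi-resolution feature pyramid
#'
#' Level `r` is the `r^3` block average of the full-resolution feature
#' volume (edge cells average their partial extent), with the tri-view
#' channel concatenation preserved. Levels are returned coarse to fine.
#'
#' @param fv a `feature_volume` from [build_feature_volume()].
#' @param ratios positive integer downsampling ratios, strictly decreasing
#'   (coarse to fine), e.g. `c(16, 8, 4)`.
#' @return List of `feature_pyramid_level`s, each with `ratio`, `feats`
#'   (ceiling(D/r) x ceiling(H/r) x ceiling(W/r) x 3C) and `full_dim`.
#' @export
build_pyramid <- function(fv, ratios = c(16L, 8L, 4L)) {
  stopifnot(inherits(fv, "feature_volume"))
  ratios <- as.integer(ratios)
  if (length(ratios) == 0L || any(ratios < 1L)) {
    stop("ratios must be positive integers", call. = FALSE)
  }
  if (length(ratios) > 1L && any(diff(ratios) >= 0L)) {
    stop("ratios must be strictly decreasing (coarse to fine)", call. = FALSE)
  }
  full_dim <- dim(fv$feats)[1:3]
  lapply(ratios, function(r) {
    f <- fv$feats
    if (r > 1L) for (ax in 1:3) f <- pool_axis(f, ax, r)
    structure(list(ratio = r, feats = f, full_dim = full_dim),
              class = "feature_pyramid_level")
  })
}

#' Map pyramid cell indices to full-resolution voxel centers
#'
#' Cell `i` (1-based) at ratio `r` covers voxels `(i-1)*r + 1 .. i*r`; its
#' center voxel is `(i-1)*r + floor(r/2) + 1`, clipped to the volume.
#'
#' @param idx integer cell indices (1-based).
#' @param ratio the level's downsampling ratio.
#' @param extent the full-resolution extent of this axis.
#' @return Integer voxel indices, 1-based.
#' @export
cell_center <- function(idx, ratio, extent) {
  pmin(extent, (idx - 1L) * ratio + ratio %/% 2L + 1L)
}
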