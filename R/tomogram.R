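#' Construct a tomogram object
#'
#' A tomogram is a dense 3D scalar density grid with (z, y, x) voxel indexing:
#' the first array dimension runs over sections (z, depth D), the second over
#' rows (y, height H) and the third over columns (x, width W). All in-R voxel
#' coordinates are 1-based; file interchange (CSV, CLI) is 0-based.
#'
#' @param voxels numeric 3D array, dimension `c(D, H, W)`, all values finite.
#' @param voxel_size optional physical voxel spacing (Angstrom/voxel).
#' @return An object of class `tomogram` with elements `voxels` and
#'   `voxel_size`.
#' @export
tomogram <- function(voxels, voxel_size = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(voxels))) {
    stop("tomogram contains non-finite voxel values", call. = FALSE)
  }
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tomogram> %d x %d x %d (z,y,x)%s\n", d[1], d[2], d[3],
              if (is.null(x$voxel_size)) ""
              else sprintf(", %.3g A/voxel", x$voxel_size)))
  invisible(x)
}

#' @export
dim.tomogram <- function(x) dim(x$voxels)

#' Read a tomogram from an MRC file
#'
#' Reads an MRC2014 volume (modes 0, 1, 2 and 12). MRC sections map to z,
#' rows to y and columns to x, so `read_tomogram(f)$voxels` has dimension
#' `c(D, H, W)`. The voxel size is taken from the cell dimensions when the
#' header carries them.
#'
#' @param path path to an MRC (or REC) file containing a 3D volume.
#' @return A [tomogram()].
#' @export
read_tomogram <- function(path) {
  v <- read_mrc_volume(path)
  tomogram(v$voxels, voxel_size = v$voxel_size)
}

#' Write a tomogram to an MRC file
#'
#' @param t a [tomogram()].
#' @param path output path.
#' @export
write_tomogram <- function(t, path) {
  stopifnot(inherits(t, "tomogram"))
  write_mrc_volume(path, t$voxels, mode = 2L, voxel_size = t$voxel_size)
  invisible(NULL)
}

#' Write a binary mask volume as MRC
#'
#' Writes a 3D binary mask (an instance or semantic segmentation) as an MRC
#' mode-0 volume with values in \{0, 1\}, using the same axis convention as
#' [read_tomogram()].
#'
#' @param mask a logical/0-1 numeric 3D array, or an `instance_mask3d`.
#' @param path output path.
#' @param voxel_size optional voxel spacing carried into the header.
#' @export
write_mask <- function(mask, path, voxel_size = NULL) {
  if (inherits(mask, "instance_mask3d")) mask <- mask$mask
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("mask must be a 3D array", call. = FALSE)
  }
  vals <- as.numeric(mask)
  if (!all(vals %in% c(0, 1))) {
    stop("non-binary mask: values must be 0/1", call. = FALSE)
  }
  write_mrc_volume(path, array(vals, dim(mask)), mode = 0L,
                   voxel_size = voxel_size)
  invisible(NULL)
}

#' Extract an orthogonal slice from a tomogram
#'
#' The three views are: `axis = "z"` gives the YX-plane (an H x W image,
#' rows = y, columns = x); `axis = "y"` the ZX-plane (D x W, rows = z,
#' columns = x); `axis = "x"` the ZY-plane (D x H, rows = z, columns = y).
#' A pixel at (row, col) of the returned image maps back to exactly one
#' voxel; see [slice_pixel_to_voxel()].
#'
#' @param t a [tomogram()] (or bare 3D array).
#' @param axis one of `"z"`, `"y"`, `"x"`.
#' @param index 1-based slice index along `axis`.
#' @return A matrix with attribute `axes` naming its (row, col) volume axes
#'   and attribute `slice` recording `axis` and `index`.
#' @export
extract_slice <- function(t, axis = c("z", "y", "x"), index) {
  axis <- match.arg(axis)
  vox <- if (inherits(t, "tomogram")) t$voxels else t
  d <- dim(vox)
  extent <- switch(axis, z = d[1], y = d[2], x = d[3])
  if (index < 1L || index > extent) {
    stop("slice index ", index, " out of range [1, ", extent, "] for axis ",
         axis, call. = FALSE)
  }
  m <- switch(axis,
              z = vox[index, , , drop = TRUE],
              y = vox[, index, , drop = TRUE],
              x = vox[, , index, drop = TRUE])
  m <- matrix(m, nrow = switch(axis, z = d[2], y = d[1], x = d[1]))
  attr(m, "axes") <- switch(axis, z = c("y", "x"), y = c("z", "x"),
                            x = c("z", "y"))
  attr(m, "slice") <- list(axis = axis, index = index)
  m
}

#' Map a slice pixel back to its voxel coordinate
#'
#' Inverse of the [extract_slice()] coordinate map.
#'
#' @param axis the slicing axis of the image.
#' @param index the slice index.
#' @param row,col 1-based pixel coordinates.
#' @return Integer vector `c(z, y, x)`, 1-based.
#' @export
slice_pixel_to_voxel <- function(axis, index, row, col) {
  switch(axis,
         z = c(index, row, col),
         y = c(row, index, col),
         x = c(row, col, index),
         stop("unknown axis ", axis, call. = FALSE))
}

# Voxel (z,y,x) -> (row, col) pixel on the slice through it along `axis`.
voxel_to_slice_pixel <- function(axis, p) {
  switch(axis,
         z = c(p[2], p[3]),
         y = c(p[1], p[3]),
         x = c(p[1], p[2]))
}

#' Percentile-normalize a slice
#'
#' Clips values to the `[low_pct, high_pct]` percentile range and linearly
#' rescales to `[0, 1]`. A constant image (or a degenerate percentile range)
#' maps to all zeros. Segmenter and encoder backends expect this bounded
#' range.
#'
#' @param img numeric matrix.
#' @param low_pct,high_pct percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @param bounds optional absolute clip range `c(low, high)` overriding the
#'   per-image percentiles; used to normalize many slices on one common
#'   (e.g. volume-wide) scale.
#' @return Matrix of the same shape with values in `[0, 1]`; slice
#'   attributes are preserved.
#' @export
normalize_slice <- function(img, low_pct = 1, high_pct = 99, bounds = NULL) {
  if (low_pct >= high_pct) stop("low_pct must be < high_pct", call. = FALSE)
  q <- if (is.null(bounds)) {
    stats::quantile(img, c(low_pct, high_pct) / 100, names = FALSE)
  } else bounds
  out <- if (q[2] > q[1]) (pmin(pmax(img, q[1]), q[2]) - q[1]) / (q[2] - q[1])
         else img * 0
  out <- matrix(out, nrow = nrow(img))
  attributes(out) <- attributes(img)
  out
}

# Embed a 2D slice mask into an all-FALSE volume position, OR-ing in place.
embed_slice_mask <- function(vol_mask, axis, index, m) {
  switch(axis,
         z = vol_mask[index, , ] <- vol_mask[index, , ] | m,
         y = vol_mask[, index, ] <- vol_mask[, index, ] | m,
         x = vol_mask[, , index] <- vol_mask[, , index] | m)
  vol_mask
}
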