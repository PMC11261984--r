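# Cross-plane self-prompting: prompt-based 3D instance segmentation.
#
# A single voxel prompt seeds 2D segmentation on the three orthogonal planes
# through it; each plane's (peak, mask) then re-prompts the adjacent slice,
# recursively, in both directions along its axis, until the adjacent-slice
# IoU drops below tau_iou (or the mask empties, or the volume ends). The
# 3D instance mask is the union of all accepted per-plane masks.

#' Intersection over union of two binary masks
#'
#' @param a,b logical matrices (or arrays) of identical shape.
#' @return `|a & b| / |a | b|` in `[0, 1]`; defined as 0 when both are empty.
#' @export
compute_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Propagate a 2D segmentation along one axis direction
#'
#' Starting from an accepted (peak, mask) pair on slice `start_index`, each
#' step segments the next slice prompting with the previous slice's peak
#' point and mask, accepts it if its IoU with the previous mask is at least
#' `tau_iou`, and otherwise stops. The mask that triggered the stop is not
#' part of the returned trace.
#'
#' @param t a [tomogram()].
#' @param axis slicing axis, `"z"`, `"y"` or `"x"`.
#' @param direction `+1` or `-1`.
#' @param start_index slice index carrying the seed.
#' @param seed_peak pixel coordinate `c(row, col)` of the seed confidence peak.
#' @param seed_mask nonempty logical matrix, the seed slice's mask.
#' @param segmenter a segmenter backend.
#' @param tau_iou IoU stopping threshold in `[0, 1]`.
#' @param normalize_percentiles percentile pair passed to [normalize_slice()].
#' @return A `propagation_trace`: list with `steps` (each holding `index`,
#'   `mask`, `peak`, `iou`) and `stop_reason` (one of `"iou_below_threshold"`,
#'   `"empty_mask"`, `"volume_boundary"`).
#' @export
propagate_direction <- function(t, axis, direction, start_index, seed_peak,
                                seed_mask, segmenter, tau_iou = 0.5,
                                normalize_percentiles = c(1, 99)) {
  stopifnot(direction %in% c(-1L, 1L))
  if (!any(seed_mask)) stop("seed mask is empty", call. = FALSE)
  d <- dim(t$voxels)
  extent <- switch(axis, z = d[1], y = d[2], x = d[3])
  if (start_index < 1L || start_index > extent) {
    stop("start index out of range", call. = FALSE)
  }
  prev_mask <- seed_mask
  prev_peak <- seed_peak
  idx <- start_index + direction
  steps <- list()
  stop_reason <- "volume_boundary"
  while (idx >= 1L && idx <= extent) {
    img <- normalize_slice(extract_slice(t, axis, idx),
                           normalize_percentiles[1], normalize_percentiles[2])
    res <- promptable_segment(segmenter, img, point = prev_peak,
                              mask_prompt = prev_mask)
    if (!any(res$mask2d)) {
      stop_reason <- "empty_mask"
      break
    }
    iou <- compute_iou(res$mask2d, prev_mask)
    if (iou < tau_iou) {
      stop_reason <- "iou_below_threshold"
      break
    }
    steps[[length(steps) + 1L]] <- list(index = idx, mask = res$mask2d,
                                        peak = res$peak, iou = iou)
    prev_mask <- res$mask2d
    prev_peak <- res$peak
    idx <- idx + direction
  }
  structure(list(axis = axis, direction = direction, steps = steps,
                 stop_reason = stop_reason),
            class = "propagation_trace")
}

#' Tabulate a propagation trace
#'
#' @param trace a `propagation_trace` from [propagate_direction()].
#' @return A data frame with columns `slice` (0-based, for interchange),
#'   `area`, `iou`, plus the trace's `stop_reason` as an attribute; suitable
#'   for CSV export.
#' @export
trace_table <- function(trace) {
  df <- data.frame(
    slice = vapply(trace$steps, function(s) s$index - 1L, integer(1)),
    area = vapply(trace$steps, function(s) sum(s$mask), numeric(1)),
    iou = vapply(trace$steps, function(s) s$iou, numeric(1))
  )
  attr(df, "stop_reason") <- trace$stop_reason
  df
}

instance_mask3d <- function(mask, prompt = NULL, traces = NULL) {
  structure(list(mask = mask, prompt = prompt, traces = traces),
            class = "instance_mask3d")
}

#' @export
print.instance_mask3d <- function(x, ...) {
  cat(sprintf("<instance_mask3d> %s voxels%s\n", sum(x$mask),
              if (is.null(x$prompt)) ""
              else sprintf(", prompt (%s)", paste(x$prompt, collapse = ","))))
  invisible(x)
}

#' Prompt-based 3D instance segmentation from a single point
#'
#' Segments the three orthogonal planes through the prompt with a point
#' prompt, then runs [propagate_direction()] for each of the six axis
#' directions seeded by the corresponding plane's peak and mask, and unions
#' every accepted 2D mask (including the three initial ones) into a binary
#' volume. A plane whose initial mask is empty skips its two directions; if
#' all three initial masks are empty the result is the empty mask.
#'
#' @param t a [tomogram()].
#' @param p integer voxel prompt `c(z, y, x)`, 1-based.
#' @param segmenter a segmenter backend.
#' @param tau_iou IoU stopping threshold.
#' @param normalize_percentiles percentile pair for slice normalization.
#' @param keep_traces record per-direction propagation traces.
#' @return An `instance_mask3d` whose `mask` has the tomogram's shape.
#' @export
segment_from_point <- function(t, p, segmenter, tau_iou = 0.5,
                               normalize_percentiles = c(1, 99),
                               keep_traces = FALSE) {
  d <- dim(t$voxels)
  p <- as.integer(p)
  if (length(p) != 3L || any(p < 1L) || any(p > d)) {
    stop("prompt (", paste(p, collapse = ","), ") outside volume", call. = FALSE)
  }
  axes <- c("z", "y", "x")
  idx_of <- c(z = p[1], y = p[2], x = p[3])
  vol <- array(FALSE, d)
  traces <- if (keep_traces) list() else NULL

  initial <- list()
  for (ax in axes) {
    img <- normalize_slice(extract_slice(t, ax, idx_of[[ax]]),
                           normalize_percentiles[1], normalize_percentiles[2])
    initial[[ax]] <- promptable_segment(segmenter, img,
                                        point = voxel_to_slice_pixel(ax, p))
  }
  if (!any(vapply(initial, function(r) any(r$mask2d), logical(1)))) {
    return(instance_mask3d(vol, prompt = p, traces = traces))
  }
  for (ax in axes) {
    res <- initial[[ax]]
    if (!any(res$mask2d)) next
    vol <- embed_slice_mask(vol, ax, idx_of[[ax]], res$mask2d)
    for (dir in c(1L, -1L)) {
      tr <- propagate_direction(t, ax, dir, idx_of[[ax]], res$peak,
                                res$mask2d, segmenter, tau_iou,
                                normalize_percentiles)
      for (s in tr$steps) vol <- embed_slice_mask(vol, ax, s$index, s$mask)
      if (keep_traces) traces[[paste0(ax, ifelse(dir > 0, "+", "-"))]] <- tr
    }
  }
  instance_mask3d(vol, prompt = p, traces = traces)
}
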