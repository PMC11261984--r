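# Hierarchical feature matching: MAP query, cosine similarity fields,
# coarse-to-fine keep-mask propagation, NMS and top-K prompt proposal;
# plus the naive full-resolution matcher used as baseline and oracle.

#' Masked average pooling query feature
#'
#' Pools the full-resolution feature volume over a set of instance masks:
#' the sum of masked feature vectors over all masks divided by the total
#' nonzero-voxel count (a voxel covered by several masks contributes once
#' per mask).
#'
#' @param fv a `feature_volume`.
#' @param masks list of `instance_mask3d`s or logical volumes; at least one
#'   must be nonempty.
#' @return A `query_feature`: list with `vector` (length 3C) and
#'   `n_voxels` (total contributing count).
#' @export
masked_average_pool <- function(fv, masks) {
  stopifnot(inherits(fv, "feature_volume"))
  if (!is.list(masks)) masks <- list(masks)
  d <- dim(fv$feats)
  nvox <- prod(d[1:3])
  fm <- matrix(fv$feats, nrow = nvox)
  acc <- numeric(d[4])
  total <- 0
  for (m in masks) {
    if (inherits(m, "instance_mask3d")) m <- m$mask
    if (!identical(dim(m), d[1:3])) {
      stop("mask shape does not match the feature volume", call. = FALSE)
    }
    idx <- which(m)
    if (length(idx) == 0L) next
    acc <- acc + colSums(fm[idx, , drop = FALSE])
    total <- total + length(idx)
  }
  if (total == 0) stop("all masks are empty: no support for the query",
                       call. = FALSE)
  structure(list(vector = acc / total, n_voxels = total),
            class = "query_feature")
}

# Cosine of q against rows of a cell matrix; zero rows score 0.
cosine_rows <- function(cells, q) {
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("zero query vector", call. = FALSE)
  rn <- sqrt(rowSums(cells^2))
  s <- as.vector(cells %*% q) / (rn * qn)
  s[rn == 0] <- 0
  s
}

#' Cosine similarity of a query against one pyramid level
#'
#' @param q a `query_feature` (or bare numeric vector).
#' @param level a `feature_pyramid_level`.
#' @param evaluate_mask optional logical array over the level's cells; only
#'   these cells are evaluated, the rest are left `NA` ("unevaluated").
#' @return A `similarity_level`: list with `scores` (array over cells,
#'   `NA` = unevaluated), `evaluated` (logical array), `ratio`, `full_dim`,
#'   and `n_evaluated`.
#' @export
cosine_similarity_level <- function(q, level, evaluate_mask = NULL) {
  qv <- if (inherits(q, "query_feature")) q$vector else q
  d <- dim(level$feats)
  grid <- d[1:3]
  cells <- matrix(level$feats, nrow = prod(grid))
  if (is.null(evaluate_mask)) {
    idx <- seq_len(prod(grid))
  } else {
    if (!identical(dim(evaluate_mask), grid)) {
      stop("evaluate_mask shape does not match level grid", call. = FALSE)
    }
    idx <- which(evaluate_mask)
  }
  scores <- array(NA_real_, grid)
  if (length(idx) > 0L) {
    scores[idx] <- cosine_rows(cells[idx, , drop = FALSE], qv)
  }
  evaluated <- array(FALSE, grid)
  evaluated[idx] <- TRUE
  structure(list(scores = scores, evaluated = evaluated, ratio = level$ratio,
                 full_dim = level$full_dim, n_evaluated = length(idx)),
            class = "similarity_level")
}

#' Propagate a keep-mask to the next (finer) pyramid level
#'
#' Nearest-neighbor upsampling of the keep decision: a cell at ratio `r'`
#' is evaluable iff the cell containing it at ratio `r` was kept. Requires
#' `r'` to divide `r`.
#'
#' @param keep logical array over the coarser level's cells.
#' @param ratio the coarser ratio `r`.
#' @param next_ratio the finer ratio `r'`.
#' @param next_grid integer dimension of the finer level's cell grid.
#' @return Logical array over the finer grid.
#' @export
propagate_keep_mask <- function(keep, ratio, next_ratio, next_grid) {
  if (ratio %% next_ratio != 0L) {
    stop("ratio mismatch: ", next_ratio, " does not divide ", ratio,
         call. = FALSE)
  }
  parent <- function(i) ((i - 1L) * next_ratio) %/% ratio + 1L
  keep[parent(seq_len(next_grid[1])),
       parent(seq_len(next_grid[2])),
       parent(seq_len(next_grid[3])), drop = FALSE]
}

#' Coarse-to-fine hierarchical feature matching
#'
#' Evaluates the cosine similarity of `q` against every cell of the coarsest
#' pyramid level, keeps cells scoring at least `tau_sim`, propagates the
#' keep-mask to the next finer level as its evaluation mask, and repeats.
#' If a level's keep-mask comes out empty, its single best-scoring cell is
#' kept instead (logged via a warning) so a proposal chain always survives.
#'
#' @param levels list of `feature_pyramid_level`s ordered coarse to fine.
#' @param q a `query_feature`.
#' @param tau_sim similarity threshold in `[-1, 1]`.
#' @return List with `similarity` (the finest level's `similarity_level`,
#'   including its `keep` mask), `n_evaluations` (total cosine evaluations
#'   across levels), `per_level` (evaluation counts), and
#'   `finest_full_count` (cells a full finest-level evaluation would cost).
#' @export
hierarchical_match <- function(levels, q, tau_sim = 0.5) {
  if (length(levels) == 0L) stop("empty pyramid level list", call. = FALSE)
  ratios <- vapply(levels, function(l) l$ratio, integer(1))
  if (length(ratios) > 1L && any(diff(ratios) >= 0L)) {
    stop("levels must be ordered coarse to fine", call. = FALSE)
  }
  ev_mask <- NULL
  per_level <- integer(length(levels))
  sim <- NULL
  keep <- NULL
  for (k in seq_along(levels)) {
    sim <- cosine_similarity_level(q, levels[[k]], ev_mask)
    per_level[k] <- sim$n_evaluated
    keep <- sim$evaluated & !is.na(sim$scores) & sim$scores >= tau_sim
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) {
      best <- which(sim$scores == max(sim$scores, na.rm = TRUE))
      keep[best[1]] <- TRUE
      warning("keep-mask empty at ratio ", sim$ratio,
              "; falling back to the single best cell", call. = FALSE)
    }
    if (k < length(levels)) {
      ev_mask <- propagate_keep_mask(keep, ratios[k], ratios[k + 1],
                                     dim(levels[[k + 1]]$feats)[1:3])
    }
  }
  sim$keep <- keep
  list(similarity = sim, n_evaluations = sum(per_level),
       per_level = per_level,
       finest_full_count = prod(dim(levels[[length(levels)]]$feats)[1:3]))
}

#' Naive full-resolution feature matching
#'
#' The brute-force baseline: cosine similarity of the query against every
#' voxel of the full-resolution feature volume.
#'
#' @param fv a `feature_volume`.
#' @param q a `query_feature`.
#' @return Numeric D x H x W array of cosine scores.
#' @export
naive_match <- function(fv, q) {
  qv <- if (inherits(q, "query_feature")) q$vector else q
  d <- dim(fv$feats)
  array(cosine_rows(matrix(fv$feats, nrow = prod(d[1:3])), qv), d[1:3])
}

#' Greedy non-maximum suppression and top-K proposal selection
#'
#' Candidate cells (the finest level's kept cells) are visited in order of
#' descending score (ties: ascending cell coordinate, lexicographic); a
#' candidate is accepted iff its full-resolution center is at least `radius`
#' (Euclidean) from every previously accepted center; selection stops at `K`.
#'
#' @param sim a `similarity_level` carrying a `keep` mask (from
#'   [hierarchical_match()]), or one whose evaluated cells are all candidates.
#' @param radius suppression radius in full-resolution voxels, > 0.
#' @param k maximum number of proposals, >= 1.
#' @return A `proposal_set`: data frame with columns `z`, `y`, `x` (1-based
#'   voxel centers) and `score`, sorted by descending score.
#' @export
nms_top_k <- function(sim, radius, k = 512L) {
  stopifnot(radius > 0, k >= 1L)
  cand_mask <- if (!is.null(sim$keep)) sim$keep else sim$evaluated
  idx <- which(cand_mask, arr.ind = TRUE)
  empty <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      score = numeric(0))
  class(empty) <- c("proposal_set", "data.frame")
  if (nrow(idx) == 0L) return(empty)
  scores <- sim$scores[cand_mask]
  ord <- order(-scores, idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  scores <- scores[ord]
  centers <- cbind(cell_center(idx[, 1], sim$ratio, sim$full_dim[1]),
                   cell_center(idx[, 2], sim$ratio, sim$full_dim[2]),
                   cell_center(idx[, 3], sim$ratio, sim$full_dim[3]))
  acc <- matrix(0, nrow = 0, ncol = 3)
  acc_score <- numeric(0)
  r2 <- radius^2
  for (i in seq_len(nrow(centers))) {
    if (nrow(acc) > 0L) {
      d2 <- (acc[, 1] - centers[i, 1])^2 + (acc[, 2] - centers[i, 2])^2 +
        (acc[, 3] - centers[i, 3])^2
      if (any(d2 < r2)) next
    }
    acc <- rbind(acc, centers[i, ])
    acc_score <- c(acc_score, scores[i])
    if (nrow(acc) >= k) break
  }
  out <- data.frame(z = as.integer(acc[, 1]), y = as.integer(acc[, 2]),
                    x = as.integer(acc[, 3]), score = acc_score)
  class(out) <- c("proposal_set", "data.frame")
  out
}

# Mean bounding-box diameter (mean of the three bbox extents) of a set of
# instance masks; used as the automatic NMS radius.
mean_bbox_diameter <- function(masks) {
  diams <- vapply(masks, function(m) {
    if (inherits(m, "instance_mask3d")) m <- m$mask
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NA_real_)
    mean(apply(idx, 2, function(v) diff(range(v)) + 1))
  }, numeric(1))
  diams <- diams[!is.na(diams)]
  if (length(diams) == 0L) stop("no nonempty masks to size the NMS radius",
                                call. = FALSE)
  mean(diams)
}
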