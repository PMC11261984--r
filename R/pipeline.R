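# End-to-end orchestration: configuration, the one-prompt-to-full-tomogram
# semantic segmentation run, and file interchange (proposals CSV, config
# YAML, JSON-lines run log).

#' Pipeline configuration
#'
#' @param tau_iou adjacent-slice IoU stopping threshold in `[0, 1]`.
#' @param tau_sim cosine-similarity keep threshold in `[-1, 1]`.
#' @param top_k maximum number of proposed prompts, >= 1.
#' @param ratios pyramid downsampling ratios, strictly decreasing.
#' @param nms_radius suppression radius in voxels, or `"auto"` to use the
#'   mean bounding-box diameter of the prompted instance masks.
#' @param segmenter,encoder backend names (`"mock"` or `"foundation"`).
#' @param segmenter_options,encoder_options option lists for the backends.
#' @param normalize_percentiles percentile pair for slice normalization.
#' @param seed RNG seed (synthetic-data paths only; the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(tau_iou = 0.5, tau_sim = 0.5, top_k = 512L,
                            ratios = c(16L, 8L, 4L), nms_radius = "auto",
                            segmenter = "mock", encoder = "mock",
                            segmenter_options = list(),
                            encoder_options = list(),
                            normalize_percentiles = c(1, 99),
                            seed = 0L) {
  stopifnot(tau_iou >= 0, tau_iou <= 1, tau_sim >= -1, tau_sim <= 1,
            top_k >= 1L, all(ratios >= 1))
  if (length(ratios) > 1L && any(diff(ratios) >= 0)) {
    stop("ratios must be strictly decreasing", call. = FALSE)
  }
  if (!identical(nms_radius, "auto")) stopifnot(nms_radius > 0)
  structure(list(tau_iou = tau_iou, tau_sim = tau_sim,
                 top_k = as.integer(top_k), ratios = as.integer(ratios),
                 nms_radius = nms_radius, segmenter = segmenter,
                 encoder = encoder, segmenter_options = segmenter_options,
                 encoder_options = encoder_options,
                 normalize_percentiles = normalize_percentiles,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(NULL)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run prompt-based instance segmentation
#'
#' @param t a [tomogram()].
#' @param p voxel prompt `c(z, y, x)`, 1-based.
#' @param cfg a `pipeline_config`.
#' @param keep_traces record propagation traces.
#' @return An `instance_mask3d`.
#' @export
run_instance <- function(t, p, cfg = pipeline_config(), keep_traces = FALSE) {
  seg <- make_segmenter(cfg$segmenter, cfg$segmenter_options)
  segment_from_point(t, p, seg, tau_iou = cfg$tau_iou,
                     normalize_percentiles = cfg$normalize_percentiles,
                     keep_traces = keep_traces)
}

#' One-prompt (or few-prompt) full-tomogram semantic segmentation
#'
#' The five stages: (1) encode the three views and build the feature
#' pyramid; (2) segment an instance from every prompt; (3) pool the
#' instances into a masked-average query feature; (4) hierarchical matching
#' plus NMS proposes up to `top_k` new point prompts; (5) instance
#' segmentation at every proposal. Proposals whose instance mask comes out
#' empty are dropped; the semantic mask is the voxel union of the prompted
#' and all retained proposal instance masks.
#'
#' @param t a [tomogram()].
#' @param prompts matrix or data frame of voxel prompts (rows `z, y, x`,
#'   1-based), all marking particles of one category.
#' @param cfg a `pipeline_config`.
#' @return A `semantic_result`: list with `semantic_mask` (logical volume),
#'   `instances` (retained proposal instance masks), `prompted_instances`,
#'   `proposals` (retained `proposal_set`), `query`, and `log` (list of
#'   per-stage entries with timings and counters).
#' @export
run_semantic <- function(t, prompts, cfg = pipeline_config()) {
  prompts <- as.matrix(prompts)
  if (nrow(prompts) < 1L) stop("need at least one prompt", call. = FALSE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    log[[length(log) + 1L]] <<- list(stage = name,
                                     seconds = proc.time()[["elapsed"]] - t0)
    val
  }

  encoder <- make_encoder(cfg$encoder, cfg$encoder_options)
  fv <- stage("encode_features",
              encode_feature_volume(t, encoder, cfg$normalize_percentiles))
  pyramid <- stage("build_pyramid", build_pyramid(fv, cfg$ratios))

  prompted <- stage("prompt_instances", lapply(seq_len(nrow(prompts)),
    function(i) run_instance(t, prompts[i, ], cfg)))
  nonempty <- vapply(prompted, function(m) any(m$mask), logical(1))
  if (!any(nonempty)) {
    stop("no query support: every prompt produced an empty instance mask",
         call. = FALSE)
  }
  log[[length(log) + 1L]] <- list(stage = "prompt_instances_summary",
                                  n_prompts = nrow(prompts),
                                  n_nonempty = sum(nonempty))

  q <- stage("map_query", masked_average_pool(fv, prompted[nonempty]))
  hm <- stage("hierarchical_match",
              hierarchical_match(pyramid, q, cfg$tau_sim))
  log[[length(log) + 1L]] <- list(
    stage = "match_summary", n_evaluations = hm$n_evaluations,
    per_level = hm$per_level, finest_full_count = hm$finest_full_count)

  radius <- if (identical(cfg$nms_radius, "auto"))
    mean_bbox_diameter(prompted[nonempty]) else cfg$nms_radius
  proposals <- stage("nms", nms_top_k(hm$similarity, radius, cfg$top_k))

  inst <- stage("proposal_instances", lapply(seq_len(nrow(proposals)),
    function(i) run_instance(t, c(proposals$z[i], proposals$y[i],
                                  proposals$x[i]), cfg)))
  keep <- vapply(inst, function(m) any(m$mask), logical(1))
  retained <- proposals[keep, , drop = FALSE]
  class(retained) <- c("proposal_set", "data.frame")
  inst <- inst[keep]
  log[[length(log) + 1L]] <- list(stage = "proposal_summary",
                                  n_proposed = nrow(proposals),
                                  n_retained = nrow(retained),
                                  nms_radius = radius)

  semantic <- array(FALSE, dim(t$voxels))
  for (m in prompted[nonempty]) semantic <- semantic | m$mask
  for (m in inst) semantic <- semantic | m$mask

  structure(list(semantic_mask = semantic, instances = inst,
                 prompted_instances = prompted[nonempty],
                 proposals = retained, query = q, log = log),
            class = "semantic_result")
}

#' @export
print.semantic_result <- function(x, ...) {
  cat(sprintf(
    "<semantic_result> %d prompted + %d proposed instances, %d mask voxels\n",
    length(x$prompted_instances), length(x$instances), sum(x$semantic_mask)))
  invisible(x)
}

#' Write / read a proposals CSV
#'
#' Interchange format: header `z,y,x,score`, 0-based coordinates.
#'
#' @param proposals a `proposal_set` (1-based, as returned in R).
#' @param path CSV path.
#' @export
write_proposals <- function(proposals, path) {
  out <- data.frame(z = proposals$z - 1L, y = proposals$y - 1L,
                    x = proposals$x - 1L,
                    score = format(proposals$score, digits = 17))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' @rdname write_proposals
#' @export
read_proposals <- function(path) {
  df <- utils::read.csv(path)
  df$z <- df$z + 1L; df$y <- df$y + 1L; df$x <- df$x + 1L
  class(df) <- c("proposal_set", "data.frame")
  df
}

#' Write a run log as JSON lines
#'
#' @param log the `log` element of a `semantic_result`.
#' @param path output path.
#' @export
write_run_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (entry in log) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(NULL)
}
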