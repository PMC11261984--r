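# Particle-picking evaluation: greedy center matching and precision/recall/F1.

#' Match predicted centers to ground-truth particles
#'
#' Greedy one-to-one matching: predictions are visited in descending score
#' (input order when unscored); each is matched to the nearest still-unmatched
#' truth center within Euclidean distance `tol`. Matched predictions are true
#' positives, unmatched predictions false positives, unmatched truths false
#' negatives.
#'
#' @param pred data frame with columns `z`, `y`, `x` and optionally `score`.
#' @param truth data frame with columns `z`, `y`, `x` (restricted to the
#'   target class).
#' @param tol matching tolerance in voxels, > 0.
#' @return List with `tp`, `fp`, `fn` and `matches` (data frame of matched
#'   prediction/truth row indices and distances).
#' @export
match_predictions <- function(pred, truth, tol) {
  stopifnot(tol > 0)
  np <- nrow(pred); nt <- nrow(truth)
  ord <- if (!is.null(pred$score)) order(-pred$score) else seq_len(np)
  matched_t <- rep(FALSE, nt)
  matches <- data.frame(pred = integer(0), truth = integer(0),
                        dist = numeric(0))
  for (i in ord) {
    if (nt == 0L) break
    d <- sqrt((truth$z - pred$z[i])^2 + (truth$y - pred$y[i])^2 +
              (truth$x - pred$x[i])^2)
    d[matched_t] <- Inf
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= tol) {
      matched_t[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(pred = i, truth = j, dist = d[j]))
    }
  }
  tp <- nrow(matches)
  list(tp = tp, fp = np - tp, fn = nt - tp, matches = matches)
}

#' Precision, recall and F1 from match counts
#'
#' Degenerate conventions: precision is 0 when there are no predictions;
#' recall is 1 when both truth and predictions are empty and 0 when there
#' are predictions but no truth; F1 is 0 when precision + recall is 0.
#'
#' @param tp,fp,fn nonnegative counts.
#' @param tol the matching tolerance used (recorded, not used).
#' @return An `eval_result`: list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `tol`.
#' @export
precision_recall_f1 <- function(tp, fp, fn, tol = NA_real_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    if (tp + fp == 0) 1 else 0
  } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, tol = tol),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> TP %d FP %d FN %d | precision %.3f recall %.3f F1 %.3f (tol %.2f)\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$tol))
  invisible(x)
}

#' Evaluate picking predictions against ground truth
#'
#' @param pred predictions data frame (`z, y, x[, score]`), e.g. a
#'   `proposal_set`.
#' @param truth truth data frame (`z, y, x`), restricted to the target class.
#' @param tol matching tolerance in voxels; defaults to the mean truth
#'   particle radius when `truth` has a `radius` column.
#' @return An `eval_result`.
#' @export
evaluate_picking <- function(pred, truth, tol = NULL) {
  if (is.null(tol)) {
    if (is.null(truth$radius)) {
      stop("supply `tol` or a truth table with a `radius` column",
           call. = FALSE)
    }
    tol <- mean(truth$radius)
  }
  m <- match_predictions(pred, truth, tol)
  precision_recall_f1(m$tp, m$fp, m$fn, tol = tol)
}
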