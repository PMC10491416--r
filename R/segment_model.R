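# Simplified branch models: every detected fragment is replaced by its
# minimum-area bounding rectangle, which is far more robust to ragged or
# incomplete masks than the mask itself. A segmented instance becomes a
# three-point long-axis model B = (V, W); a forked instance is reduced to
# its rectangle center.

.new_segment_model <- function(id, rect) {
  V <- axis_points(rect)
  structure(list(
    id = id,
    V = V,
    W_top = rect$corners[1:2, , drop = FALSE],
    W_end = rect$corners[3:4, , drop = FALSE],
    members = list(list(id = id, kind = "segment", rect = rect)),
    top_fork = NULL,
    end_fork = NULL
  ), class = "branch_segment")
}

#' Member instance ids of a model or chain, in top-to-end order
#' @param model A `branch_segment` or `branch_chain`.
#' @return Integer vector.
#' @export
member_ids <- function(model) {
  vapply(model$members, function(m) as.integer(m$id), integer(1))
}

#' Build simplified branch models from an instance set
#'
#' Each "segmented" instance is reduced to the minimum-area bounding
#' rectangle of its mask, corner-ordered, and seeded as a three-point
#' long-axis model (top midpoint, center, end midpoint). Each "forked"
#' instance is reduced to its rectangle center point. Instances whose
#' rectangle is degenerate (zero long axis) cannot carry a model and are
#' dropped with a message; near-square segmented instances (aspect ratio
#' below 1.2, outside the 2-4 range the fragment annotations guarantee) are
#' kept but reported, since the search constraints filter them downstream.
#'
#' @param instances An `instance_set`.
#' @return List with `segments` (list of `branch_segment`) and `forks`
#'   (list of forks: `id`, `center`, `rect`).
#' @export
build_models <- function(instances) {
  segments <- list()
  forks <- list()
  for (inst in instances$instances) {
    rect <- min_area_rect(inst$mask)
    if (inst$label == "forked") {
      forks[[length(forks) + 1]] <-
        list(id = inst$id, center = rect$center, rect = rect)
      next
    }
    if (rect$long_len < 1e-9) {
      message("instance ", inst$id,
              ": degenerate rectangle (zero long axis), dropped")
      next
    }
    aspect <- rect$long_len / max(rect$short_len, 1e-12)
    if (aspect < 1.2)
      message("instance ", inst$id, sprintf(
        ": near-square rectangle (aspect %.2f), kept but atypical for a branch fragment",
        aspect))
    segments[[length(segments) + 1]] <- .new_segment_model(inst$id, rect)
  }
  list(segments = segments, forks = forks)
}

.model_rect <- function(s) s$members[[1]]$rect

#' Discard duplicated fragment detections
#'
#' Segmentation models sometimes emit near-duplicate masks of the same
#' fragment, which would corrupt the reconstruction. Pairs of segment
#' rectangles whose IoU exceeds the threshold are resolved by discarding the
#' smaller-area member, processing pairs in decreasing-IoU order; survivors
#' are pairwise at or below the threshold. The default 0.15 sits below the
#' 0.2 critical overlap that genuinely adjacent fragments of aspect ratio
#' 2-4 can reach, with margin for short-axis deviation. Idempotent. Fork
#' instances do not participate.
#'
#' @param segments List of `branch_segment` models (fresh, single-member).
#' @param iou_threshold Overlap above which the pair is a duplicate.
#' @return Filtered list of `branch_segment`.
#' @export
dedup <- function(segments, iou_threshold = 0.15) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  n <- length(segments)
  if (n < 2) return(segments)
  pairs <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    iou <- rect_iou(.model_rect(segments[[i]]), .model_rect(segments[[j]]))
    if (iou > iou_threshold) pairs <- rbind(pairs, c(i, j, iou))
  }
  alive <- rep(TRUE, n)
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs[, 3]), , drop = FALSE]
    areas <- vapply(segments, function(s) {
      r <- .model_rect(s); r$long_len * r$short_len
    }, numeric(1))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!alive[i] || !alive[j]) next
      # drop the smaller area (tie: the later id), keeping the fuller mask
      drop <- if (areas[i] < areas[j]) i
              else if (areas[j] < areas[i]) j
              else if (segments[[i]]$id > segments[[j]]$id) i else j
      alive[drop] <- FALSE
    }
  }
  segments[alive]
}
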