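# Evaluation metrics for detection and branch reconstruction.

#' Pixel IoU of two binary masks
#' @param a,b Logical matrices on a common canvas.
#' @return Intersection over union in \[0, 1\]; 0 when the union is empty.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Detection precision, recall and F1 by greedy mask matching
#'
#' Predictions and ground-truth masks are matched one-to-one greedily in
#' decreasing IoU; pairs at or above `match_iou` are true positives,
#' unmatched predictions false positives, unmatched truths false negatives.
#' Precision (and recall) default to 0 when their denominator is 0, and
#' F1 = 2PR/(P+R) is 0 when P + R = 0.
#'
#' @param predicted,truth Lists of logical masks on a common canvas.
#' @param match_iou Matching threshold, default 0.5.
#' @return List with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
detection_prf <- function(predicted, truth, match_iou = 0.5) {
  np <- length(predicted); nt <- length(truth)
  pairs <- NULL
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    iou <- mask_iou(predicted[[i]], truth[[j]])
    if (iou >= match_iou) pairs <- rbind(pairs, c(i, j, iou))
  }
  tp <- 0
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs[, 3]), , drop = FALSE]
    pu <- rep(FALSE, np); tu <- rep(FALSE, nt)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (pu[i] || tu[j]) next
      pu[i] <- TRUE; tu[j] <- TRUE
      tp <- tp + 1
    }
  }
  fp <- np - tp; fn <- nt - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Is a reconstructed branch correct?
#'
#' A reconstructed branch counts as correct when its pixel IoU with the
#' ground-truth branch mask is strictly greater than `threshold`
#' (default 0.9).
#'
#' @param chain_mask,gt_branch_mask Logical masks on a common canvas; the
#'   ground-truth mask must be non-empty.
#' @param threshold Strict IoU threshold.
#' @return Logical.
#' @export
branch_correct <- function(chain_mask, gt_branch_mask, threshold = 0.9) {
  if (!any(gt_branch_mask)) stop("ground-truth branch mask is empty")
  mask_iou(chain_mask, gt_branch_mask) > threshold
}

#' Reconstruction accuracy
#'
#' Percentage of ground-truth branches that were reconstructed correctly:
#' 100 * R_b / G_b.
#'
#' @param correct_count Number of correctly reconstructed branches (R_b).
#' @param total Number of ground-truth branches (G_b); must be positive.
#' @return Percentage in \[0, 100\].
#' @export
acc_r <- function(correct_count, total) {
  if (total <= 0) stop("acc_r() requires a positive number of ground-truth branches")
  100 * correct_count / total
}

#' Mean reconstruction IoU
#'
#' 100 times the mean of per-branch pixel IoUs between reconstructed and
#' ground-truth branch masks.
#'
#' @param pairs Non-empty list of list(reconstructed mask, truth mask)
#'   pairs, or a numeric vector of precomputed per-branch IoUs.
#' @return Percentage in \[0, 100\].
#' @export
miou <- function(pairs) {
  if (length(pairs) == 0) stop("miou() requires at least one branch pair")
  ious <- if (is.numeric(pairs)) pairs
          else vapply(pairs, function(p) mask_iou(p[[1]], p[[2]]), numeric(1))
  100 * mean(ious)
}

#' Mean absolute and relative diameter errors
#'
#' E_a is the mean absolute difference between reconstructed and measured
#' branch diameters in pixels; E_r is 100 times the mean of per-branch
#' relative errors |D_r - D_g| / D_g.
#'
#' @param D_r Reconstructed diameters (px).
#' @param D_g Measured (ground-truth) diameters (px); all must be positive.
#' @return List with `e_a` (px) and `e_r` (percent).
#' @export
diameter_errors <- function(D_r, D_g) {
  stopifnot(length(D_r) == length(D_g), length(D_g) > 0)
  if (any(D_g <= 0)) stop("ground-truth diameters must be positive")
  err <- abs(D_r - D_g)
  list(e_a = mean(err), e_r = 100 * mean(err / D_g))
}

#' Evaluate a reconstruction against ground truth
#'
#' Matches reconstructed chains to ground-truth branches one-to-one greedily
#' by decreasing mask IoU, then reports the reconstruction accuracy (share
#' of ground-truth branches whose matched chain exceeds the strict IoU
#' correctness threshold), the mean IoU over ground-truth branches
#' (unmatched branches contribute 0), and the diameter errors over matched
#' pairs.
#'
#' @param chains List of `branch_chain` objects (with `mask`, `diameter`).
#' @param gt_masks List of ground-truth full-branch masks.
#' @param gt_diameters Optional numeric vector of ground-truth diameters
#'   (px), parallel to `gt_masks`.
#' @param control A [recon_control()] (for `correct_branch_iou`).
#' @return A `metrics_report`: `acc_r`, `miou`, `e_a`, `e_r`, `r_b`, `g_b`,
#'   and a `per_branch` data frame (gt index, matched chain id, iou,
#'   correct, D_r, D_g).
#' @export
evaluate_reconstruction <- function(chains, gt_masks, gt_diameters = NULL,
                                    control = recon_control()) {
  gb <- length(gt_masks)
  if (gb == 0) stop("no ground-truth branches to evaluate against")
  nc <- length(chains)
  iou_mat <- matrix(0, nc, gb)
  for (i in seq_len(nc)) for (j in seq_len(gb))
    iou_mat[i, j] <- mask_iou(chains[[i]]$mask, gt_masks[[j]])
  matched_chain <- rep(NA_integer_, gb)
  matched_iou <- rep(0, gb)
  if (nc > 0) {
    flat <- order(-iou_mat)
    cu <- rep(FALSE, nc); gu <- rep(FALSE, gb)
    for (f in flat) {
      if (iou_mat[f] <= 0) break
      i <- (f - 1) %% nc + 1
      j <- (f - 1) %/% nc + 1
      if (cu[i] || gu[j]) next
      cu[i] <- TRUE; gu[j] <- TRUE
      matched_chain[j] <- i
      matched_iou[j] <- iou_mat[i, j]
    }
  }
  correct <- matched_iou > control$correct_branch_iou
  rb <- sum(correct)
  d_r <- rep(NA_real_, gb)
  for (j in seq_len(gb))
    if (!is.na(matched_chain[j])) d_r[j] <- chains[[matched_chain[j]]]$diameter
  d_g <- if (is.null(gt_diameters)) rep(NA_real_, gb) else gt_diameters
  ok <- !is.na(d_r) & !is.na(d_g)
  derr <- if (any(ok)) diameter_errors(d_r[ok], d_g[ok])
          else list(e_a = NA_real_, e_r = NA_real_)
  structure(list(
    acc_r = acc_r(rb, gb),
    miou = miou(matched_iou),
    e_a = derr$e_a,
    e_r = derr$e_r,
    r_b = rb,
    g_b = gb,
    n_chains = nc,
    per_branch = data.frame(gt = seq_len(gb), chain = matched_chain,
                            iou = matched_iou, correct = correct,
                            D_r = d_r, D_g = d_g)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Branch reconstruction evaluation\n")
  cat(sprintf("  Reconstruction accuracy (Acc_r)  %6.2f %%  (%d / %d branches)\n",
              x$acc_r, x$r_b, x$g_b))
  cat(sprintf("  Mean branch IoU (mIoU)           %6.2f %%\n", x$miou))
  if (!is.na(x$e_a))
    cat(sprintf("  Diameter error (E_a)             %6.2f px\n", x$e_a))
  if (!is.na(x$e_r))
    cat(sprintf("  Relative diameter error (E_r)    %6.2f %%\n", x$e_r))
  cat(sprintf("  Reconstructed chains             %d\n", x$n_chains))
  invisible(x)
}
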