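#' Control parameters for branch reconstruction
#'
#' All tunables of the pipeline with their standard defaults. Unknown
#' parameter names are a hard error, so typos cannot silently fall back to
#' defaults.
#'
#' @param iou_dedup Rectangle IoU above which two segmented detections are
#'   duplicates; the smaller is discarded. Default 0.15.
#' @param depth_factor_segment Sector search depth for segment candidates,
#'   as a multiple of the local axis window `dis`. Default 3.
#' @param depth_factor_fork Sector search depth for fork candidates.
#'   Default 1.6.
#' @param free_depth_factor Relaxed search depth used by the secondary
#'   gap-bridging pass. Default 5.
#' @param bifurcation_angle_deg Interior angle at a shared fork above which
#'   a secondary chain is joined to its main chain; 100 degrees separates a
#'   straight continuation (about 180) from a perpendicular side branch
#'   (about 90) with margin for bent branches.
#' @param correct_branch_iou Mask IoU above which a reconstructed branch
#'   counts as correct. Default 0.9 (strict inequality).
#' @param match_iou IoU threshold for one-to-one detection matching in
#'   precision/recall/F1. Default 0.5.
#' @param prune_isolated Remove single-fragment chains with no fork (mostly
#'   mis-detected leaves and petioles). Default TRUE.
#' @param secondary Run the secondary connection passes (joining chains
#'   across shared forks and across gaps left by missed detections).
#'   Default TRUE.
#' @return A `recon_control` list.
#' @export
recon_control <- function(iou_dedup = 0.15,
                          depth_factor_segment = 3.0,
                          depth_factor_fork = 1.6,
                          free_depth_factor = 5.0,
                          bifurcation_angle_deg = 100,
                          correct_branch_iou = 0.9,
                          match_iou = 0.5,
                          prune_isolated = TRUE,
                          secondary = TRUE) {
  ctl <- list(iou_dedup = iou_dedup,
              depth_factor_segment = depth_factor_segment,
              depth_factor_fork = depth_factor_fork,
              free_depth_factor = free_depth_factor,
              bifurcation_angle_deg = bifurcation_angle_deg,
              correct_branch_iou = correct_branch_iou,
              match_iou = match_iou,
              prune_isolated = prune_isolated,
              secondary = secondary)
  stopifnot(ctl$iou_dedup > 0, ctl$iou_dedup < 1,
            ctl$depth_factor_segment > 0, ctl$depth_factor_fork > 0,
            ctl$free_depth_factor > 0,
            ctl$bifurcation_angle_deg > 0, ctl$bifurcation_angle_deg < 180,
            ctl$correct_branch_iou > 0, ctl$correct_branch_iou < 1,
            is.logical(ctl$prune_isolated), is.logical(ctl$secondary))
  structure(ctl, class = "recon_control")
}

# Merge user-supplied overrides (a named list) into a control object,
# erroring on unknown keys.
.apply_overrides <- function(control, overrides) {
  if (length(overrides) == 0) return(control)
  bad <- setdiff(names(overrides), names(control))
  if (length(bad) > 0)
    stop("unknown control parameter(s): ", paste(bad, collapse = ", "))
  args <- unclass(control)
  args[names(overrides)] <- overrides
  do.call(recon_control, args)
}
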