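#' Reconstruct branches from a scene of instance masks
#'
#' The main entry point: runs the full reconstruction pipeline of
#' [reconstruct_scene()] on an instance set and returns a classed result
#' holding the reconstructed chains together with per-stage bookkeeping.
#'
#' @param x An `instance_set` (see [load_instances()], [instance_set()],
#'   [generate_scene()]).
#' @param control A [recon_control()]; individual parameters may also be
#'   passed through `...` as overrides.
#' @param ... Named control overrides, e.g. `iou_dedup = 0.2`. Unknown
#'   names are an error.
#' @return A `branch_recon` object: `chains` (list of `branch_chain`),
#'   `control`, `image_size`, and `counts` (instances in, segments and
#'   forks modeled, segments after dedup, chains out).
#' @examples
#' scene <- generate_scene(scene_spec(n_branches = 2, seed = 7))
#' fit <- reconstruct_branches(scene$instances)
#' fit
#' @export
reconstruct_branches <- function(x, control = recon_control(), ...) {
  stopifnot(inherits(x, "instance_set"))
  control <- .apply_overrides(control, list(...))
  bm <- build_models(x)
  segs <- dedup(bm$segments, control$iou_dedup)
  chains <- reconstruct(segs, bm$forks, control)
  n_primary <- length(chains)
  if (isTRUE(control$secondary)) {
    chains <- connect_at_fork(chains, bm$forks, control$bifurcation_angle_deg)
    chains <- connect_free(chains, control)
  }
  chains <- prune_isolated(chains, control$prune_isolated)
  chains <- lapply(seq_along(chains), function(i)
    .finalize_chain(chains[[i]], i, x$image_size))
  structure(list(
    chains = chains,
    control = control,
    image_size = x$image_size,
    counts = c(instances = length(x$instances),
               segments = length(bm$segments),
               forks = length(bm$forks),
               segments_after_dedup = length(segs),
               chains_primary = n_primary,
               chains = length(chains))
  ), class = "branch_recon")
}

#' @export
print.branch_recon <- function(x, ...) {
  cat(sprintf("Branch reconstruction: %d chain(s) from %d instance(s) (%d x %d px)\n",
              length(x$chains), x$counts["instances"],
              x$image_size[1], x$image_size[2]))
  cat(sprintf("  %d segment model(s), %d after dedup; %d fork(s)\n",
              x$counts["segments"], x$counts["segments_after_dedup"],
              x$counts["forks"]))
  invisible(x)
}

#' @export
summary.branch_recon <- function(object, ...) {
  ch <- object$chains
  df <- data.frame(
    chain = vapply(ch, function(c) as.integer(c$id), integer(1)),
    members = vapply(ch, function(c) length(c$members), integer(1)),
    segments = vapply(ch, function(c)
      sum(vapply(c$members, function(m) m$kind == "segment", logical(1))),
      integer(1)),
    forks = vapply(ch, function(c)
      sum(vapply(c$members, function(m) m$kind == "fork", logical(1))),
      integer(1)),
    axis_points = vapply(ch, function(c) nrow(c$V), integer(1)),
    diameter_px = vapply(ch, function(c) c$diameter, numeric(1)),
    area_px = vapply(ch, function(c) sum(c$mask), numeric(1))
  )
  structure(list(table = df, counts = object$counts,
                 control = object$control),
            class = "summary.branch_recon")
}

#' @export
print.summary.branch_recon <- function(x, ...) {
  cat("Branch reconstruction summary\n")
  cat("Stage counts:\n")
  print(x$counts)
  cat("\nChains:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot reconstructed chains as a colored overlay
#'
#' @param x A `branch_recon`.
#' @param axes Draw the merged axis polylines on top.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.branch_recon <- function(x, axes = TRUE, ...) {
  img <- render_overlay(x$chains, x$image_size)
  h <- x$image_size[1]; w <- x$image_size[2]
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", ...)
  graphics::rasterImage(grDevices::as.raster(img), 0, h, w, 0)
  if (axes) {
    for (ch in x$chains)
      graphics::lines(ch$V[, 1], ch$V[, 2], col = "white", lwd = 1.5)
  }
  invisible(x)
}
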