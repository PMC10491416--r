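# Seeded synthetic vine scenes with ground truth.
#
# The generator emulates the statistical structure the reconstruction
# assumes: smooth curved branches of roughly constant width, fragmented
# into quadrilateral instances with long/short aspect ratio in [2, 4],
# near-square fork instances at bifurcations, and the common failure modes
# of an instance-segmentation model (missed detections, duplicated masks,
# small non-branch false positives). Branches run predominantly downward,
# each in its own vertical strip, so scenes are unambiguous by
# construction; distractors are placed in the top margin between branch
# heads, outside every search cone, so they remain isolated singletons.

#' Specification of a synthetic vine scene
#'
#' @param image_size c(height, width) px.
#' @param n_branches Number of main branches (one per vertical strip).
#' @param curvature_scale Maximum per-segment heading change, radians.
#' @param branch_width_range Per-branch constant width, px (uniform).
#' @param fork_probability Chance that a main branch carries one
#'   bifurcation with a child branch.
#' @param segment_aspect_range Long/short ratio of segment quadrilaterals
#'   (uniform); the annotation convention guarantees \[2, 4\].
#' @param gap_range Gap between consecutive segment quadrilaterals, px.
#' @param dropout_rate Per-segment missed-detection probability.
#' @param duplicate_rate Per-segment probability of an extra jittered
#'   duplicate mask (overlapping the original well above the 0.15 dedup
#'   threshold).
#' @param distractor_count Number of small near-square non-branch instances
#'   (leaf/petiole stand-ins).
#' @param seed Integer RNG seed; scenes are fully deterministic given the
#'   spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(600, 600),
                       n_branches = 5,
                       curvature_scale = 0.12,
                       branch_width_range = c(8, 14),
                       fork_probability = 0.25,
                       segment_aspect_range = c(2, 4),
                       gap_range = c(2, 5),
                       dropout_rate = 0,
                       duplicate_rate = 0,
                       distractor_count = 3,
                       seed = 1) {
  spec <- list(image_size = as.integer(image_size), n_branches = n_branches,
               curvature_scale = curvature_scale,
               branch_width_range = branch_width_range,
               fork_probability = fork_probability,
               segment_aspect_range = segment_aspect_range,
               gap_range = gap_range, dropout_rate = dropout_rate,
               duplicate_rate = duplicate_rate,
               distractor_count = distractor_count, seed = as.integer(seed))
  stopifnot(all(spec$image_size > 0),
            spec$n_branches >= 1,
            spec$curvature_scale >= 0,
            all(spec$branch_width_range > 0),
            spec$fork_probability >= 0, spec$fork_probability <= 1,
            all(spec$segment_aspect_range >= 1),
            spec$dropout_rate >= 0, spec$dropout_rate <= 1,
            spec$duplicate_rate >= 0, spec$duplicate_rate <= 1,
            spec$distractor_count >= 0)
  if (max(spec$branch_width_range) * 4 > min(spec$image_size))
    stop("branch width is infeasible for this image size")
  structure(spec, class = "scene_spec")
}

# quadrilateral (4 corners, clockwise) for a straight piece from point p of
# length len and width wd along unit direction d
.quad_for <- function(p, d, len, wd) {
  nrm <- c(-d[2], d[1])
  q <- p + len * d
  rbind(p + wd / 2 * nrm, p - wd / 2 * nrm,
        q - wd / 2 * nrm, q + wd / 2 * nrm)
}

.dir <- function(phi) c(sin(phi), cos(phi))  # heading: 0 = straight down

# walk one branch; returns segment quads plus the junction geometry needed
# to hang a fork and child branch off it
.walk_branch <- function(p, phi, wd, n_seg, spec, xlim, mode = c("main", "child")) {
  mode <- match.arg(mode)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cs <- spec$curvature_scale
  aspect_range <- spec$segment_aspect_range
  if (mode == "child") {
    # side branches leave the fork at a steep angle and curve back; shorter
    # quads follow the stronger curvature
    aspect_range <- c(aspect_range[1], min(aspect_range[1] + 0.8, aspect_range[2]))
  }
  segs <- list()
  for (k in seq_len(n_seg)) {
    # heading update for the *next* segment; the per-step change is always
    # bounded (main: curvature_scale; child: twice that, still inside the
    # child's own sector half-angle) so the reverse alignment check of the
    # sector search holds along the branch, even while steering back toward
    # the strip interior
    if (mode == "main") {
      phi_next <- phi + stats::runif(1, -cs, cs)
      if (p[1] < xlim[1]) phi_next <- phi + cs
      else if (p[1] > xlim[2]) phi_next <- phi - cs
      phi_next <- max(-0.3, min(0.3, phi_next))
    } else {
      phi_next <- 0.8 * phi + 0.5 * stats::runif(1, -cs, cs)
      if (p[1] < xlim[1]) phi_next <- phi_next + cs
      else if (p[1] > xlim[2]) phi_next <- phi_next - cs
      phi_next <- max(-1.0, min(1.0, phi_next))
      phi_next <- phi + max(-2 * cs, min(2 * cs, phi_next - phi))
    }
    turn <- phi_next - phi
    aspect <- stats::runif(1, aspect_range[1], aspect_range[2])
    # tighter quads where the branch bends harder
    if (cs > 0 && abs(turn) > 0.5 * cs)
      aspect <- max(spec$segment_aspect_range[1], 0.75 * aspect)
    len <- aspect * wd
    d <- .dir(phi)
    q <- p + len * d
    if (q[2] > h - 18 || q[1] < 12 || q[1] > w - 12 || q[2] < 12) break
    segs[[length(segs) + 1]] <- list(
      quad = .quad_for(p, d, len, wd),
      start = p, end = q, dir = d, len = len)
    gap <- stats::runif(1, spec$gap_range[1], spec$gap_range[2])
    p <- q + gap * d
    phi <- phi_next
    segs[[length(segs)]]$gap_after <- gap
  }
  segs
}

#' Generate a synthetic vine scene with ground truth
#'
#' See [scene_spec()] for what is emulated. Fully deterministic given the
#' spec (the global RNG state is saved and restored). Dropped-out segments
#' are omitted from the returned instance set but remain in the ground
#' truth, whose full-branch masks are the union of the branch's segment
#' masks (plus incident forks) before dropout.
#'
#' @param spec A [scene_spec()].
#' @return List with `instances` (an `instance_set`), and `truth`:
#'   `branches` (per branch: `id`, `mask`, `diameter`, `instance_ids`),
#'   `instance_table` (data frame: id, branch, role, dropped), and `forks`
#'   (data frame: instance id, x, y, parent and child branch ids).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- spec$n_branches
  strip_w <- w / n

  branches <- list()   # per-branch: quads, fork quad, width
  records <- list()    # per-instance creation records
  add_record <- function(polygon, label, branch, role) {
    records[[length(records) + 1]] <<-
      list(polygon = polygon, label = label, branch = branch, role = role)
    length(records)
  }

  fork_tab <- NULL
  n_children <- 0
  for (b in seq_len(n)) {
    x_lo <- (b - 1) * strip_w; x_hi <- b * strip_w
    xlim <- c(x_lo + 0.3 * strip_w, x_hi - 0.3 * strip_w)
    wd <- stats::runif(1, spec$branch_width_range[1], spec$branch_width_range[2])
    start <- c(stats::runif(1, xlim[1], xlim[2]), 25)
    phi0 <- stats::runif(1, -0.15, 0.15)
    n_seg <- sample(4:8, 1)
    segs <- .walk_branch(start, phi0, wd, n_seg, spec, xlim, mode = "main")
    if (length(segs) == 0) next
    seg_ids <- integer(0)
    for (s in segs)
      seg_ids <- c(seg_ids, add_record(s$quad, "segmented", b, "segment"))
    branches[[b]] <- list(id = b, width = wd, segs = segs,
                          instance_ids = seg_ids, fork_id = NA)

    # optionally hang a fork + child branch off an interior junction
    if (stats::runif(1) < spec$fork_probability && length(segs) >= 4) {
      j <- if (length(segs) == 4) 2 else sample(2:(length(segs) - 2), 1)
      sj <- segs[[j]]
      gap <- if (is.null(sj$gap_after)) mean(spec$gap_range) else sj$gap_after
      junction <- sj$end + (gap / 2) * sj$dir
      phi_j <- atan2(sj$dir[1], sj$dir[2])
      side_l <- 1.3 * wd; side_s <- 1.15 * wd
      fq <- .quad_for(junction - (side_l / 2) * sj$dir, sj$dir, side_l, side_s)
      fid <- add_record(fq, "forked", b, "fork")
      branches[[b]]$fork_id <- fid
      branches[[b]]$fork_quad <- fq

      strip_center <- (x_lo + x_hi) / 2
      side_sign <- if (abs(junction[1] - strip_center) < 1) sample(c(-1, 1), 1)
                   else sign(strip_center - junction[1])
      delta <- stats::runif(1, 0.58, 0.7) * side_sign
      phi_c <- phi_j + delta
      wd_c <- max(5, wd * stats::runif(1, 0.7, 0.9))
      d_c <- .dir(phi_c)
      child_start <- junction + (0.7 * side_l + mean(spec$gap_range)) * d_c
      csegs <- .walk_branch(child_start, phi_c, wd_c, sample(3:4, 1),
                            spec, xlim, mode = "child")
      if (length(csegs) > 0) {
        n_children <- n_children + 1
        cb <- as.integer(n + n_children)
        cids <- integer(0)
        for (s in csegs)
          cids <- c(cids, add_record(s$quad, "segmented", cb, "segment"))
        branches[[cb]] <- list(id = cb, width = wd_c, segs = csegs,
                               instance_ids = cids, fork_id = fid,
                               fork_quad = fq, parent = b)
        fork_tab <- rbind(fork_tab,
                          data.frame(id = fid, x = junction[1], y = junction[2],
                                     parent_branch = b, child_branch = cb))
      } else {
        fork_tab <- rbind(fork_tab,
                          data.frame(id = fid, x = junction[1], y = junction[2],
                                     parent_branch = b, child_branch = NA))
      }
    }
  }
  branches <- Filter(Negate(is.null), branches)

  # dropout of segment instances (ground truth keeps them)
  dropped <- rep(FALSE, length(records))
  if (spec$dropout_rate > 0) {
    for (k in seq_along(records))
      if (records[[k]]$role == "segment" &&
          stats::runif(1) < spec$dropout_rate) dropped[k] <- TRUE
  }

  # duplicated detections: jittered copies of surviving segments
  if (spec$duplicate_rate > 0) {
    for (k in seq_along(records)) {
      r <- records[[k]]
      if (r$role != "segment" || dropped[k]) next
      if (stats::runif(1) < spec$duplicate_rate) {
        shift <- stats::runif(2, -1.8, 1.8)
        poly <- sweep(r$polygon, 2, shift, "+")
        add_record(poly, "segmented", r$branch, "duplicate")
        dropped <- c(dropped, FALSE)
      }
    }
  }

  # distractors: small near-square blobs in the top margin midway between
  # branch heads, clear of every chain terminal's search cone
  if (spec$distractor_count > 0) {
    slots <- (seq_len(n + 1) - 1) * strip_w
    slots <- pmin(pmax(slots, 18), w - 18)
    slots <- sample(slots)
    for (k in seq_len(min(spec$distractor_count, length(slots)))) {
      s <- stats::runif(1, 7, 11)
      th <- stats::runif(1, 0, pi)
      ctr <- c(slots[k] + stats::runif(1, -6, 6), stats::runif(1, 15, 45))
      poly <- .quad_for(ctr - (s * 1.1 / 2) * .dir(th), .dir(th),
                        s * 1.1, s)
      add_record(poly, "segmented", NA, "distractor")
      dropped <- c(dropped, FALSE)
    }
  }

  # rasterize
  masks <- lapply(records, function(r) rasterize_polygon(r$polygon, spec$image_size))

  insts <- list()
  for (k in seq_along(records)) {
    if (dropped[k]) next
    if (!any(masks[[k]])) next
    insts[[length(insts) + 1]] <- list(mask = masks[[k]],
                                       label = records[[k]]$label,
                                       id = k,
                                       polygon = records[[k]]$polygon)
  }

  gt_branches <- lapply(branches, function(br) {
    m <- matrix(FALSE, h, w)
    for (iid in br$instance_ids) m <- m | masks[[iid]]
    if (!is.na(br$fork_id)) m <- m | masks[[br$fork_id]]
    ids <- br$instance_ids
    if (!is.na(br$fork_id)) ids <- c(ids, br$fork_id)
    list(id = br$id, mask = m, diameter = br$width, instance_ids = ids)
  })

  itab <- data.frame(
    id = seq_along(records),
    branch = vapply(records, function(r)
      if (is.na(r$branch[1])) NA_integer_ else as.integer(r$branch), integer(1)),
    role = vapply(records, `[[`, character(1), "role"),
    dropped = dropped
  )

  list(instances = instance_set(spec$image_size, insts),
       truth = list(branches = gt_branches, instance_table = itab,
                    forks = fork_tab),
       spec = spec)
}
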