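# Secondary connection: repairing chains that the primary pass left split
# at shared bifurcations or across gaps from missed detections and
# occlusion, then pruning isolated fragments (mostly mis-detected leaves
# and petioles).

#' Group chains around a shared fork
#'
#' At a bifurcation the chain whose tail node is the fork is a main branch;
#' a chain whose top node is the fork is a secondary branch.
#'
#' @param chains List of chains.
#' @param fork_id Fork instance id.
#' @return List with `fork_id`, `main_idx` and `secondary_idx` (indices into
#'   `chains`).
#' @export
fork_group <- function(chains, fork_id) {
  is_main <- vapply(chains, function(ch)
    !is.null(ch$end_fork) && ch$end_fork == fork_id, logical(1))
  is_sec <- vapply(chains, function(ch)
    !is.null(ch$top_fork) && ch$top_fork == fork_id, logical(1))
  list(fork_id = fork_id, main_idx = which(is_main), secondary_idx = which(is_sec))
}

# interior angle at the fork between the main chain (ray to its second-to-
# last axis point) and a secondary chain (ray to its second axis point):
# a straight continuation gives ~180 degrees, a perpendicular side branch ~90.
.fork_angle <- function(main, secondary, fork_center) {
  n <- nrow(main$V)
  u <- main$V[n - 1, ] - fork_center
  v <- secondary$V[2, ] - fork_center
  angle_between(u, v)
}

#' Join chains across shared bifurcations
#'
#' For every fork, each main chain is paired with the secondary chain that
#' maximises the interior angle at the fork; the pair is joined only when
#' that maximum exceeds `angle_threshold` (default 100 degrees), so a
#' straight continuation through the fork reconnects while a roughly
#' perpendicular side branch stays its own branch. Pairings are resolved
#' best-angle-first; a secondary joins at most one main. The joined axis is
#' main axis, fork center, secondary axis.
#'
#' @param chains List of chains.
#' @param forks List of forks (for center coordinates).
#' @param angle_threshold Degrees; default 100.
#' @return Updated chain list.
#' @export
connect_at_fork <- function(chains, forks, angle_threshold = 100) {
  fork_ids <- sort(vapply(forks, function(f) as.integer(f$id), integer(1)))
  for (fid in fork_ids) {
    fk <- Find(function(f) f$id == fid, forks)
    grp <- fork_group(chains, fid)
    if (length(grp$main_idx) == 0 || length(grp$secondary_idx) == 0) next
    cand <- NULL
    for (mi in grp$main_idx) for (si in grp$secondary_idx) {
      if (mi == si) next
      a <- .fork_angle(chains[[mi]], chains[[si]], fk$center)
      if (a > angle_threshold) cand <- rbind(cand, c(mi, si, a))
    }
    if (is.null(cand)) next
    cand <- cand[order(-cand[, 3]), , drop = FALSE]
    used_main <- integer(0); used_sec <- integer(0)
    merged <- list()  # main idx -> new chain
    for (k in seq_len(nrow(cand))) {
      mi <- cand[k, 1]; si <- cand[k, 2]
      if (mi %in% used_main || si %in% used_sec || si %in% used_main) next
      main <- chains[[mi]]; sec <- chains[[si]]
      new <- main
      new$V <- rbind(main$V, matrix(fk$center, 1), sec$V)
      new$W_end <- sec$W_end
      new$end_fork <- sec$end_fork
      # the fork member is present in both; keep the main's copy only
      sec_members <- Filter(function(m) !(m$kind == "fork" && m$id == fid),
                            sec$members)
      if (!any(vapply(main$members, function(m)
            m$kind == "fork" && m$id == fid, logical(1)))) {
        # main may have passed the junction without attaching the fork
        sec_members <- c(list(list(id = fid, kind = "fork", rect = fk$rect)),
                         sec_members)
      }
      new$members <- c(main$members, sec_members)
      merged[[as.character(mi)]] <- new
      used_main <- c(used_main, mi)
      used_sec <- c(used_sec, si)
    }
    if (length(used_sec) > 0) {
      for (mi in names(merged)) chains[[as.integer(mi)]] <- merged[[mi]]
      chains <- chains[-used_sec]
    }
  }
  chains
}

#' Join chain fragments across detection gaps
#'
#' Second-pass bridging of chains split by missed detections or occlusion,
#' using a relaxed sector: the offset angle may reach the full sector angle
#' (double the primary half-angle), the depth reaches
#' `free_depth_factor * dis` (default 5), and a deflection constraint is
#' applied to both chains: the angle between each chain's terminal axis
#' direction and the line joining the two facing terminals must not exceed
#' half that chain's terminal sector angle. The deflection test is what
#' rejects parallel side-by-side branches, whose joining line is roughly
#' perpendicular to both axes. Qualifying pairs are merged nearest-first,
#' iterating to a fixpoint; sides already closed by a fork do not
#' participate.
#'
#' @param chains List of chains.
#' @param control A [recon_control()].
#' @return Updated chain list.
#' @export
connect_free <- function(chains, control = recon_control()) {
  repeat {
    n <- length(chains)
    if (n < 2) return(chains)
    cand <- NULL
    for (ai in seq_len(n)) {
      A <- chains[[ai]]
      if (!is.null(A$top_fork)) next
      specA <- sector_for(A, "top", control$free_depth_factor)
      termA <- A$V[1, ]
      for (bi in seq_len(n)) {
        if (bi == ai) next
        B <- chains[[bi]]
        if (!is.null(B$end_fork)) next
        nb <- nrow(B$V)
        termB <- B$V[nb, ]
        if (!in_sector(specA, termB, half_angle_scale = 2)) next
        join <- termB - termA
        if (sum(join^2) < 1e-18) next
        specB <- sector_for(B, "end", control$free_depth_factor)
        alphaA <- angle_between(specA$center_ray, join)
        alphaB <- angle_between(specB$center_ray, -join)
        if (alphaA > specA$full_angle / 2 + 1e-7) next
        if (alphaB > specB$full_angle / 2 + 1e-7) next
        cand <- rbind(cand, c(ai, bi, sqrt(sum(join^2))))
      }
    }
    if (is.null(cand)) return(chains)
    cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    touched <- rep(FALSE, n)   # chains involved in a merge this pass
    consumed <- rep(FALSE, n)  # chains absorbed into another
    out <- chains
    for (k in seq_len(nrow(cand))) {
      ai <- cand[k, 1]; bi <- cand[k, 2]
      if (touched[ai] || touched[bi]) next
      A <- chains[[ai]]; B <- chains[[bi]]
      new <- B
      new$V <- rbind(B$V, A$V)
      new$W_end <- A$W_end
      new$end_fork <- A$end_fork
      new$members <- c(B$members, A$members)
      out[[bi]] <- new
      touched[ai] <- TRUE; touched[bi] <- TRUE
      consumed[ai] <- TRUE
    }
    if (!any(consumed)) return(chains)
    chains <- out[!consumed]
  }
}

#' Remove isolated single-fragment chains
#'
#' Chains consisting of exactly one segmented fragment and no fork are, in
#' practice, mis-detected leaves or petioles rather than branches and are
#' deleted from the final result.
#'
#' @param chains List of chains.
#' @param enabled When FALSE, returns the input unchanged.
#' @return Filtered chain list.
#' @export
prune_isolated <- function(chains, enabled = TRUE) {
  if (!enabled) return(chains)
  Filter(function(ch) {
    !(length(ch$members) == 1 && ch$members[[1]]$kind == "segment")
  }, chains)
}

#' Length-weighted diameter estimate of a chain
#'
#' The rectangles are the only width-bearing primitive of the
#' reconstruction, so the branch diameter is estimated as the mean of the
#' member rectangles' short sides weighted by their long sides (longer
#' fragments carry more of the branch).
#'
#' @param chain A chain with at least one member rectangle.
#' @return Diameter in pixels.
#' @export
chain_diameter <- function(chain) {
  s <- vapply(chain$members, function(m) m$rect$short_len, numeric(1))
  l <- vapply(chain$members, function(m) m$rect$long_len, numeric(1))
  if (sum(l) < 1e-12) return(mean(s))
  sum(s * l) / sum(l)
}

# finalize a chain: render its mask as the union of member rectangle
# polygons (fork rectangles included) and attach the diameter estimate.
.finalize_chain <- function(chain, chain_id, image_size) {
  mask <- matrix(FALSE, image_size[1], image_size[2])
  for (m in chain$members)
    mask <- mask | rasterize_polygon(m$rect$corners, image_size)
  structure(list(
    id = chain_id,
    members = chain$members,
    V = chain$V,
    W_top = chain$W_top,
    W_end = chain$W_end,
    top_fork = chain$top_fork,
    end_fork = chain$end_fork,
    mask = mask,
    diameter = chain_diameter(chain)
  ), class = "branch_chain")
}

#' Full branch reconstruction pipeline for one scene
#'
#' Runs the whole pipeline: simplify instances to rectangle models, discard
#' duplicate detections, group fragments by bidirectional sector search,
#' join chains across shared forks and across detection gaps (when
#' `control$secondary` is TRUE), and prune isolated fragments. Each
#' resulting chain carries its ordered members, merged axis polyline,
#' rendered mask (union of member rectangles) and estimated diameter.
#'
#' @param instances An `instance_set`.
#' @param control A [recon_control()].
#' @return List of `branch_chain` objects (empty for an empty scene).
#' @export
reconstruct_scene <- function(instances, control = recon_control()) {
  if (length(instances$instances) == 0) return(list())
  bm <- build_models(instances)
  segs <- dedup(bm$segments, control$iou_dedup)
  chains <- reconstruct(segs, bm$forks, control)
  if (isTRUE(control$secondary)) {
    chains <- connect_at_fork(chains, bm$forks, control$bifurcation_angle_deg)
    chains <- connect_free(chains, control)
  }
  chains <- prune_isolated(chains, control$prune_isolated)
  lapply(seq_along(chains), function(i)
    .finalize_chain(chains[[i]], i, instances$image_size))
}
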