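# Primary reconstruction: bidirectional sector search.
#
# Each chain grows from both terminals. On a side, a cone-shaped sector is
# anchored at the interior axis point next to the terminal, bounded by the
# rays through that side's rectangle corners, and limited in depth to a
# multiple of the local axis window. Segment candidates must place their
# facing terminal inside the sector and pass a reverse alignment check;
# fork candidates need only their center inside a shallower sector. The
# nearest qualifying candidate is merged; a fork closes the side.

#' Find merge candidates for one side of a chain
#'
#' A segment candidate qualifies when its facing terminal axis point (its
#' last point for the chain's top side, its first for the end side) lies in
#' the chain's sector with depth `depth_factor_segment * dis`, and the
#' reverse check passes: the angle between the chain's center ray and the
#' candidate's facing axis direction (pointing into the candidate) is at
#' most half the sector angle, which suppresses captures across adjacent
#' branches. A fork qualifies when its center lies in the shallower sector
#' with depth `depth_factor_fork * dis`; forks carry no axis, so no reverse
#' check applies. Distances are measured from the chain's terminal point to
#' the candidate's facing point (the gap between tips), since branches grow
#' at their ends.
#'
#' @param target The growing `branch_segment` chain.
#' @param side `"top"` or `"end"`.
#' @param segments Candidate segment models; must exclude `target` and
#'   already-consumed members.
#' @param forks List of forks.
#' @param control A [recon_control()].
#' @return List of marks: `candidate_id`, `side`, `kind` ("segment" or
#'   "fork"), `distance` (px), `passed_reverse_check`.
#' @export
find_candidates <- function(target, side = c("top", "end"), segments, forks,
                            control = recon_control()) {
  side <- match.arg(side)
  n <- nrow(target$V)
  term <- if (side == "top") target$V[1, ] else target$V[n, ]
  spec_seg <- sector_for(target, side, control$depth_factor_segment)
  spec_fork <- sector_for(target, side, control$depth_factor_fork)
  half <- spec_seg$full_angle / 2
  marks <- list()
  for (cand in segments) {
    m <- nrow(cand$V)
    if (side == "top") {
      facing <- cand$V[m, ]
      facing_dir <- cand$V[m - 1, ] - cand$V[m, ]
    } else {
      facing <- cand$V[1, ]
      facing_dir <- cand$V[2, ] - cand$V[1, ]
    }
    if (!in_sector(spec_seg, facing)) next
    if (sum(facing_dir^2) < 1e-18) next
    rev_ok <- angle_between(spec_seg$center_ray, facing_dir) <= half + 1e-7
    if (!rev_ok) next
    marks[[length(marks) + 1]] <- list(
      candidate_id = cand$id, side = side, kind = "segment",
      distance = sqrt(sum((term - facing)^2)), passed_reverse_check = TRUE)
  }
  for (fk in forks) {
    if (!in_sector(spec_fork, fk$center)) next
    marks[[length(marks) + 1]] <- list(
      candidate_id = fk$id, side = side, kind = "fork",
      distance = sqrt(sum((term - fk$center)^2)), passed_reverse_check = NA)
  }
  marks
}

#' Merge a marked candidate into a chain
#'
#' A segment merged on the top side prepends its axis points and members and
#' donates its top boundary corners (symmetrically on the end side); the
#' axis windows dis_top/dis_end follow automatically from the updated axis.
#' A fork is recorded as the side's terminating fork, its rectangle joins
#' the member list, and that side is closed to further search.
#'
#' @param target The chain the mark was produced for.
#' @param mark A mark from [find_candidates()].
#' @param segments Full segment model list (to resolve segment candidates).
#' @param forks Full fork list.
#' @return The updated chain.
#' @export
merge_mark <- function(target, mark, segments, forks) {
  side <- mark$side
  if ((side == "top" && !is.null(target$top_fork)) ||
      (side == "end" && !is.null(target$end_fork)))
    stop("cannot merge onto the ", side, " side: already closed by a fork")
  if (mark$kind == "fork") {
    fk <- Find(function(f) f$id == mark$candidate_id, forks)
    mem <- list(id = fk$id, kind = "fork", rect = fk$rect)
    if (side == "top") {
      target$top_fork <- fk$id
      target$members <- c(list(mem), target$members)
    } else {
      target$end_fork <- fk$id
      target$members <- c(target$members, list(mem))
    }
    return(target)
  }
  cand <- Find(function(s) s$id == mark$candidate_id, segments)
  if (side == "top") {
    target$V <- rbind(cand$V, target$V)
    target$W_top <- cand$W_top
    target$members <- c(cand$members, target$members)
    target$top_fork <- cand$top_fork
  } else {
    target$V <- rbind(target$V, cand$V)
    target$W_end <- cand$W_end
    target$members <- c(target$members, cand$members)
    target$end_fork <- cand$end_fork
  }
  target
}

#' Group segment models into chains by bidirectional sector search
#'
#' Greedy pass over the deduplicated segment models in decreasing rectangle
#' area (large fragments carry the widest, most reliable sectors), each
#' unconsumed model seeding a chain. The chain's top side is grown first,
#' then its end side: on a side, candidates are searched among unconsumed
#' segments and all forks, the nearest mark is taken (ties broken by
#' candidate id), a segment merge updates the chain and repeats the search,
#' and a fork closes the side. Every segment belongs to at most one chain;
#' forks are junctions and may terminate several chains.
#'
#' @param segments Deduplicated `branch_segment` models.
#' @param forks List of forks.
#' @param control A [recon_control()].
#' @return List of chains (still `branch_segment` structures, possibly
#'   multi-member).
#' @export
reconstruct <- function(segments, forks, control = recon_control()) {
  areas <- vapply(segments, function(s) {
    r <- .model_rect(s); r$long_len * r$short_len
  }, numeric(1))
  ids <- vapply(segments, function(s) as.integer(s$id), integer(1))
  order_idx <- order(-areas, ids)
  consumed <- rep(FALSE, length(segments))
  names(consumed) <- as.character(ids)
  chains <- list()
  for (oi in order_idx) {
    if (consumed[[as.character(ids[oi])]]) next
    chain <- segments[[oi]]
    consumed[[as.character(chain$id)]] <- TRUE
    for (side in c("top", "end")) {
      repeat {
        closed <- if (side == "top") !is.null(chain$top_fork)
                  else !is.null(chain$end_fork)
        if (closed) break
        avail <- Filter(function(s) !consumed[[as.character(s$id)]], segments)
        marks <- find_candidates(chain, side, avail, forks, control)
        if (length(marks) == 0) break
        d <- vapply(marks, `[[`, numeric(1), "distance")
        cid <- vapply(marks, function(m) as.integer(m$candidate_id), integer(1))
        best <- marks[[order(d, cid)[1]]]
        chain <- merge_mark(chain, best, segments, forks)
        if (best$kind == "fork") break
        consumed[[as.character(best$candidate_id)]] <- TRUE
      }
    }
    chains[[length(chains) + 1]] <- chain
  }
  chains
}
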