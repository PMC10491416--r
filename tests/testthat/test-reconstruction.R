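# independent re-derivation of the candidate marking rules, straight from
# the model fields, used as oracle for find_candidates
oracle_marks <- function(target, side, segments, forks,
                         f_seg = 3, f_fork = 1.6) {
  n <- nrow(target$V)
  ang <- function(u, v) {
    d <- abs(atan2(u[2], u[1]) - atan2(v[2], v[1])) %% (2 * pi)
    (if (d > pi) 2 * pi - d else d) * 180 / pi
  }
  if (side == "top") {
    apex <- target$V[2, ]; ray <- target$V[1, ] - apex
    S <- ang(target$W_top[1, ] - apex, target$W_top[2, ] - apex)
    dis <- sqrt(sum((target$V[1, ] - target$V[3, ])^2))
    term <- target$V[1, ]
  } else {
    apex <- target$V[n - 1, ]; ray <- target$V[n, ] - apex
    S <- ang(target$W_end[1, ] - apex, target$W_end[2, ] - apex)
    dis <- sqrt(sum((target$V[n - 2, ] - target$V[n, ])^2))
    term <- target$V[n, ]
  }
  hits <- list()
  for (cand in segments) {
    m <- nrow(cand$V)
    tp <- if (side == "top") cand$V[m, ] else cand$V[1, ]
    tdir <- if (side == "top") cand$V[m - 1, ] - cand$V[m, ]
            else cand$V[2, ] - cand$V[1, ]
    r <- sqrt(sum((tp - apex)^2))
    if (r > f_seg * dis) next
    if (r > 0 && ang(tp - apex, ray) > S / 2 + 1e-7) next
    if (ang(ray, tdir) > S / 2 + 1e-7) next
    hits[[length(hits) + 1]] <- list(id = cand$id, kind = "segment",
                                     dist = sqrt(sum((term - tp)^2)))
  }
  for (fk in forks) {
    r <- sqrt(sum((fk$center - apex)^2))
    if (r > f_fork * dis) next
    if (r > 0 && ang(fk$center - apex, ray) > S / 2 + 1e-7) next
    hits[[length(hits) + 1]] <- list(id = fk$id, kind = "fork",
                                     dist = sqrt(sum((term - fk$center)^2)))
  }
  hits
}

mark_key <- function(marks) {
  if (length(marks) == 0) return(character(0))
  sort(vapply(marks, function(m)
    paste0(m$kind, ":", if (!is.null(m$candidate_id)) m$candidate_id else m$id),
    character(1)))
}

test_that("a collinear candidate just above the target is marked with zero offset", {
  target <- vertical_model(c(50, 60), long = 30, short = 10, id = 1L)
  # candidate directly above, tip gap = 0.5 * dis = 15
  cand <- vertical_model(c(50, 60 - 15 - 15 - 15), long = 30, short = 10, id = 2L)
  marks <- find_candidates(target, "top", list(cand), list())
  expect_length(marks, 1)
  expect_equal(marks[[1]]$candidate_id, 2L)
  expect_equal(marks[[1]]$kind, "segment")
  expect_equal(marks[[1]]$distance, 15, tolerance = 1e-9)
})

test_that("a candidate beyond the depth limit is not marked", {
  target <- vertical_model(c(50, 200), long = 30, short = 10, id = 1L)
  far <- vertical_model(c(50, 200 - 15 - 4 * 30 - 15), long = 30, short = 10, id = 2L)
  expect_length(find_candidates(target, "top", list(far), list()), 0)
})

test_that("the reverse alignment check rejects a crossing candidate", {
  target <- vertical_model(c(50, 60), long = 30, short = 10, id = 1L)
  # tip inside the sector but candidate axis rotated 40 deg: S/2 ~ 18.4 deg
  rot <- vertical_model(c(50, 22), long = 30, short = 10,
                        phi = 40 * pi / 180, id = 2L)
  expect_length(find_candidates(target, "top", list(rot), list()), 0)
})

test_that("find_candidates agrees with the brute-force oracle on random scenes", {
  set.seed(17)
  for (rep in 1:15) {
    target <- vertical_model(runif(2, 80, 120), long = runif(1, 20, 40),
                             short = runif(1, 6, 12),
                             phi = runif(1, -0.3, 0.3), id = 100L)
    segs <- lapply(1:8, function(i)
      vertical_model(runif(2, 0, 200), long = runif(1, 16, 36),
                     short = runif(1, 5, 11), phi = runif(1, -0.6, 0.6), id = i))
    forks <- lapply(1:3, function(i) {
      r <- order_corners(rect_corners(runif(2, 0, 200), runif(1, 0, pi), 12, 10))
      list(id = 50L + i, center = r$center, rect = r)
    })
    for (side in c("top", "end")) {
      got <- find_candidates(target, side, segs, forks)
      want <- oracle_marks(target, side, segs, forks)
      expect_equal(mark_key(got), mark_key(want),
                   label = paste("marks", side, "rep", rep))
    }
  }
})

test_that("merging two fresh models concatenates axes and recomputes windows", {
  bottom <- vertical_model(c(50, 60), long = 30, short = 10, id = 1L)
  top <- vertical_model(c(50, 13), long = 24, short = 9, id = 2L)
  marks <- find_candidates(bottom, "top", list(top), list())
  expect_length(marks, 1)
  merged <- merge_mark(bottom, marks[[1]], list(top), list())
  expect_equal(nrow(merged$V), 6)
  expect_equal(member_ids(merged), c(2L, 1L))
  expect_equal(merged$W_top, top$W_top)
  # the new top window is the prepended segment's own axis
  expect_equal(sector_for(merged, "top", 1)$dis, 24, tolerance = 1e-9)
  expect_equal(sector_for(merged, "end", 1)$dis, 30, tolerance = 1e-9)
})

test_that("a fork merge closes the side", {
  target <- vertical_model(c(50, 60), long = 30, short = 10, id = 1L)
  r <- order_corners(rect_corners(c(50, 38), pi / 2, 12, 11))
  fk <- list(id = 7L, center = r$center, rect = r)
  marks <- find_candidates(target, "top", list(), list(fk))
  expect_length(marks, 1)
  expect_equal(marks[[1]]$kind, "fork")
  closed <- merge_mark(target, marks[[1]], list(), list(fk))
  expect_equal(closed$top_fork, 7L)
  expect_error(merge_mark(closed, marks[[1]], list(), list(fk)), "closed")
})

test_that("member order matches the axis projection of member centers", {
  scene <- generate_scene(small_spec(seed = 8))
  chains <- suppressMessages(reconstruct_branches(scene$instances))$chains
  for (ch in chains) {
    segs <- Filter(function(m) m$kind == "segment", ch$members)
    if (length(segs) < 2) next
    axis <- ch$V[nrow(ch$V), ] - ch$V[1, ]
    proj <- vapply(segs, function(m) sum((m$rect$center - ch$V[1, ]) * axis),
                   numeric(1))
    expect_equal(order(proj), seq_along(proj))
  }
})

test_that("collinear fragments group into one chain, distant branches stay apart", {
  segs <- lapply(0:2, function(i)
    vertical_model(c(40, 20 + i * 36), long = 30, short = 10, id = i + 1L))
  chains <- reconstruct(segs, list())
  expect_length(chains, 1)
  expect_setequal(member_ids(chains[[1]]), 1:3)
  # two parallel branches far apart laterally
  far <- c(segs,
           lapply(0:2, function(i)
             vertical_model(c(300, 20 + i * 36), long = 30, short = 10, id = i + 10L)))
  chains2 <- reconstruct(far, list())
  expect_length(chains2, 2)
  # a lone fragment is its own chain before pruning
  expect_length(reconstruct(list(segs[[1]]), list()), 1)
})

test_that("chains partition the segments and the loop terminates", {
  set.seed(23)
  for (rep in 1:5) {
    segs <- lapply(1:12, function(i)
      vertical_model(runif(2, 20, 280), long = runif(1, 18, 34),
                     short = runif(1, 5, 10), phi = runif(1, -0.5, 0.5), id = i))
    chains <- reconstruct(segs, list())
    ids <- unlist(lapply(chains, function(ch)
      member_ids(ch)[vapply(ch$members, function(m) m$kind == "segment", TRUE)]))
    expect_setequal(ids, 1:12)   # every segment in exactly one chain
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("the partition of a clean scene is independent of input order", {
  scene <- generate_scene(small_spec(seed = 12))
  bm <- suppressMessages(build_models(scene$instances))
  part <- function(segs) {
    chains <- reconstruct(segs, bm$forks)
    sort(vapply(chains, function(ch)
      paste(sort(member_ids(ch)), collapse = ","), character(1)))
  }
  base <- part(bm$segments)
  set.seed(2)
  for (rep in 1:3)
    expect_equal(part(sample(bm$segments)), base)
})

test_that("chains match the transitive closure of mutual linkage on small scenes", {
  # oracle: brute-force connected components of the "mutually marked"
  # relation between fresh segment models
  set.seed(41)
  for (rep in 1:6) {
    k <- sample(4:8, 1)
    segs <- lapply(seq_len(k), function(i)
      vertical_model(c(50 + (i %% 2) * 200 + runif(1, -5, 5), 20 + i * 40),
                     long = 30, short = 9, phi = runif(1, -0.05, 0.05), id = i))
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      for (side in c("top", "end")) {
        hits <- oracle_marks(segs[[i]], side, segs[j], list())
        if (length(hits) > 0) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    comp <- seq_len(k)
    repeat {
      changed <- FALSE
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (!adj[i, j]) next
        m <- min(comp[i], comp[j])
        if (comp[i] != m || comp[j] != m) {
          comp[i] <- m; comp[j] <- m; changed <- TRUE
        }
      }
      if (!changed) break
    }
    want <- sort(vapply(split(seq_len(k), comp), function(g)
      paste(sort(g), collapse = ","), character(1)))
    chains <- reconstruct(segs, list())
    got <- sort(vapply(chains, function(ch)
      paste(sort(member_ids(ch)), collapse = ","), character(1)))
    expect_equal(got, unname(want))
  }
})
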