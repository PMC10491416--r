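# helpers to build chains terminated by a fork on a chosen side
chain_with_fork <- function(center, phi, fork, side, long = 30, short = 10, id = 1L) {
  m <- vertical_model(center, long = long, short = short, phi = phi, id = id)
  mem <- list(id = fork$id, kind = "fork", rect = fork$rect)
  if (side == "end") {
    m$end_fork <- fork$id
    m$members <- c(m$members, list(mem))
  } else {
    m$top_fork <- fork$id
    m$members <- c(list(mem), m$members)
  }
  m
}

make_fork <- function(center, id = 99L) {
  r <- order_corners(rect_corners(center, pi / 2, 12, 11))
  list(id = id, center = r$center, rect = r)
}

test_that("a straight continuation through a fork is rejoined, a perpendicular one is not", {
  fk <- make_fork(c(50, 100))
  main <- chain_with_fork(c(50, 70), 0, fk, "end", id = 1L)       # above, ends at fork
  straight <- chain_with_fork(c(50, 130), 0, fk, "top", id = 2L)  # continues below
  out <- connect_at_fork(list(main, straight), list(fk))
  expect_length(out, 1)
  expect_setequal(member_ids(out[[1]]), c(1L, 99L, 2L))
  expect_equal(nrow(out[[1]]$V), 7)  # 3 + fork + 3

  # perpendicular secondary: interior angle 90 <= 100, no merge
  perp <- vertical_model(c(80, 100), long = 30, short = 10, phi = pi / 2, id = 3L)
  perp$V <- perp$V[c(1, 2, 3), , drop = FALSE]
  # orient the perpendicular chain so its top node is the fork side
  pm <- model_from_corners(rect_corners(c(80, 100), 0, 30, 10), id = 3L)
  pm$top_fork <- fk$id
  pm$members <- c(list(list(id = fk$id, kind = "fork", rect = fk$rect)), pm$members)
  out2 <- connect_at_fork(list(main, pm), list(fk))
  expect_length(out2, 2)
})

test_that("with several secondaries only the largest interior angle merges", {
  fk <- make_fork(c(100, 100))
  main <- chain_with_fork(c(100, 70), 0, fk, "end", id = 1L)
  # secondary at ~170 deg (nearly straight) and one at ~120 deg
  s170 <- chain_with_fork(c(100 + 30 * sin(0.17), 130), 0.17, fk, "top", id = 2L)
  s120 <- chain_with_fork(c(100 + 30 * sin(1.05), 115), 1.05, fk, "top", id = 3L)
  out <- connect_at_fork(list(main, s170, s120), list(fk))
  expect_length(out, 2)
  joined <- out[[which(vapply(out, function(c) 1L %in% member_ids(c), TRUE))]]
  expect_true(2L %in% member_ids(joined))
  expect_false(3L %in% member_ids(joined))
})

test_that("free connection bridges collinear gaps within depth but not beyond", {
  # two collinear vertical fragments, gap measured tip to tip
  upper <- vertical_model(c(50, 35), long = 30, short = 10, id = 1L)
  gap4 <- vertical_model(c(50, 35 + 30 + 4 * 30), long = 30, short = 10, id = 2L)
  out <- connect_free(list(gap4, upper))
  expect_length(out, 1)
  expect_equal(member_ids(out[[1]]), c(1L, 2L))

  gap6 <- vertical_model(c(50, 35 + 30 + 6 * 30), long = 30, short = 10, id = 3L)
  expect_length(connect_free(list(gap6, upper)), 2)
})

test_that("free connection rejects parallel side-by-side chains", {
  a <- vertical_model(c(50, 50), long = 30, short = 10, id = 1L)
  b <- vertical_model(c(75, 50), long = 30, short = 10, id = 2L)
  expect_length(connect_free(list(a, b)), 2)
})

test_that("free connection never merges across sides closed by forks", {
  fk <- make_fork(c(50, 100))
  upper <- chain_with_fork(c(50, 70), 0, fk, "end", id = 1L)
  lower <- chain_with_fork(c(50, 130), 0, fk, "top", id = 2L)
  # both facing terminals are closed at the fork: connect_free must not act
  expect_length(connect_free(list(upper, lower)), 2)
})

test_that("enlarging the free search depth never reduces the number of merges", {
  set.seed(19)
  for (rep in 1:4) {
    frags <- lapply(1:6, function(i)
      vertical_model(c(60 + (i %% 2) * 150, 30 + i * 55), long = 24, short = 8,
                     phi = runif(1, -0.2, 0.2), id = i))
    n5 <- length(connect_free(frags, recon_control(free_depth_factor = 5)))
    n8 <- length(connect_free(frags, recon_control(free_depth_factor = 8)))
    expect_lte(n8, n5)
  }
})

test_that("prune_isolated removes only fork-less singletons", {
  single <- vertical_model(c(20, 20), long = 20, short = 8, id = 1L)
  fk <- make_fork(c(40, 60))
  with_fork <- chain_with_fork(c(40, 40), 0, fk, "end", id = 2L)
  pair <- merge_mark(vertical_model(c(80, 60), long = 20, short = 8, id = 3L),
                     list(candidate_id = 4L, side = "top", kind = "segment",
                          distance = 5, passed_reverse_check = TRUE),
                     list(vertical_model(c(80, 30), long = 20, short = 8, id = 4L)),
                     list())
  out <- prune_isolated(list(single, with_fork, pair))
  expect_length(out, 2)
  expect_false(1L %in% unlist(lapply(out, member_ids)))
  expect_length(prune_isolated(list(single), enabled = FALSE), 1)
})

test_that("reconstruct_scene handles the empty scene and a simple fragmented branch", {
  empty <- structure(list(image_size = c(50L, 50L), instances = list()),
                     class = "instance_set")
  expect_length(reconstruct_scene(empty), 0)

  size <- c(200, 80)
  insts <- lapply(0:3, function(i) list(
    mask = rect_mask(size, c(40, 25 + i * 40), pi / 2, 30, 10),
    label = "segmented", id = i + 1L))
  chains <- reconstruct_scene(instance_set(size, insts))
  expect_length(chains, 1)
  expect_setequal(member_ids(chains[[1]]), 1:4)
  expect_true(any(chains[[1]]$mask))
  expect_equal(chains[[1]]$diameter, 9, tolerance = 0.2)
})

test_that("a Y-shaped branch yields two chains sharing the fork, collinear pair joined", {
  size <- c(260, 200)
  # trunk down the middle, fork at y = 105, continuation below, side limb at 40 deg
  trunk <- lapply(0:1, function(i) list(
    mask = rect_mask(size, c(100, 25 + i * 38), pi / 2, 30, 10),
    label = "segmented", id = i + 1L))
  forkq <- list(mask = rect_mask(size, c(100, 105), pi / 2, 13, 12),
                label = "forked", id = 3L)
  below <- lapply(0:1, function(i) list(
    mask = rect_mask(size, c(100, 130 + i * 38), pi / 2, 30, 10),
    label = "segmented", id = i + 4L))
  th <- pi / 2 + 0.7
  u <- c(cos(th), sin(th))
  limb <- lapply(0:1, function(i) list(
    mask = rect_mask(size, c(100, 105) + (28 + 19 + i * 38) * u, th, 30, 10),
    label = "segmented", id = i + 6L))
  chains <- suppressMessages(
    reconstruct_scene(instance_set(size, c(trunk, list(forkq), below, limb))))
  expect_length(chains, 2)
  memb <- lapply(chains, member_ids)
  expect_true(all(vapply(memb, function(m) 3L %in% m, TRUE)))  # fork shared
  main <- memb[[which(vapply(memb, function(m) 1L %in% m, TRUE))]]
  expect_setequal(main, c(1L, 2L, 3L, 4L, 5L))
  limb_chain <- memb[[which(vapply(memb, function(m) 6L %in% m, TRUE))]]
  expect_setequal(limb_chain, c(3L, 6L, 7L))
})

test_that("the pipeline is deterministic end to end", {
  scene <- generate_scene(small_spec(seed = 14, dropout_rate = 0.1,
                                     duplicate_rate = 0.1))
  a <- suppressMessages(reconstruct_branches(scene$instances))
  b <- suppressMessages(reconstruct_branches(scene$instances))
  expect_identical(lapply(a$chains, member_ids), lapply(b$chains, member_ids))
  expect_identical(a$chains[[1]]$mask, b$chains[[1]]$mask)
})
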