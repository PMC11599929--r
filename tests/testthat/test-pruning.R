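# helper: straight stem along +x with a bifurcation at its end and two
# configurable child branches given as direction vectors
fork_tree <- function(d1, d2, n_child = 5, radius_child = c(1, 1)) {
  rows <- data.frame(id = 1:11, type = c(1, rep(2, 10)),
                     x = c(0:10), y = 0, z = 0, radius = 1,
                     parent = c(-1, 1:10))
  nid <- 12L
  for (ci in 1:2) {
    d <- list(d1, d2)[[ci]] / sqrt(sum(list(d1, d2)[[ci]]^2))
    prev <- 11L
    for (i in 1:n_child) {
      rows <- rbind(rows, data.frame(id = nid, type = 2,
                                     x = 10 + d[1] * i, y = d[2] * i,
                                     z = d[3] * i, radius = radius_child[ci],
                                     parent = prev))
      prev <- nid; nid <- nid + 1L
    }
  }
  neuron_tree(rows)
}

test_that("angle filter removes turn-backs and radius blow-ups", {
  # collinear child (angle 180) kept; 60-degree turn-back removed
  tr <- fork_tree(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0))
  res <- prune_angle(tr)
  expect_equal(sort(res$removed), 17:21) # the turn-back branch
  expect_equal(nrow(res$tree$nodes), 16L)

  # both children forward -> nothing removed
  tr2 <- fork_tree(c(1, 1, 0), c(1, -1, 0))
  expect_length(prune_angle(tr2)$removed, 0L)

  # child radius over 1.5x the parent branch mean radius -> removed
  tr3 <- fork_tree(c(1, 1, 0), c(1, -1, 0), radius_child = c(1, 2))
  expect_equal(sort(prune_angle(tr3)$removed), 17:21)

  # radii absent -> radius rule skipped with a warning
  tr4 <- tr3
  tr4$nodes$radius <- 0
  expect_warning(r4 <- prune_angle(tr4), "radius rule skipped")
  expect_length(r4$removed, 0L)

  # removal set matches a rule-by-rule oracle on random trees
  for (s in 1:10) {
    tr <- random_tree(s + 300, depth = 3L)
    res <- prune_angle(tr)
    branches <- branch_decomposition(tr)
    xyz <- as.matrix(tr$nodes[, c("x", "y", "z")])
    chord <- function(b) xyz[b$rows[length(b$rows)], ] - xyz[b$rows[1], ]
    bad <- vapply(branches, function(b) {
      if (is.na(b$parent_branch)) return(FALSE)
      pb <- branches[[b$parent_branch]]
      ang <- acos(max(-1, min(1, sum(-chord(pb) * chord(b)) /
        sqrt(sum(chord(pb)^2) * sum(chord(b)^2))))) * 180 / pi
      rb <- mean(tr$nodes$radius[b$rows[-1]])
      rp <- mean(tr$nodes$radius[pb$rows[-1]])
      ang < 80 || (rp > 0 && rb > 1.5 * rp)
    }, logical(1))
    # closure over descendants
    expected <- integer()
    for (i in seq_along(branches)) {
      anc <- i; hit <- FALSE
      while (!is.na(anc)) {
        if (bad[anc]) { hit <- TRUE; break }
        anc <- branches[[anc]]$parent_branch
      }
      if (hit) expected <- union(expected,
                                 branches[[i]]$ids[-1])
    }
    expect_setequal(res$removed, expected)
  }
})

test_that("crossover filter removes opposing spur pairs, keeps through-path", {
  # two straight fibers crossing: fiber 1 along x (through), fiber 2 read as
  # two ~90-degree spurs opposing each other at a fake bifurcation pair
  rows <- data.frame(id = 1:21, type = c(1, rep(2, 20)),
                     x = c(0:20), y = 0, z = 0, radius = 1,
                     parent = c(-1, 1:20))
  up <- data.frame(id = 22:26, type = 2, x = 10.2, y = 1:5 * 1.0, z = 0,
                   radius = 1, parent = c(11L, 22:25))
  down <- data.frame(id = 27:31, type = 2, x = 9.8, y = -(1:5) * 1.0, z = 0,
                     radius = 1, parent = c(10L, 27:30))
  up$x <- 10.2 + (1:5) * 0.05
  down$x <- 9.8 - (1:5) * 0.05
  tr <- neuron_tree(rbind(rows, up, down))
  res <- prune_crossover(tr)
  expect_setequal(res$removed, 22:31)
  expect_equal(nrow(res$tree$nodes), 21L)

  # genuine T-branching at a multifurcation: ~170 through + ~90 spur kept
  rows2 <- data.frame(id = 1:11, type = c(1, rep(2, 10)),
                      x = 0:10, y = 0, z = 0, radius = 1, parent = c(-1, 1:10))
  cont <- data.frame(id = 12:15, type = 2, x = 10 + (1:4) * 0.98,
                     y = (1:4) * 0.17, z = 0, radius = 1, parent = c(11L, 12:14))
  spur <- data.frame(id = 16:19, type = 2, x = 10, y = 0, z = (1:4),
                     radius = 1, parent = c(11L, 16:18))
  third <- data.frame(id = 20:23, type = 2, x = 10 + (1:4) * 0.9,
                      y = -(1:4) * 0.43, z = 0, radius = 1,
                      parent = c(11L, 20:22))
  tr2 <- neuron_tree(rbind(rows2, cont, spur, third))
  res2 <- prune_crossover(tr2)
  expect_length(res2$removed, 0L)

  # no multifurcation and no close bifurcation pair -> unchanged
  tr3 <- fork_tree(c(1, 1, 0), c(1, -1, 0))
  expect_length(prune_crossover(tr3)$removed, 0L)
})

test_that("soma filter cuts off a far secondary blob", {
  # dumbbell: true soma, a 200 um fiber, then a fat blob (radius 8 px)
  fiber <- data.frame(id = 1:21, type = c(1, rep(2, 20)),
                      x = seq(0, 200, 10), y = 0, z = 0,
                      radius = c(8, rep(1, 20)), parent = c(-1, 1:20))
  blob <- data.frame(id = 22:24, type = 2, x = c(202, 204, 206), y = 0, z = 0,
                     radius = 8, parent = c(21L, 22L, 23L))
  tr <- neuron_tree(rbind(fiber, blob))
  res <- prune_soma(tr)
  expect_true(all(22:24 %in% res$removed))
  expect_false(1L %in% res$removed)

  # no large-radius nodes -> unchanged
  clean <- neuron_tree(transform(fiber, radius = c(8, rep(1, 20))))
  expect_length(prune_soma(clean)$removed, 0L)

  # candidate inside the 50 px exclusion zone -> ignored
  near <- fiber
  near$radius[4] <- 8 # ~30 px from the soma
  expect_length(prune_soma(neuron_tree(near))$removed, 0L)
})

test_that("winding filter removes circuitous tips with strict ratio 3", {
  straight <- chain_tree(20)
  expect_length(prune_winding(straight)$removed, 0L)

  # tight sine coil: path length far exceeds net displacement
  t <- seq(0, 12 * pi, length.out = 61)
  coil <- neuron_tree(data.frame(id = 1:62, type = c(1, rep(2, 61)),
                                 x = c(0, seq(1, 5, length.out = 61)),
                                 y = c(0, 3 * sin(t)), z = 0, radius = 1,
                                 parent = c(-1, 1:61)))
  expect_gt(length(prune_winding(coil)$removed), 0L)

  # ratio exactly 3 is kept (strict >): an L with path 3, euclid 1 on a tip
  lshape <- neuron_tree(data.frame(
    id = 1:4, type = c(1, 2, 2, 2),
    x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0, radius = 1,
    parent = c(-1, 1, 2, 3)))
  expect_length(prune_winding(lshape)$removed, 0L)
})

test_that("apply_all intersects filters, drops fragments, discards tiny trees", {
  # clean tree passes through unchanged
  tr <- random_tree(401)
  res <- apply_all(tr)
  expect_false(res$discarded)
  expect_equal(nrow(res$tree$nodes), nrow(tr$nodes))

  # union-of-defects: kept node set equals the intersection of single-filter
  # keeps (minus orphaned fragments)
  bad <- fork_tree(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), n_child = 15)
  res2 <- apply_all(bad)
  keep_each <- lapply(list(prune_angle(bad), prune_crossover(bad),
                           prune_soma(bad), prune_winding(bad)),
                      function(r) setdiff(bad$nodes$id, r$removed))
  expect_setequal(res2$tree$nodes$id, Reduce(intersect, keep_each))

  # fewer than 20 surviving nodes -> discarded entirely
  tiny <- chain_tree(10)
  res3 <- apply_all(tiny)
  expect_true(res3$discarded)
  expect_null(res3$tree)

  # idempotence and subset property on random trees
  for (s in 1:10) {
    tr <- random_tree(s + 500, depth = 3L)
    r1 <- apply_all(tr)
    if (r1$discarded) next
    expect_true(all(r1$tree$nodes$id %in% tr$nodes$id))
    r2 <- apply_all(r1$tree)
    expect_false(r2$discarded)
    expect_identical(r2$tree$nodes, r1$tree$nodes)
    # soma retained
    expect_true(any(r1$tree$nodes$type == 1))
  }
})
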