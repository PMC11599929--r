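make_block <- function(arcs = c(10, 25, 40), gain = 2, sigma = 1.5,
                       noise = NULL, seed = 1, n = 50) {
  tr <- straight_axon_tree(n)
  spec <- block_gen_spec(dim = c(64, 64, 32), voxel = 1, tube_radius = 1.5,
                         fg_intensity = 100,
                         varicosities = if (length(arcs))
                           data.frame(arc = arcs, gain = gain, sigma = sigma)
                         else NULL,
                         noise = noise)
  list(tree = tr, block = synth_image_block(tr, spec, seed = seed))
}

test_that("fragment profiles partition the axon and localize bumps", {
  mb <- make_block(arcs = numeric(0))
  prof <- fragment_profiles(mb$tree, mb$block$image, voxel = 1)
  expect_equal(length(unique(prof$fragment)), 3L) # 50 um -> 3 fragments
  tr100 <- straight_axon_tree(100, step = 0.5)
  spec <- block_gen_spec(dim = c(64, 64, 32), voxel = 1, tube_radius = 1.5,
                         fg_intensity = 100)
  blk <- synth_image_block(tr100, spec, seed = 1)
  p100 <- fragment_profiles(tr100, blk$image, voxel = 1, step = 10)
  expect_equal(length(unique(p100$fragment)), 5L) # 50 um at 10 um steps

  mb2 <- make_block(arcs = 25)
  prof2 <- fragment_profiles(mb2$tree, mb2$block$image, voxel = 1)
  peak_arc <- mean(prof2$arc[prof2$intensity == max(prof2$intensity)])
  expect_lt(abs(peak_arc - 25), 1.01)
  expect_lt(abs(prof2$arc[which.max(prof2$radius)] - 25), 1.01)

  out_tree <- straight_axon_tree(200) # extends past the block
  expect_error(fragment_profiles(out_tree, mb2$block$image, voxel = 1),
               "outside image")
})

test_that("noise-free detection is exact and respects its filter rules", {
  mb <- make_block()
  prof <- fragment_profiles(mb$tree, mb$block$image, voxel = 1)
  det <- detect_varicosities(prof)
  ev <- evaluate_detection(det, mb$block$truth, 2)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  # gain below the 1.5x radius threshold -> rejected
  low <- make_block(arcs = 25, gain = 1.2)
  det_low <- detect_varicosities(
    fragment_profiles(low$tree, low$block$image, voxel = 1))
  expect_equal(nrow(det_low), 0L)

  # two bumps 3 voxels apart -> one detection (dedup radius 5)
  close <- make_block(arcs = c(24, 27), sigma = 1)
  det_close <- detect_varicosities(
    fragment_profiles(close$tree, close$block$image, voxel = 1))
  expect_equal(nrow(det_close), 1L)

  # dedup: all surviving pairs farther apart than the radius
  many <- make_block(arcs = seq(8, 44, 6), sigma = 1)
  det_many <- detect_varicosities(
    fragment_profiles(many$tree, many$block$image, voxel = 1))
  if (nrow(det_many) > 1) {
    dd <- dist(as.matrix(det_many[, c("x", "y", "z")]))
    expect_true(all(dd > 5))
  }

  # monotone in thresholds
  n_base <- nrow(det)
  expect_lte(nrow(detect_varicosities(prof, min_intensity = 180)), n_base)
  expect_lte(nrow(detect_varicosities(prof, gain = 2.5)), n_base)
})

test_that("TEB/EPB typing uses arc distance to the nearest axonal tip", {
  tr <- straight_axon_tree(50)
  tip <- tr$nodes[nrow(tr$nodes), c("x", "y", "z")]
  mid <- data.frame(x = 30, y = 32, z = 16)
  v <- rbind(tip, mid)
  types <- classify_varicosity_type(v, tr, eps = 2)
  expect_equal(types, c("TEB", "EPB"))

  # 1 tip bump + 99 shaft bumps -> EPB fraction 0.99
  tr2 <- straight_axon_tree(200, step = 1, x0 = 7)
  shaft <- data.frame(x = seq(10, 108, length.out = 99), y = 32, z = 16)
  tipv <- data.frame(x = 207, y = 32, z = 16)
  types2 <- classify_varicosity_type(rbind(tipv, shaft), tr2, eps = 2)
  expect_equal(mean(types2 == "EPB"), 0.99)
})

test_that("branch statistics aggregate flags, classes, and quartiles", {
  # Y-shaped axon, varicosities in both children -> B0; one child -> B1
  s <- 40 * sqrt(2) / 2
  ytr <- neuron_tree(data.frame(
    id = 1:13, type = c(1, rep(2, 12)),
    x = c(0, 0, 0, 0, 0, s / 4 * 1:4, -s / 4 * 1:4),
    y = c(0, 10, 20, 30, 40, 40 + s / 4 * 1:4, 40 + s / 4 * 1:4),
    z = 0, radius = 1, parent = c(-1, 1, 2, 3, 4, 5, 6:8, 5, 10:12)))
  v_both <- data.frame(branch = c(2L, 3L), branch_arc = c(10, 10))
  st <- branch_varicosity_stats(ytr, v_both)
  expect_equal(unname(st$summary$b_proportions["B0"]), 1)
  v_one <- data.frame(branch = 2L, branch_arc = 10)
  st1 <- branch_varicosity_stats(ytr, v_one)
  expect_equal(unname(st1$summary$b_proportions["B1"]), 1)
  expect_equal(st1$summary$varicosity_branches, 1L)
  expect_equal(st1$summary$null_branches, 2L)

  # quartile assignment by fractional arc length; uniform -> flat-ish
  one_branch <- chain_tree(40)
  v_unif <- data.frame(branch = 1L, branch_arc = seq(0.5, 39.5, 1))
  stq <- branch_varicosity_stats(one_branch, v_unif)
  expect_equal(sum(stq$branches[1, c("q1", "q2", "q3", "q4")]), 40)
  expect_equal(unname(unlist(
    stq$branches[1, c("q1", "q2", "q3", "q4")])), rep(10L, 4))
  expect_equal(unname(stq$summary$quartile_ratios), rep(0.25, 4))
  expect_true(all(stq$branches$curviness >= 1 - 1e-12))
})

test_that("radial distributions normalize to unit mass", {
  tr <- straight_axon_tree(50)
  v <- data.frame(x = c(20, 30, 40), y = 32, z = 16)
  rd <- radial_distribution(tr, v, n_bins = 10)
  expect_equal(sum(rd$histogram), 1, tolerance = 1e-12)
  # all varicosities at one distance -> a single occupied bin
  v1 <- data.frame(x = rep(30, 5), y = 32, z = 16)
  rd1 <- radial_distribution(tr, v1, n_bins = 10)
  expect_equal(max(rd1$histogram), 1)
  expect_true(all(rd1$quartiles == rd1$quartiles[1]))
  expect_error(radial_distribution(tr, v[0, ]), ">= 1")
})

test_that("radar features min-max scale to 0..100 over the set", {
  tr <- straight_axon_tree(50)
  sets <- list(
    a = data.frame(x = c(20, 30), y = 32, z = 16, branch = 1L),
    b = data.frame(x = c(15, 25, 35, 45), y = 32, z = 16, branch = 1L),
    c = data.frame(x = 40, y = 32, z = 16, branch = 1L))
  vr <- varicosity_radar(sets, list(tr, tr, tr))
  expect_equal(unname(vr$scaled[, "F1"]), c(100 / 3, 100, 0))
  expect_true(all(vr$scaled >= 0 & vr$scaled <= 100))
  expect_equal(unname(vr$raw[, "F1"]), c(2, 4, 1))

  sets$d <- sets$a[0, ]
  vr2 <- varicosity_radar(sets, list(tr, tr, tr, tr))
  expect_equal(vr2$excluded, "d")
  expect_equal(nrow(vr2$scaled), 3L)
})

test_that("varicosity MST is minimal and spans soma plus sites", {
  # 3 collinear points at 0, 1, 3 -> edges (0-1), (1-3), weight 3
  m <- mst_varicosities(cbind(c(0, 1, 3), 0, 0))
  expect_equal(attr(m, "total_weight"), 3)
  expect_equal(nrow(m), 2L)

  # exhaustive oracle for n <= 6: total weight equals the best spanning tree
  set.seed(51)
  pts <- matrix(runif(15, 0, 10), 5)
  m5 <- mst_varicosities(pts, soma = c(0, 0, 0))
  expect_equal(nrow(m5), 5L) # n edges over n+1 vertices
  all_pts <- rbind(c(0, 0, 0), pts)
  d <- as.matrix(dist(all_pts))
  g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                           mode = "undirected")
  ref <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(attr(m5, "total_weight"), ref, tolerance = 1e-12)
})

test_that("detection evaluation is a greedy one-to-one matching", {
  truth <- data.frame(x = c(0, 10, 20), y = 0, z = 0)
  det <- data.frame(x = c(0.5, 10.2, 19.8), y = 0, z = 0,
                    intensity = c(3, 2, 1))
  ev <- evaluate_detection(det, truth, 2)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  half <- evaluate_detection(det[1:2, ], truth, 2)
  expect_equal(half$recall, 2 / 3)
  # two detections cannot claim the same truth site
  dup <- data.frame(x = c(0, 0.4), y = 0, z = 0, intensity = c(2, 1))
  evd <- evaluate_detection(dup, truth, 2)
  expect_equal(evd$matched, 1L)
  expect_equal(evd$precision, 0.5)
})
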