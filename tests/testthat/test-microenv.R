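test_that("radius calibration matches hand enumeration and brute force", {
  pop <- list(somata = data.frame(id = 1:7, region = "A", x = 0:6, y = 0, z = 0))
  expect_equal(calibrate_radius(pop), 4)
  expect_equal(DEFAULT_MICROENV_RADIUS, 249)

  set.seed(11)
  pos <- matrix(runif(60, 0, 500), 20)
  pop2 <- list(somata = data.frame(id = 1:20, region = "A",
                                   x = pos[, 1], y = pos[, 2], z = pos[, 3]))
  d <- as.matrix(dist(pos))
  brute <- median(apply(d, 1, function(r) sort(r)[6]))
  expect_equal(calibrate_radius(pop2), brute)
  expect_error(calibrate_radius(list(somata = pop$somata[1:4, ])), "at least")
})

test_that("neighbor search is radius-bounded and similarity-ranked", {
  # 10 clones of the target within D plus 5 dissimilar neurons
  feats <- rbind(matrix(5, 11, 6), matrix(-50, 5, 6)) +
    matrix(rnorm(16 * 6, 0, 1e-3), 16)
  rownames(feats) <- 1:16
  pop <- list(somata = data.frame(id = 1:16, region = "A",
                                  x = c(0, seq(10, 100, 10), seq(20, 60, 10)),
                                  y = 0, z = 0),
              features = feats)
  nb <- find_neighbors(1, pop, D = 200, k = 5)
  expect_length(nb$id, 5L)
  expect_true(all(nb$id %in% 2:11))

  # isolated target -> empty list, fusion returns its own features
  pop$somata$x[1] <- 1e6
  nb0 <- find_neighbors(1, pop, D = 200, k = 5)
  expect_equal(nrow(nb0), 0L)
  m <- fuse(1, nb0, pop, D = 200)
  expect_equal(m$weights, 1)
  expect_equal(unname(m$features), unname(feats[1, ]))

  # exhaustive-search oracle on a random population
  set.seed(12)
  pop3 <- list(somata = data.frame(id = 1:30, region = "A",
                                   x = runif(30, 0, 300), y = runif(30, 0, 300),
                                   z = runif(30, 0, 300)),
               features = matrix(rnorm(30 * 8), 30,
                                 dimnames = list(1:30, NULL)))
  z <- standardize(pop3$features)
  pos <- as.matrix(pop3$somata[, c("x", "y", "z")])
  for (target in c(3L, 17L)) {
    nb <- find_neighbors(target, pop3, D = 150, k = 5)
    sd_ <- sqrt(colSums((t(pos) - pos[target, ])^2))
    cand <- setdiff(which(sd_ <= 150), target)
    fd <- sqrt(colSums((t(z[cand, , drop = FALSE]) - z[target, ])^2))
    expected <- cand[order(fd)][seq_len(min(5, length(cand)))]
    expect_equal(nb$id, pop3$somata$id[expected])
  }
})

test_that("fusion weights follow the exponential proximity rule", {
  pop <- list(somata = data.frame(id = 1:6, region = "A",
                                  x = c(0, rep(50, 5)), y = 0, z = 0),
              features = matrix(rep(1:6, 4), 6, 4,
                                dimnames = list(1:6, paste0("f", 1:4))))
  nb <- data.frame(id = 2:6, soma_dist = 50, feature_dist = 0)
  m <- fuse(1, nb, pop, D = 100)
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  expect_equal(unname(m$weights[1]),
               exp(0) / (exp(0) + 5 * exp(-0.5)), tolerance = 1e-12)
  expect_equal(unname(m$weights[2]), 0.1504, tolerance = 1e-3)
  # equal distances -> uniform neighbor weights; order invariance
  expect_true(all(abs(diff(m$weights[-1])) < 1e-15))
  m2 <- fuse(1, nb[5:1, ], pop, D = 100)
  expect_equal(sort(m2$weights), sort(m$weights))
  expect_equal(m2$features, m$features)
  # identical member features -> fused vector equals them (convexity)
  popc <- pop; popc$features[] <- 7
  mc <- fuse(1, nb, popc, D = 100)
  expect_equal(unname(mc$features), rep(7, 4))
  # fused features stay in the member-wise convex hull
  rng <- apply(pop$features[1:6, ], 2, range)
  expect_true(all(m$features >= rng[1, ] - 1e-12 & m$features <= rng[2, ] + 1e-12))
})

test_that("mRMR ranks relevance first and penalizes redundancy", {
  set.seed(13)
  y <- rep(c(0, 1), each = 60)
  X <- cbind(dup = y, noise1 = rnorm(120), info = y * 2 + rnorm(120, 0, 0.4),
             noise2 = rnorm(120))
  expect_equal(mrmr_select(X, y, 1), "dup")

  # identical informative columns: the duplicate is redundancy-penalized
  X2 <- cbind(a = y + rnorm(120, 0, 0.1))
  X2 <- cbind(info1 = X2[, 1], info2 = X2[, 1],
              weak = y + rnorm(120, 0, 2), noise = rnorm(120))
  sel <- mrmr_select(X2, y, 2)
  expect_equal(sel[1], "info1")
  expect_false(sel[2] == "info2")

  # informative features beat pure noise in >= 95/100 seeded runs
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    yy <- rep(c(0, 1), each = 50)
    XX <- cbind(sig = yy + rnorm(100, 0, 0.5), n1 = rnorm(100), n2 = rnorm(100))
    mrmr_select(XX, yy, 1) == "sig"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("RGB maps scale channels and mirror hemispheres", {
  me <- data.frame(id = 1:2, region = "A", x = c(10, 60), y = c(10, 10),
                   z = c(10, 10), f1 = c(1, 2), f2 = c(5, 5), f3 = c(0, 1))
  map <- render_map(me, c("f1", "f2", "f3"), spacing = 25, dims = c(4, 4, 4),
                    mirror = FALSE)
  vals <- sort(unique(as.vector(map$array[, , , 1])))
  expect_equal(vals, c(0, 255))
  # constant channel (singleton value) pinned to 255
  expect_equal(sort(unique(as.vector(map$array[, , , 2]))), c(0, 255))

  single <- render_map(me[1, ], c("f1", "f2", "f3"), spacing = 25,
                       dims = c(4, 4, 4))
  expect_equal(sum(single$array > 0), 3L) # one voxel, three channels at 255

  # a point and its mirror land in the same voxel
  me2 <- data.frame(id = 1:2, region = "A", x = 10, y = 10, z = c(10, 90),
                    f1 = c(1, 2), f2 = c(1, 2), f3 = c(1, 2))
  mm <- render_map(me2, c("f1", "f2", "f3"), spacing = 25, dims = c(4, 4, 4),
                   mirror = TRUE)
  expect_equal(sum(apply(mm$array, 1:3, max) > 0), 1L)
  expect_error(render_map(me, c("f1", "f2", "nope"), dims = c(4, 4, 4)),
               "absent")
})

test_that("path profiles track planted gradients and independence", {
  set.seed(14)
  n <- 200
  me <- data.frame(id = 1:n, region = rep(c("R1", "R2", "R3", "R4"), each = n / 4),
                   x = seq(0, 2000, length.out = n), y = 0, z = 0)
  me$grad <- me$x / 2000 + rnorm(n, 0, 0.01)
  me$indep <- rnorm(n)
  pp <- path_profile(me, c("R1", "R2", "R3", "R4"), c("grad", "indep"))
  expect_true(all(diff(pp$profile$grad) > 0))

  poly <- cbind(seq(0, 2000, length.out = 50), 0, 0)
  pl <- path_profile(me, poly, c("grad", "indep"), tube_radius = 50,
                     n_bins = 20)
  arc <- pl$profile$step
  expect_gte(cor(arc, pl$profile$grad, use = "complete.obs"), 0.99)
  expect_lt(abs(cor(pl$profile$grad, pl$profile$indep,
                    use = "complete.obs")), 0.5)

  # identical microenvironments -> flat profile, correlation flagged NA
  me_flat <- me; me_flat$grad <- 1; me_flat$indep <- 2
  pf <- path_profile(me_flat, c("R1", "R2"), c("grad", "indep"))
  expect_true(all(is.na(pf$correlations[upper.tri(pf$correlations)])))
})

test_that("region clustering separates planted region groups", {
  pop <- two_region_population(n = 30, seed = 9)
  me <- build_microenvironments(pop, D = 249, k = 5)
  cl <- cluster_regions(me, features = paste0("f", 1:24), k = 2, seed = 1)
  expect_length(unique(cl$clusters), 2L)
  # duplicated region data -> same cluster
  me2 <- rbind(me, transform(me[me$region == "A", ], region = "A2"))
  cl2 <- cluster_regions(me2, features = paste0("f", 1:24), k = 2, seed = 1)
  expect_equal(unname(cl2$clusters["A"]), unname(cl2$clusters["A2"]))
  # k = number of regions -> one cluster each, inertia 0
  cl3 <- cluster_regions(me, features = paste0("f", 1:24), k = 2, seed = 1)
  expect_equal(cl3$inertia >= 0, TRUE)
  expect_warning(
    cluster_regions(rbind(me, transform(me[1, ], region = "tiny")),
                    features = paste0("f", 1:24), k = 2, seed = 1),
    "excluded")
})
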