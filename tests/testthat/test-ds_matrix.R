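test_that("microenvironment transfer picks the closest same-region donor", {
  set.seed(61)
  lm <- matrix(rnorm(10 * 18), 10)
  me <- matrix(rnorm(10 * 18), 10)
  donors <- list(regions = rep(c("A", "B"), each = 5), lmeasure = lm,
                 microenv = me)
  # the donor population containing the target itself -> self selected
  tf <- transfer_microenv_features(lm[3, ], "A", donors)
  expect_equal(tf$donor, 3L)
  expect_equal(tf$block, me[3, ])
  # one-donor region -> that donor
  donors1 <- list(regions = c("A", rep("B", 9)), lmeasure = lm, microenv = me)
  expect_equal(transfer_microenv_features(rnorm(18), "A", donors1)$donor, 1L)
  # exhaustive oracle
  z <- standardize(lm)
  target <- rnorm(18)
  zt <- (target - colMeans(lm)) / apply(lm, 2, function(x) sqrt(mean((x - mean(x))^2)))
  dd <- sqrt(rowSums(sweep(z[6:10, ], 2, zt)^2))
  expect_equal(transfer_microenv_features(target, "B", donors)$donor,
               5L + which.min(dd))
  expect_warning(out <- transfer_microenv_features(target, "Z", donors),
                 "no donor")
  expect_true(out$missing)
})

test_that("cross-scale assembly z-scores blocks in fixed order", {
  set.seed(62)
  ids <- paste0("n", 1:6)
  blocks <- list(
    microenviron = matrix(rnorm(6 * 18), 6, dimnames = list(ids, NULL)),
    fullMorpho = matrix(rnorm(6 * 18), 6, dimnames = list(ids, NULL)),
    arbor = matrix(rnorm(6 * 12), 6, dimnames = list(ids, NULL)),
    motif = matrix(rnorm(6 * 21), 6, dimnames = list(ids, NULL)),
    varicosity = matrix(rnorm(6 * 6), 6, dimnames = list(ids, NULL)))
  cst <- cross_scale_table(blocks)
  expect_equal(dim(cst), c(6L, 75L))
  bc <- attr(cst, "block_columns")
  expect_equal(names(bc), c("microenviron", "fullMorpho", "arbor", "motif",
                            "varicosity"))
  expect_equal(unname(lengths(bc)), c(18L, 18L, 12L, 21L, 6L))
  # block slices equal independently standardized module outputs
  expect_equal(unname(cst[, bc$arbor]),
               unname(standardize(blocks$arbor)), tolerance = 1e-12)
  # per-feature affine rescaling before z-scoring changes nothing
  blocks2 <- blocks
  blocks2$motif <- blocks$motif * 7 + 3
  expect_equal(unname(cross_scale_table(blocks2)), unname(cst),
               tolerance = 1e-12)
  # a neuron with a missing entry is excluded
  blocks$arbor[2, 1] <- NA
  expect_message(cst2 <- cross_scale_table(blocks), "excluding 1")
  expect_equal(attr(cst2, "excluded"), "n2")
  expect_equal(nrow(cst2), 5L)
})

test_that("DS matrices recover planted stereotypy and diversity", {
  for (rho in c(0, 0.5, 0.8)) {
    spec <- population_gen_spec(list(
      list(label = "A", center = c(0, 0, 0), extent = 100, n = 50, rho = rho),
      list(label = "B", center = c(1000, 0, 0), extent = 100, n = 50,
           rho = rho)), n_features = 75)
    pop <- synth_population(spec, seed = round(rho * 10) + 1)
    ds <- ds_matrix(pop$features, pop$somata$region)
    expect_true(all(abs(diag(ds$S) - rho) < 0.05))
    expect_lt(abs(ds$S["A", "B"]), 0.05)
    expect_equal(ds$S, t(ds$S))
    expect_equal(unname(ds$counts["A", "A"]), choose(50, 2))
    expect_equal(unname(ds$counts["A", "B"]), 50 * 50)
  }
  # within-type clones -> diagonal 1
  v <- rbind(matrix(rep(rnorm(10), 3), 3, byrow = TRUE),
             matrix(rep(rnorm(10), 3), 3, byrow = TRUE))
  ds <- ds_matrix(v, rep(c("A", "B"), each = 3))
  expect_equal(unname(diag(ds$S)), c(1, 1), tolerance = 1e-12)
  expect_warning(ds_matrix(v, c("A", rep("B", 5))), "undefined")
})

test_that("scale distances and intra-type moments behave as defined", {
  A <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  B <- matrix(c(.2, .9, .9, .3), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d <- scale_distance(list(s1 = A, s2 = A, s3 = B))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], d["s3", "s1"])
  # anti-correlated matrices -> distance 2
  d2 <- scale_distance(list(p = A, q = matrix(-as.vector(A), 2,
                                              dimnames = dimnames(A))))
  expect_equal(d2["p", "q"], 2)

  # moments match an independent implementation on a toy set
  set.seed(63)
  v <- matrix(rnorm(5 * 12), 5)
  m <- intra_moments(v, rep("T", 5))
  cc <- cor(t(v)); x <- cc[upper.tri(cc)]
  expect_equal(unname(m["T", "all", "mean"]), mean(x), tolerance = 1e-12)
  expect_equal(unname(m["T", "all", "skewness"]),
               e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(unname(m["T", "all", "kurtosis"]),
               e1071::kurtosis(x, type = 1), tolerance = 1e-12)
  # identical vectors -> mean 1, sd 0, higher moments flagged
  vi <- matrix(rep(rnorm(12), 4), 4, byrow = TRUE)
  mi <- intra_moments(vi, rep("T", 4))
  expect_equal(unname(mi["T", "all", "mean"]), 1)
  expect_equal(unname(mi["T", "all", "sd"]), 0)
  expect_true(is.na(mi["T", "all", "skewness"]))

  # DS diagonal equals the mean of the intra-type correlation distribution
  set.seed(64)
  vv <- matrix(rnorm(20 * 30), 20)
  lab <- rep(c("A", "B"), each = 10)
  ds <- ds_matrix(vv, lab)
  mm <- intra_moments(vv, lab)
  expect_equal(unname(diag(ds$S)), unname(mm[, "all", "mean"]),
               tolerance = 1e-12)
})

test_that("similarity decays with distance only when planted", {
  df <- decay_features()
  sv <- similarity_vs_distance(df$features, df$somas, max_d = 4000)
  expect_lte(sv$overall_correlation, -0.9)

  set.seed(65)
  f0 <- matrix(rnorm(80 * 40), 80)
  s0 <- cbind(runif(80, 0, 3000), runif(80, 0, 100), 0)
  sv0 <- similarity_vs_distance(f0, s0, max_d = 4000)
  expect_lt(abs(sv0$overall_correlation), 0.1)

  # bin means reproduce brute-force averages
  cc <- cor(t(df$features))
  dd <- as.matrix(dist(df$somas))
  ut <- upper.tri(dd)
  bins <- cut(dd[ut], seq(0, 4000, length.out = 21), include.lowest = TRUE,
              labels = FALSE)
  b1 <- mean(cc[ut][bins == 1])
  expect_equal(sv$curve$mean_r[1], b1, tolerance = 1e-12)
  expect_error(similarity_vs_distance(f0, s0 * 1e5, max_d = 10), "no pairs")
})

test_that("the end-to-end cross-scale builder yields 75 dimensions", {
  trees <- lapply(1:4, function(i) synth_neuron(neuron_gen_spec(
    n_stems = 2, max_depth = 3,
    axon = list(tract_length = 2000, n_arbors = 2, arbor_sep = 800,
                arbor_spread = 80, arbor_branches = 7)), seed = i))
  names(trees) <- paste0("n", 1:4)
  donors <- list(
    regions = rep(c("A", "B"), each = 2),
    lmeasure = t(vapply(trees, function(t)
      global_features(t)[morphoscales:::MICROENV_GLOBAL_NAMES], numeric(18))),
    microenv = matrix(rnorm(4 * 18), 4))
  vsets <- lapply(trees, function(tr) {
    ax <- tr$nodes[tr$nodes$type == 2, ][seq(1, 40, 8), ]
    data.frame(x = ax$x, y = ax$y, z = ax$z, branch = 1L,
               branch_arc = seq_along(ax$x) * 10)
  })
  blocks <- cross_scale_blocks(trees, donors, rep(c("A", "B"), each = 2),
                               vsets, seed = 1)
  expect_equal(unname(vapply(blocks, ncol, integer(1))),
               c(18L, 18L, 12L, 21L, 6L))
  cst <- cross_scale_table(blocks)
  expect_equal(ncol(cst), 75L)
  expect_equal(nrow(cst), 4L)
})
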