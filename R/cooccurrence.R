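# Neurite co-occurrence analysis: block-level neurite segmentation,
# region-by-brain density matrices, weighted Spearman correlation maps,
# target-correlated region sets, and tight-module detection.

#' Empirical foreground threshold of a brain
#'
#' `0.9 * min(max(mu + 1.5 * sigma, 400), 1000)` over a 16-bit intensity
#' sample.
#'
#' @param sample numeric vector of voxel intensities.
#' @return Threshold value.
#' @export
brain_threshold <- function(sample) {
  if (!length(sample)) stop("empty intensity sample")
  mu <- mean(sample)
  sigma <- sd(as.numeric(sample))
  if (is.na(sigma)) sigma <- 0
  0.9 * min(max(mu + 1.5 * sigma, 400), 1000)
}

#' Pre-filter an image block
#'
#' A block is skipped when its compressed size is below 1.7 MB or its
#' maximum intensity is below 300 (boundary value 300 is kept).
#'
#' @param max_intensity block maximum intensity.
#' @param compressed_size compressed file size in bytes.
#' @return `"keep"` or `"skip"`.
#' @export
block_prefilter <- function(max_intensity, compressed_size = Inf) {
  if (compressed_size < 1.7e6 || max_intensity < 300) "skip" else "keep"
}

# weighted covariance PCA eigenvalues of voxel coordinates (weights = intensity)
cuboid_eigen <- function(cub) {
  w <- as.numeric(cub)
  tot <- sum(w)
  if (tot <= 0) return(c(0, 0, 0))
  dims <- dim(cub)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                                  z = seq_len(dims[3L])))
  mu <- colSums(coords * w) / tot
  cc <- sweep(coords, 2L, mu)
  cov <- crossprod(cc * sqrt(w / tot))
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}

#' Anisotropy score map of an image block
#'
#' The block is tiled into `cuboid` x `cuboid` x `cuboid/z_upsample` voxel
#' cuboids; each is upsampled to isotropic shape (nearest-neighbor in z) and
#' scored by `(S1-S2)/(S1+S2) * (S1-S3)/(S1+S3)` where `S1 >= S2 >= S3` are
#' the eigenvalues of the intensity-weighted coordinate PCA. Flat cuboids
#' score 0; scores lie in `[0, 1]`.
#'
#' @param block 3-D array.
#' @param cuboid isotropic cuboid edge (voxels), default 16.
#' @param z_upsample z anisotropy factor, default 4.
#' @return List with `score` (array over cuboid grid) and `grid` dims.
#' @export
anisotropy_map <- function(block, cuboid = 16L, z_upsample = 4L) {
  dims <- dim(block)
  zc <- max(1L, cuboid %/% z_upsample)
  nx <- max(1L, dims[1L] %/% cuboid)
  ny <- max(1L, dims[2L] %/% cuboid)
  nz <- max(1L, dims[3L] %/% zc)
  score <- array(0, c(nx, ny, nz))
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) for (iz in seq_len(nz)) {
    xs <- ((ix - 1L) * cuboid + 1L):min(ix * cuboid, dims[1L])
    ys <- ((iy - 1L) * cuboid + 1L):min(iy * cuboid, dims[2L])
    zs <- ((iz - 1L) * zc + 1L):min(iz * zc, dims[3L])
    cub <- block[xs, ys, zs, drop = FALSE]
    cub <- cub[, , rep(seq_len(dim(cub)[3L]), each = z_upsample), drop = FALSE]
    ev <- sort(cuboid_eigen(cub), decreasing = TRUE)
    s <- if (ev[1L] + ev[2L] > 0 && ev[1L] + ev[3L] > 0)
      (ev[1L] - ev[2L]) / (ev[1L] + ev[2L]) * (ev[1L] - ev[3L]) / (ev[1L] + ev[3L])
    else 0
    score[ix, iy, iz] <- s
  }
  list(score = score, grid = c(nx, ny, nz), cuboid = cuboid, z_cuboid = zc)
}

# local-mean-subtraction denoise (window w^3, negatives clipped) via a
# 3-D integral image
box_mean3 <- function(a, w = 5L) {
  dims <- dim(a)
  k <- (w - 1L) %/% 2L
  cs <- array(0, dims + 1L)
  cs[-1L, -1L, -1L] <- a
  for (i in 2L:(dims[1L] + 1L)) cs[i, , ] <- cs[i, , ] + cs[i - 1L, , ]
  for (j in 2L:(dims[2L] + 1L)) cs[, j, ] <- cs[, j, ] + cs[, j - 1L, ]
  for (l in 2L:(dims[3L] + 1L)) cs[, , l] <- cs[, , l] + cs[, , l - 1L]
  lo <- lapply(dims, function(d) pmax(seq_len(d) - k, 1L))
  hi <- lapply(dims, function(d) pmin(seq_len(d) + k, d))
  out <- array(0, dims)
  nx <- hi[[1L]] - lo[[1L]] + 1L
  ny <- hi[[2L]] - lo[[2L]] + 1L
  nz <- hi[[3L]] - lo[[3L]] + 1L
  S <- function(i, j, l) cs[i + 1L, j + 1L, l + 1L]
  for (z in seq_len(dims[3L])) for (y in seq_len(dims[2L])) {
    z0 <- lo[[3L]][z] - 1L; z1 <- hi[[3L]][z]
    y0 <- lo[[2L]][y] - 1L; y1 <- hi[[2L]][y]
    x0 <- lo[[1L]] - 1L; x1 <- hi[[1L]]
    tot <- S(x1, y1, z1) - S(x0, y1, z1) - S(x1, y0, z1) - S(x1, y1, z0) +
      S(x0, y0, z1) + S(x0, y1, z0) + S(x1, y0, z0) - S(x0, y0, z0)
    out[, y, z] <- tot / (nx * ny[y] * nz[z])
  }
  out
}

#' Segment neurite voxels in a block
#'
#' The block is denoised by local mean subtraction (window 5^3, negatives
#' clipped), multiplied by the upsampled anisotropy score, and thresholded
#' at `0.1 * thresh`.
#'
#' @param block 3-D array.
#' @param thresh brain-level threshold from [brain_threshold()].
#' @param cuboid,z_upsample passed to [anisotropy_map()].
#' @param denoise_window local-mean window, default 5.
#' @return Logical mask array of the block's dimensions.
#' @export
segment_neurites <- function(block, thresh, cuboid = 16L, z_upsample = 4L,
                             denoise_window = 5L) {
  den <- pmax(block - box_mean3(block, denoise_window), 0)
  am <- anisotropy_map(block, cuboid, z_upsample)
  dims <- dim(block)
  ix <- pmin(ceiling(seq_len(dims[1L]) / am$cuboid), am$grid[1L])
  iy <- pmin(ceiling(seq_len(dims[2L]) / am$cuboid), am$grid[2L])
  iz <- pmin(ceiling(seq_len(dims[3L]) / am$z_cuboid), am$grid[3L])
  sal <- den * am$score[ix, iy, iz]
  array(sal > 0.1 * thresh, dims)
}

#' Region-by-brain neurite density matrix
#'
#' Per brain, neurite-mask voxels are counted per region label and divided
#' by the brain total, so each column is a probability vector.
#'
#' @param masks named list of logical mask arrays (one per brain).
#' @param labels integer label array (same dims) or per-voxel label vector.
#' @param regions region label universe (defaults to labels present).
#' @return Matrix regions x brains; columns with no signal are flagged via
#'   attribute `invalid_brains`.
#' @export
density_matrix <- function(masks, labels, regions = NULL) {
  lab <- as.integer(labels)
  if (is.null(regions)) regions <- sort(unique(lab[lab > 0L]))
  out <- vapply(masks, function(m) {
    v <- lab[as.logical(m)]
    v <- v[v > 0L]
    cnt <- tabulate(match(v, regions), nbins = length(regions))
    tot <- sum(cnt)
    if (tot > 0) cnt / tot else rep(0, length(regions))
  }, numeric(length(regions)))
  rownames(out) <- as.character(regions)
  invalid <- names(masks)[colSums(out) == 0]
  attr(out, "invalid_brains") <- invalid
  out
}

#' Weighted Spearman rank correlation
#'
#' Ranks (average ranks on ties) of both vectors correlated by weighted
#' Pearson with weights `w`: with uniform weights this reduces exactly to
#' the ordinary Spearman coefficient.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param w positive weights (defaults to uniform).
#' @return Correlation coefficient, or `NA` when a rank vector is constant.
#' @export
weighted_spearman <- function(x, y, w = NULL) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3")
  if (is.null(w)) w <- rep(1, n)
  if (any(w <= 0)) stop("weights must be positive")
  rx <- rank(x); ry <- rank(y)
  if (length(unique(rx)) < 2L || length(unique(ry)) < 2L) return(NA_real_)
  w <- w / sum(w)
  mx <- sum(w * rx); my <- sum(w * ry)
  vx <- sum(w * (rx - mx)^2); vy <- sum(w * (ry - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (rx - mx) * (ry - my)) / sqrt(vx * vy)
}

#' Pairwise regional correlation map
#'
#' All region pairs of a density matrix correlated by [weighted_spearman()]
#' with per-brain weights (e.g. reciprocal of the brain count of each
#' transgenic line; brains without line information get the mean weight).
#'
#' @param M_d density matrix (regions x brains).
#' @param brain_lines optional character vector of line labels per brain
#'   (`NA` = unlabeled); used to build reciprocal weights.
#' @param weights explicit per-brain weights (overrides `brain_lines`).
#' @return Symmetric correlation matrix with unit diagonal; all-zero region
#'   rows yield `NA` correlations.
#' @export
correlation_map <- function(M_d, brain_lines = NULL, weights = NULL) {
  if (ncol(M_d) < 3L) stop("need >= 3 brains")
  if (is.null(weights)) {
    weights <- if (is.null(brain_lines)) rep(1, ncol(M_d)) else line_weights(brain_lines)
  }
  n <- nrow(M_d)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(M_d), rownames(M_d)))
  for (i in seq_len(n)) {
    out[i, i] <- 1
    if (i < n) for (j in (i + 1L):n) {
      r <- weighted_spearman(M_d[i, ], M_d[j, ], weights)
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Reciprocal-of-line-size brain weights
#' @param brain_lines character vector of transgenic-line labels per brain,
#'   `NA` for unlabeled brains (these receive the mean labeled weight).
#' @return Positive weight per brain.
#' @export
line_weights <- function(brain_lines) {
  tab <- table(brain_lines, useNA = "no")
  w <- 1 / as.numeric(tab[match(brain_lines, names(tab))])
  if (anyNA(w)) w[is.na(w)] <- mean(w, na.rm = TRUE)
  if (all(is.na(w))) w <- rep(1, length(brain_lines))
  w
}

#' Target-correlated region sets
#'
#' For each target region, the set of other regions whose correlation with
#' the target is at least `tau` (boundary inclusive). With a compound-area
#' map, sets are tagged intra-CA when the target and all members share one
#' compound area.
#'
#' @param M_c correlation map.
#' @param tau correlation threshold, default 0.5.
#' @param ca_map optional named vector region -> compound area.
#' @return Named list per region: `members`, `tag` (`"intra-CA"`,
#'   `"cross-CA"` or `NA`).
#' @export
target_sets <- function(M_c, tau = 0.5, ca_map = NULL) {
  regions <- rownames(M_c)
  out <- lapply(seq_along(regions), function(i) {
    members <- regions[which(M_c[i, ] >= tau & seq_along(regions) != i)]
    tag <- if (is.null(ca_map) || !length(members)) NA_character_
    else if (length(unique(ca_map[c(regions[i], members)])) == 1L) "intra-CA"
    else "cross-CA"
    list(members = members, tag = tag)
  })
  names(out) <- regions
  out
}

# recursive dendrogram walk (see detect_modules): accept a node as an
# initial module when it has min_size..max_size leaves and its merge height
# is at most 1 - c_min (under average linkage on 1 - M_c the node height is
# exactly one minus the mean correlation between its two sub-clusters);
# otherwise descend into the children.
walk_dendrogram <- function(merge, heights, node, leaves_of, M_c,
                            min_size, max_size, c_min) {
  if (node < 0) return(list()) # a single leaf cannot be a module
  leaves <- leaves_of(node)
  n <- length(leaves)
  if (n >= min_size && n <= max_size && heights[node] <= 1 - c_min) {
    sub <- M_c[leaves, leaves]
    return(list(list(regions = leaves,
                     consistency = mean(sub[upper.tri(sub)], na.rm = TRUE))))
  }
  out <- list()
  for (k in merge[node, ])
    out <- c(out, walk_dendrogram(merge, heights, k, leaves_of, M_c,
                                  min_size, max_size, c_min))
  out
}

#' Detect tight regional modules from a correlation map
#'
#' Average-linkage hierarchical clustering on `1 - M_c` is walked top-down:
#' a cluster becomes an initial module when it has 3..30 leaves and its merge
#' height is at most `1 - c_min` (i.e. its two sub-clusters correlate by at
#' least `c_min` on average); otherwise it is split into its children.
#' Initial modules are
#' then filtered: regions occurring fewer than `min_occurrence` times across
#' all target-correlated region sets are dropped, and modules keeping at
#' least 2 regions are reported as tight modules with their consistency.
#'
#' @param M_c correlation map (>= 3 regions).
#' @param sets target sets from [target_sets()] (recomputed at `tau = 0.5`
#'   when `NULL`).
#' @param min_size,max_size module size limits (3 and 30).
#' @param c_min consistency gate for accepting a cluster, default 0.4.
#' @param min_occurrence target-set occurrence filter, default 2.
#' @return List of modules: `regions`, `consistency`, plus attribute
#'   `initial` (pre-filter modules).
#' @export
detect_modules <- function(M_c, sets = NULL, min_size = 3L, max_size = 30L,
                           c_min = 0.4, min_occurrence = 2L) {
  n <- nrow(M_c)
  if (n < 3L) stop("need >= 3 regions")
  if (is.null(sets)) sets <- target_sets(M_c, tau = 0.5)
  d <- as.dist(1 - M_c)
  hc <- hclust(d, method = "average")
  leaves_cache <- new.env(parent = emptyenv())
  leaves_of <- function(node) {
    if (node < 0) return(rownames(M_c)[-node])
    key <- as.character(node)
    if (!is.null(leaves_cache[[key]])) return(leaves_cache[[key]])
    v <- c(leaves_of(hc$merge[node, 1L]), leaves_of(hc$merge[node, 2L]))
    leaves_cache[[key]] <- v
    v
  }
  initial <- walk_dendrogram(hc$merge, hc$height, nrow(hc$merge), leaves_of,
                             M_c, min_size, max_size, c_min)
  occurrence <- table(unlist(lapply(sets, `[[`, "members")))
  keep_region <- function(r) !is.na(occurrence[r]) && occurrence[r] >= min_occurrence
  tight <- list()
  for (m in initial) {
    kept <- m$regions[vapply(m$regions, keep_region, logical(1))]
    if (length(kept) >= 2L) {
      sub <- M_c[kept, kept]
      tight[[length(tight) + 1L]] <-
        list(regions = kept, consistency = mean(sub[upper.tri(sub)], na.rm = TRUE))
    }
  }
  attr(tight, "initial") <- initial
  tight
}

#' Intra-compound-area consistency distributions
#'
#' For each compound area, the multiset of pairwise correlations among its
#' member regions, with five-number summaries.
#'
#' @param M_c correlation map.
#' @param ca_map named vector region -> compound area.
#' @return Named list per CA: `values` and `summary` (quantiles); CAs with
#'   fewer than 2 regions are skipped.
#' @export
intra_ca_consistency <- function(M_c, ca_map) {
  cas <- unique(ca_map[rownames(M_c)])
  out <- list()
  for (ca in cas[!is.na(cas)]) {
    members <- intersect(rownames(M_c), names(ca_map)[ca_map == ca])
    if (length(members) < 2L) next
    sub <- M_c[members, members]
    vals <- sub[upper.tri(sub)]
    out[[ca]] <- list(values = vals,
                      summary = quantile(vals, c(0, 0.25, 0.5, 0.75, 1),
                                         na.rm = TRUE))
  }
  out
}
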