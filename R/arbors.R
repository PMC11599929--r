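# Arbor decomposition: axons are split into dense sub-trees by spectral
# clustering on the all-pairs affinity exp(-d/sigma); the complete dendrites
# form one arbor per neuron. Arbors are typed proximal/distal by the distance
# of their densest node from the soma (threshold 750 um) and ordered A1..Ak.

#' Proximal/distal arbor threshold (um)
#' @export
ARBOR_PROXIMAL_THRESHOLD <- 750

#' Decompose a neuron into arbors
#'
#' Axonal nodes are clustered by spectral clustering of the affinity
#' `W_uv = exp(-d_uv / sigma)` over all node pairs (d in um). When the axon
#' exceeds `max_nodes` nodes, a deterministic arc-length-uniform subsample is
#' clustered and the remaining nodes are assigned to the nearest labeled
#' node. The dendrites are returned as one additional arbor.
#'
#' @param tree a valid [neuron_tree()].
#' @param k number of axonal arbors (use [auto_arbor_count()] to choose).
#' @param seed integer seed for the embedded k-means.
#' @param sigma affinity length scale (um), default 100.
#' @param max_nodes subsampling cap for the affinity matrix.
#' @return List of arbors: each a list with `ids` (node ids), `kind`
#'   (`"axonal"` or `"dendritic"`).
#' @export
arborize <- function(tree, k, seed = 1L, sigma = 100, max_nodes = 2000L) {
  ax <- which(tree$nodes$type == SWC_AXON)
  if (k < 1L || k > length(ax)) stop("k must be in 1..", length(ax))
  if (k == 1L) {
    labels <- rep(1L, length(ax))
  } else {
    pd <- path_distance_all(tree)
    ord <- ax[order(pd[ax], tree$nodes$id[ax])]
    sub <- if (length(ord) > max_nodes)
      ord[round(seq(1L, length(ord), length.out = max_nodes))] else ord
    pos <- node_xyz(tree, sub)
    W <- exp(-as.matrix(stats::dist(pos)) / sigma)
    diag(W) <- 0
    sub_labels <- spectral_clusters(W, k = k, seed = seed)
    labels <- integer(length(ax))
    names(labels) <- ax
    labels[as.character(sub)] <- sub_labels
    rest <- setdiff(ax, sub)
    if (length(rest)) {
      rp <- node_xyz(tree, rest)
      for (i in seq_along(rest)) {
        d2 <- rowSums(sweep(pos, 2L, rp[i, ])^2)
        labels[as.character(rest[i])] <- sub_labels[which.min(d2)]
      }
    }
    labels <- labels[as.character(ax)]
  }
  arbors <- lapply(sort(unique(labels)), function(l)
    list(ids = tree$nodes$id[ax[labels == l]], kind = "axonal"))
  dend <- which(tree$nodes$type %in% c(SWC_BASAL, SWC_APICAL))
  if (length(dend))
    arbors <- c(arbors, list(list(ids = tree$nodes$id[dend], kind = "dendritic")))
  arbors
}

#' Automatic arbor count by the normalized-Laplacian eigengap
#'
#' The count is the `k` in 1..kmax maximizing the relative eigengap
#' `(lambda[k+1] - lambda[k]) / (lambda[k+1] + delta)` of the normalized
#' Laplacian; the regularizer `delta` suppresses spurious gaps between
#' near-zero eigenvalues, so `k` well-separated clusters (whose first `k`
#' eigenvalues are essentially 0) score close to 1 at `k`.
#'
#' @param tree a valid [neuron_tree()].
#' @param kmax maximum count considered.
#' @param sigma affinity length scale (um).
#' @param max_nodes subsampling cap.
#' @param delta relative-gap regularizer.
#' @return Integer count in 1..kmax (ties toward smaller k).
#' @export
auto_arbor_count <- function(tree, kmax = 5L, sigma = 100, max_nodes = 1000L,
                             delta = 1e-3) {
  ax <- which(tree$nodes$type == SWC_AXON)
  if (length(ax) < 2L) return(1L)
  pd <- path_distance_all(tree)
  ord <- ax[order(pd[ax], tree$nodes$id[ax])]
  sub <- if (length(ord) > max_nodes)
    ord[round(seq(1L, length(ord), length.out = max_nodes))] else ord
  W <- exp(-as.matrix(stats::dist(node_xyz(tree, sub))) / sigma)
  diag(W) <- 0
  lam <- pmax(normalized_laplacian_eigenvalues(W), 0)
  kmax <- min(kmax, length(lam) - 1L)
  gaps <- (lam[2:(kmax + 1L)] - lam[1:kmax]) / (lam[2:(kmax + 1L)] + delta)
  which.max(gaps) # ties: which.max returns the first (smaller k)
}

#' Majority-vote arbor count per region
#'
#' Each neuron's count is chosen by [auto_arbor_count()]; the region count is
#' the mode over its neurons (ties toward the smaller count).
#'
#' @param trees list of [neuron_tree()].
#' @param regions region label per tree.
#' @param kmax,sigma passed to [auto_arbor_count()].
#' @return Named integer vector of counts per region.
#' @export
region_arbor_count <- function(trees, regions, kmax = 5L, sigma = 100) {
  counts <- vapply(trees, auto_arbor_count, integer(1), kmax = kmax, sigma = sigma)
  vapply(split(counts, regions), function(x) {
    tab <- table(x)
    best <- max(tab)
    min(as.integer(names(tab)[tab == best]))
  }, integer(1))
}

# volume of the rotated bounding box: PCA-seeded, refined by minimizing the
# box volume over orientations (handles degenerate/isotropic point sets where
# raw PCA axes are ill-defined)
rotation_matrix <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rotated bounding-box volume of a point set
#'
#' The box orientation minimizes the axis-aligned bounding volume in the
#' rotated frame, searched by Nelder-Mead from the PCA axes plus a fixed set
#' of rotations relative to them (keeping the estimator equivariant under
#' rigid motion of the input).
#'
#' @param points numeric matrix (n x 3).
#' @return Volume in cubic micrometres (0 for degenerate sets).
#' @export
pca_box_volume <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) return(0)
  ctr <- sweep(points, 2L, colMeans(points))
  ev <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)
  B <- ev$vectors
  vol_at <- function(a, base) {
    proj <- ctr %*% (base %*% rotation_matrix(a))
    prod(apply(proj, 2L, function(x) diff(range(x))))
  }
  starts <- list(c(0, 0, 0), c(pi / 4, 0, 0), c(0, pi / 4, 0), c(0, 0, pi / 4),
                 c(pi / 4, pi / 4, 0), c(0, pi / 4, pi / 4),
                 c(pi / 4, 0, pi / 4), c(pi / 6, pi / 6, pi / 6))
  best <- Inf
  for (s in starts) {
    o <- optim(s, vol_at, base = B, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 3000))
    if (o$value < best) best <- o$value
  }
  min(best, vol_at(c(0, 0, 0), B))
}

#' Arbor features
#'
#' `n_branch` counts branches whose nodes all lie in the arbor; `max_density`
#' is the largest number of member nodes within a 20 um radius of any member
#' node (self included); `dist2soma` is the Euclidean distance from the
#' densest node (lowest id on ties) to the soma; `volume` is the rotated
#' bounding-box volume ([pca_box_volume()]).
#'
#' @param arbor an arbor from [arborize()] (list with `ids`), or a vector of
#'   node ids.
#' @param tree the parent [neuron_tree()].
#' @param density_radius density counting radius (um), default 20.
#' @return Named numeric vector: n_branch, volume, max_density, dist2soma.
#' @export
arbor_features <- function(arbor, tree, density_radius = 20) {
  ids <- if (is.list(arbor)) arbor$ids else arbor
  if (!length(ids)) stop("empty arbor")
  rows <- node_row(tree, ids)
  pos <- node_xyz(tree, rows)
  n <- length(ids)
  if (n == 1L) {
    dens <- 1L; dens_node <- 1L
  } else {
    d <- as.matrix(stats::dist(pos))
    cnt <- rowSums(d <= density_radius) # self included (d_ii = 0)
    dens <- max(cnt)
    dens_node <- which(cnt == dens)
    dens_node <- dens_node[which.min(ids[dens_node])]
  }
  sr <- soma_row(tree)
  d2s <- sqrt(sum((pos[dens_node, ] - unlist(tree$nodes[sr, c("x", "y", "z")]))^2))
  branches <- branch_decomposition(tree)
  inb <- vapply(branches, function(b) all(b$ids[-1L] %in% ids), logical(1))
  c(n_branch = sum(inb), volume = pca_box_volume(pos),
    max_density = dens, dist2soma = d2s)
}

#' Classify and order a neuron's arbors
#'
#' Arbors are `proximal` when `dist2soma <= 750` um (boundary inclusive),
#' else `distal`, and labeled A1..Ak in ascending `dist2soma`.
#'
#' @param arbor_table data.frame with a `dist2soma` column (one row per
#'   arbor of a single neuron).
#' @param threshold proximal/distal boundary (um).
#' @return The table with added `type` and `label` columns.
#' @export
classify_and_order <- function(arbor_table, threshold = ARBOR_PROXIMAL_THRESHOLD) {
  arbor_table$type <- ifelse(arbor_table$dist2soma <= threshold,
                             "proximal", "distal")
  ord <- order(arbor_table$dist2soma)
  arbor_table$label <- NA_character_
  arbor_table$label[ord] <- paste0("A", seq_len(nrow(arbor_table)))
  arbor_table
}

#' Min-max normalized region-by-arbor feature matrix
#'
#' Each feature is min-max normalized over all arbors of all regions; a
#' region's value for (arbor label, feature) is the mean over its neurons'
#' arbors with that label.
#'
#' @param arbor_table data.frame with columns `region`, `label` and feature
#'   columns.
#' @param features feature column names.
#' @return Matrix: regions x (label.feature) of mean normalized values in
#'   `[0, 1]` (NA where a region lacks an arbor label).
#' @export
normalize_arbor_matrix <- function(arbor_table, features) {
  for (f in features) {
    v <- arbor_table[[f]]
    rng <- range(v)
    if (rng[2L] == rng[1L]) {
      warning("constant feature '", f, "' mapped to 0")
      arbor_table[[f]] <- 0
    } else {
      arbor_table[[f]] <- (v - rng[1L]) / (rng[2L] - rng[1L])
    }
  }
  regions <- sort(unique(arbor_table$region))
  labels <- sort(unique(arbor_table$label))
  cols <- as.vector(outer(labels, features, paste, sep = "."))
  out <- matrix(NA_real_, length(regions), length(cols),
                dimnames = list(regions, cols))
  for (rg in regions) for (lb in labels) {
    sub <- arbor_table[arbor_table$region == rg & arbor_table$label == lb, ,
                       drop = FALSE]
    if (nrow(sub))
      out[rg, paste(lb, features, sep = ".")] <-
        colMeans(sub[, features, drop = FALSE])
  }
  out
}
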