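# Spatially tuned full-morphology similarity and spectral clustering.
# The pairwise similarity is the product of the cosine similarity between
# z-scored 47-dim feature vectors and an exponential spatial coefficient
# exp(-d_ij / d_max), where d_max is the population's maximum pairwise soma
# distance. Negative products are clipped at 0 when used as affinities.

#' Spatially tuned similarity matrix
#'
#' @param features numeric matrix (neurons x features), not yet z-scored.
#' @param somas numeric matrix (neurons x 3) of soma positions (um).
#' @param ids optional neuron ids (must be unique).
#' @return List of class `similarity_matrix` with `feature` (cosine term),
#'   `spatial` (exponential term), `similarity` (product) and `affinity`
#'   (product floored at 0), all dense symmetric with unit diagonal.
#' @export
spatially_tuned_similarity <- function(features, somas, ids = NULL) {
  features <- as.matrix(features); somas <- as.matrix(somas)
  n <- nrow(features)
  if (n < 2L) stop("need >= 2 neurons")
  if (is.null(ids)) ids <- rownames(features) %||% seq_len(n)
  if (anyDuplicated(ids)) stop("duplicate neuron ids")
  z <- suppressWarnings(standardize(features))
  nrm <- sqrt(rowSums(z^2))
  nrm[nrm == 0] <- 1
  zn <- z / nrm
  fsim <- tcrossprod(zn)
  diag(fsim) <- 1
  d <- as.matrix(stats::dist(somas))
  dmax <- max(d)
  ssim <- if (dmax > 0) exp(-d / dmax) else matrix(1, n, n)
  sim <- fsim * ssim
  aff <- pmax(sim, 0)
  dimnames(sim) <- dimnames(aff) <- dimnames(fsim) <- dimnames(ssim) <- list(ids, ids)
  structure(list(feature = fsim, spatial = ssim, similarity = sim,
                 affinity = aff), class = "similarity_matrix")
}

# k-means that tolerates k == nrow(x) (each point its own cluster)
safe_kmeans <- function(x, k, nstart) {
  x <- as.matrix(x)
  if (k >= nrow(x)) {
    if (k > nrow(x)) stop("more cluster centres than points")
    return(list(cluster = seq_len(nrow(x)), tot.withinss = 0))
  }
  kmeans(x, centers = k, nstart = nstart)
}

# Ng-Jordan-Weiss spectral embedding: top-k eigenvectors of the normalized
# affinity D^-1/2 W D^-1/2, rows renormalized to the unit sphere
spectral_embedding <- function(W, k) {
  deg <- rowSums(W)
  deg[deg == 0] <- 1
  s <- 1 / sqrt(deg)
  L <- W * outer(s, s)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U / rn
}

# eigenvalues of the normalized Laplacian I - D^-1/2 W D^-1/2, ascending
normalized_laplacian_eigenvalues <- function(W) {
  deg <- rowSums(W)
  deg[deg == 0] <- 1
  s <- 1 / sqrt(deg)
  L <- diag(nrow(W)) - W * outer(s, s)
  rev(eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Spectral clustering of an affinity matrix
#'
#' Normalized-Laplacian spectral embedding followed by k-means under a fixed
#' seed. If the affinity graph is disconnected, the connected components are
#' clustered separately with the cluster budget split proportionally to
#' component size (every component receives at least one cluster).
#'
#' @param S a `similarity_matrix` from [spatially_tuned_similarity()], or a
#'   non-negative symmetric affinity matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return Integer cluster labels (named by neuron id when available).
#' @export
spectral_clusters <- function(S, k = 4L, seed = 1L, nstart = 20L) {
  W <- if (inherits(S, "similarity_matrix")) S$affinity else as.matrix(S)
  n <- nrow(W)
  if (k > n) stop("k exceeds the number of neurons")
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  labels <- integer(n)
  if (comp$no == 1L) {
    U <- spectral_embedding(W, k)
    labels <- with_seed(seed, safe_kmeans(U, k, nstart))$cluster
  } else {
    if (k < comp$no)
      stop("affinity graph has ", comp$no, " components but k = ", k)
    sizes <- comp$csize
    alloc <- pmax(1L, floor(k * sizes / sum(sizes)))
    while (sum(alloc) < k) { # give leftovers to the largest components
      i <- which.max(sizes / alloc)
      alloc[i] <- alloc[i] + 1L
    }
    while (sum(alloc) > k) {
      i <- which(alloc > 1L)[which.max(alloc[alloc > 1L] / sizes[alloc > 1L])]
      alloc[i] <- alloc[i] - 1L
    }
    offset <- 0L
    for (ci in seq_len(comp$no)) {
      members <- which(comp$membership == ci)
      kc <- alloc[ci]
      if (kc >= length(members)) {
        labels[members] <- offset + seq_along(members)
        offset <- offset + length(members)
      } else if (kc == 1L) {
        labels[members] <- offset + 1L
        offset <- offset + 1L
      } else {
        U <- spectral_embedding(W[members, members, drop = FALSE], kc)
        cl <- with_seed(seed + ci, safe_kmeans(U, kc, nstart))$cluster
        labels[members] <- offset + cl
        offset <- offset + kc
      }
    }
  }
  names(labels) <- rownames(W)
  labels
}

#' Silhouette coefficient
#'
#' The standard silhouette with Euclidean distance: for each point,
#' `(b - a) / max(a, b)` where `a` is the mean distance to its own cluster
#' and `b` the smallest mean distance to another cluster. Singleton clusters
#' score 0.
#'
#' @param points numeric matrix (positions or features).
#' @param labels cluster labels (>= 2 clusters).
#' @return List with `mean` and per-point `values`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  cls <- unique(labels)
  if (length(cls) < 2L) stop("need >= 2 clusters")
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { vals[i] <- 0; next }
    a <- sum(d[i, own]) / (length(own) - 1L)
    b <- min(vapply(setdiff(cls, labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    vals[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(mean = mean(vals), values = vals)
}

#' Per-cluster-pair discriminating-feature hit rates
#'
#' For every unordered pair of clusters, [mrmr_select()] picks the top `k`
#' discriminating features on the two clusters' rows only; selections are
#' tallied per feature over all pairs (6 rounds for 4 clusters).
#'
#' @param features numeric matrix (neurons x features).
#' @param labels cluster labels.
#' @param k features selected per pair.
#' @return List with `hits` (feature x pair logical-count matrix) and
#'   `rate` (total selections per feature).
#' @export
discriminator_hit_rates <- function(features, labels, k = 3L) {
  features <- as.matrix(features)
  tab <- table(labels)
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < 2L) stop("need >= 2 clusters of size >= 2")
  pairs <- combn(usable, 2L)
  hits <- matrix(0L, ncol(features), ncol(pairs),
                 dimnames = list(colnames(features),
                                 apply(pairs, 2L, paste, collapse = "|")))
  for (j in seq_len(ncol(pairs))) {
    sel <- labels %in% pairs[, j]
    chosen <- mrmr_select(features[sel, , drop = FALSE], labels[sel], k = k)
    hits[chosen, j] <- 1L
  }
  list(hits = hits, rate = rowSums(hits))
}
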