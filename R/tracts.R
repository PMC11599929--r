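# Primary axonal tracts: the longest soma-to-tip axonal path after
# iteratively pruning terminal segments shorter than the second-longest
# axonal path; bundles of tracts are profiled by their cross-sectional
# spread and classified as convergent / divergent / parallel.

#' Extract the primary axonal tract of a neuron
#'
#' The main path is the axonal soma-to-tip path of maximal path length. With
#' `L2` the length of the second-longest axonal branch segment, terminal
#' segments of the main path shorter than `L2` are deleted from the tip
#' toward the soma (re-terminating at the preceding bifurcation) until the
#' terminal segment is at least `L2` long or no internal bifurcation remains
#' on the path. Short distal twigs and arbor branches are thereby stripped
#' while the long projecting trunk segments are kept.
#'
#' @param tree a valid [neuron_tree()] with a nonempty axon.
#' @return A [primary_tract_obj()] directed soma to terminus.
#' @export
primary_tract <- function(tree) {
  nodes <- tree$nodes
  ax <- which(nodes$type == SWC_AXON)
  if (!length(ax)) stop("neuron has no axon")
  kids <- children_index(tree)
  # children counts within the axon
  ax_kids <- lapply(kids, function(k) k[nodes$type[k] == SWC_AXON])
  nax <- lengths(ax_kids)
  pd <- path_distance_all(tree)
  tips <- ax[nax[ax] == 0L]
  main_tip <- tips[which.max(pd[tips])]
  prow <- node_row(tree, nodes$parent)

  path_to_root <- function(row) {
    p <- row
    while (!is.na(prow[p[1L]])) p <- c(prow[p[1L]], p)
    p
  }
  main_path <- path_to_root(main_tip)

  # terminal branch of a tip: nodes distal to the last axonal bifurcation
  last_bif_on <- function(path) {
    internal <- path[nax[path] >= 2L & nodes$type[path] == SWC_AXON]
    if (length(internal)) internal[length(internal)] else NA_integer_
  }
  # reference length: the second-longest axonal branch segment
  seg_lens <- vapply(branch_decomposition(tree, types = SWC_AXON),
                     function(b) polyline_length(node_xyz(tree, b$rows)),
                     numeric(1))
  L2 <- if (length(seg_lens) >= 2L) sort(seg_lens, decreasing = TRUE)[2L] else 0

  path <- main_path
  repeat {
    lb <- last_bif_on(path[-length(path)]) # bifurcation strictly before terminus
    if (is.na(lb)) break
    seg_len <- pd[path[length(path)]] - pd[lb]
    if (seg_len >= L2) break
    path <- path[seq_len(match(lb, path))]
  }
  primary_tract_obj(node_xyz(tree, path),
                    neuron_id = tree$meta$neuron_id %||% NA,
                    radii = nodes$radius[path])
}

#' Cross-sectional radius profile of a tract bundle
#'
#' Each tract is resampled to `n_samples` equal-arc-length points. At each
#' fractional position the bundle's points are projected onto their first two
#' principal axes, and the radius is the 75th percentile (linear
#' interpolation) of the in-plane distances to the centroid.
#'
#' @param tracts list of [primary_tract_obj()] (>= 3).
#' @param n_samples profile length, default 200.
#' @param percentile radius percentile, default 0.75.
#' @return List of class `radius_profile`: `t` (fractional arc length),
#'   `r` (um), `n` (bundle size).
#' @export
radius_profile <- function(tracts, n_samples = 200L, percentile = 0.75) {
  n <- length(tracts)
  if (n < 3L) stop("need >= 3 tracts for a radius profile")
  res <- lapply(tracts, function(tr) resample_polyline(tr$points, n_samples))
  r <- vapply(seq_len(n_samples), function(t) {
    P <- t(vapply(res, function(m) m[t, ], numeric(3)))
    ctr <- sweep(P, 2L, colMeans(P))
    if (all(abs(ctr) < 1e-12)) return(0)
    ev <- eigen(crossprod(ctr) / n, symmetric = TRUE)
    proj <- ctr %*% ev$vectors[, 1:2, drop = FALSE]
    unname(quantile(sqrt(rowSums(proj^2)), percentile, type = 7))
  }, numeric(1))
  structure(list(t = seq(0, 1, length.out = n_samples), r = r, n = n),
            class = "radius_profile")
}

#' Classify the projection pattern of a tract bundle
#'
#' With `r0` the mean radius over the first 5% of arc length and `r1` over
#' the last 5%, both floored at `eps`: divergent when `r1 / r0 >= tau`,
#' convergent when `r0 / r1 >= tau`, else parallel.
#'
#' @param profile a `radius_profile`.
#' @param tau spread-ratio threshold, default 2.
#' @param eps radius floor (um), default 10.
#' @return `"convergent"`, `"divergent"` or `"parallel"`.
#' @export
classify_pattern <- function(profile, tau = 2, eps = 10) {
  r0 <- max(mean(profile$r[profile$t <= 0.05]), eps)
  r1 <- max(mean(profile$r[profile$t >= 0.95]), eps)
  if (r1 / r0 >= tau) "divergent"
  else if (r0 / r1 >= tau) "convergent"
  else "parallel"
}

#' Terminus-minus-soma radius difference of a bundle profile
#'
#' @param profile a `radius_profile`.
#' @return `r(1) - r(0)` in um (unfloored).
#' @export
delta_radius <- function(profile) {
  profile$r[length(profile$r)] - profile$r[1L]
}

#' Cluster tracts by their terminal points
#'
#' K-means on terminus coordinates under a fixed seed; each cluster with at
#' least 3 members also carries its own radius profile and pattern.
#'
#' @param tracts list of [primary_tract_obj()].
#' @param k number of clusters (<= number of tracts).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return List with `labels` and `clusters` (per-cluster list of `members`,
#'   `profile`, `pattern`).
#' @export
cluster_termini <- function(tracts, k, seed = 1L, nstart = 10L) {
  if (k > length(tracts)) stop("k exceeds the number of tracts")
  term <- t(vapply(tracts, `[[`, numeric(3), "terminus"))
  labels <- if (k == 1L) rep(1L, length(tracts)) else
    with_seed(seed, safe_kmeans(term, k, nstart))$cluster
  clusters <- lapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    prof <- if (length(members) >= 3L) radius_profile(tracts[members]) else NULL
    list(members = members, profile = prof,
         pattern = if (is.null(prof)) NA_character_ else classify_pattern(prof))
  })
  list(labels = labels, clusters = clusters)
}
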