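# Morphometric features in the L-Measure tradition, following the Vaa3D
# global_neuron_feature conventions: coordinate spans are full (untrimmed)
# ranges, surface/volume use conical frustum segments from per-node radii,
# and contraction is the per-branch Euclid/path ratio averaged over branches.

GLOBAL_FEATURE_NAMES <- c(
  "Nodes", "SomaSurface", "Stems", "Bifurcations", "Branches", "Tips",
  "OverallWidth", "OverallHeight", "OverallDepth", "AverageDiameter",
  "Length", "Surface", "Volume", "MaxEuclideanDistance", "MaxPathDistance",
  "MaxBranchOrder", "AverageContraction", "AverageFragmentation",
  "AverageParentDaughterRatio", "AverageBifurcationAngleLocal",
  "AverageBifurcationAngleRemote", "HausdorffDimension")

BRANCH_FEATURE_NAMES <- c(
  "br_length", "br_order", "br_contraction", "bif_EucDist2soma",
  "bif_PathDist2soma", "asymmetry", "ampl_local", "ampl_remote",
  "tilt_local", "tilt_remote")

vec_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

# box-counting fractal dimension over 8 dyadic box sizes starting at
# bounding-box diagonal / 4; least-squares slope of log N(s) vs log(1/s)
hausdorff_dimension <- function(pts) {
  rng <- apply(pts, 2L, range)
  diag_len <- sqrt(sum((rng[2L, ] - rng[1L, ])^2))
  if (diag_len <= 0) return(0)
  sizes <- diag_len / 4 / 2^(0:7)
  counts <- vapply(sizes, function(s) {
    idx <- floor(sweep(pts, 2L, rng[1L, ]) / s)
    nrow(unique(idx))
  }, numeric(1))
  x <- log(1 / sizes); y <- log(counts)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Global morphometric features (22 scalars)
#'
#' Computes the 22 whole-neuron features: node/branch/tip counts, coordinate
#' spans, cable length, frustum surface and volume, maximal Euclidean and path
#' distance to the soma, branch order, contraction, fragmentation,
#' parent-daughter radius ratio, local and remote bifurcation angles, and a
#' box-counting Hausdorff dimension.
#'
#' @param tree a valid [neuron_tree()].
#' @return Named numeric vector of length 22.
#' @export
global_features <- function(tree) {
  nodes <- tree$nodes
  out <- setNames(numeric(length(GLOBAL_FEATURE_NAMES)), GLOBAL_FEATURE_NAMES)
  out["Nodes"] <- nrow(nodes)
  if (nrow(nodes) < 2L) {
    warning("tree with < 2 nodes: features defined as zero")
    out["Nodes"] <- nrow(nodes)
    return(out)
  }
  sr <- soma_row(tree)
  out["SomaSurface"] <- 4 * pi * nodes$radius[sr]^2
  kids <- children_index(tree)
  nkids <- lengths(kids)
  out["Stems"] <- nkids[sr]
  bifs <- which(nkids >= 2L & seq_along(nkids) != sr)
  out["Bifurcations"] <- length(bifs)
  branches <- branch_decomposition(tree)
  out["Branches"] <- length(branches)
  out["Tips"] <- sum(nkids == 0L & seq_along(nkids) != sr)
  out["OverallWidth"] <- diff(range(nodes$x))
  out["OverallHeight"] <- diff(range(nodes$y))
  out["OverallDepth"] <- diff(range(nodes$z))
  out["AverageDiameter"] <- mean(2 * nodes$radius)

  prow <- node_row(tree, nodes$parent)
  e <- which(!is.na(prow))
  h <- sqrt((nodes$x[e] - nodes$x[prow[e]])^2 +
            (nodes$y[e] - nodes$y[prow[e]])^2 +
            (nodes$z[e] - nodes$z[prow[e]])^2)
  r1 <- nodes$radius[prow[e]]; r2 <- nodes$radius[e]
  out["Length"] <- sum(h)
  out["Surface"] <- sum(pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2))
  out["Volume"] <- sum(pi * h * (r1^2 + r1 * r2 + r2^2) / 3)

  pd <- path_distance_all(tree)
  xyz <- node_xyz(tree)
  ed <- sqrt(rowSums(sweep(xyz, 2L, xyz[sr, ])^2))
  out["MaxEuclideanDistance"] <- max(ed)
  out["MaxPathDistance"] <- max(pd, na.rm = TRUE)
  out["MaxBranchOrder"] <- max(vapply(branches, `[[`, integer(1), "order"), 0L)

  contraction <- fragmentation <- numeric(0)
  for (b in branches) {
    pts <- xyz[b$rows, , drop = FALSE]
    plen <- polyline_length(pts)
    elen <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
    if (plen > 0) contraction <- c(contraction, elen / plen)
    fragmentation <- c(fragmentation, length(b$rows) - 1L)
  }
  out["AverageContraction"] <- if (length(contraction)) mean(contraction) else 0
  out["AverageFragmentation"] <- if (length(fragmentation)) mean(fragmentation) else 0

  pd_ratio <- numeric(0)
  ang_local <- ang_remote <- numeric(0)
  remote_pt <- remote_points(tree, kids, nkids)
  for (b in bifs) {
    ks <- kids[[b]]
    if (nodes$radius[b] > 0)
      pd_ratio <- c(pd_ratio, nodes$radius[ks] / nodes$radius[b])
    if (length(ks) >= 2L) {
      v1 <- xyz[ks[1L], ] - xyz[b, ]; v2 <- xyz[ks[2L], ] - xyz[b, ]
      ang_local <- c(ang_local, vec_angle(v1, v2))
      w1 <- remote_pt[ks[1L], ] - xyz[b, ]; w2 <- remote_pt[ks[2L], ] - xyz[b, ]
      ang_remote <- c(ang_remote, vec_angle(w1, w2))
    }
  }
  out["AverageParentDaughterRatio"] <- if (length(pd_ratio)) mean(pd_ratio) else 0
  out["AverageBifurcationAngleLocal"] <- if (length(ang_local)) mean(ang_local) else 0
  out["AverageBifurcationAngleRemote"] <- if (length(ang_remote)) mean(ang_remote) else 0
  out["HausdorffDimension"] <- hausdorff_dimension(xyz)
  out
}

# for every node, the coordinates of the next topological point reached by
# walking distally (the node itself if it is a bifurcation or tip)
remote_points <- function(tree, kids = children_index(tree), nkids = lengths(kids)) {
  xyz <- node_xyz(tree)
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    cur <- i
    while (nkids[cur] == 1L) cur <- kids[[cur]][1L]
    out[i, ] <- xyz[cur, ]
  }
  out
}

# number of tips in the subtree rooted at each node
subtree_tips <- function(tree, kids = children_index(tree)) {
  n <- nrow(tree$nodes)
  nkids <- lengths(kids)
  tips <- integer(n)
  ord <- order(path_depth(tree), decreasing = TRUE) # deepest first
  for (i in ord) {
    tips[i] <- if (nkids[i] == 0L) 1L else sum(tips[kids[[i]]])
  }
  tips
}

path_depth <- function(tree) {
  prow <- node_row(tree, tree$nodes$parent)
  n <- nrow(tree$nodes)
  depth <- rep(NA_integer_, n)
  depth[root_row(tree)] <- 0L
  repeat {
    todo <- which(is.na(depth) & !is.na(prow) &
                    !is.na(depth[ifelse(is.na(prow), 1L, prow)]))
    if (!length(todo)) break
    depth[todo] <- depth[prow[todo]] + 1L
  }
  depth
}

#' Per-branch morphometric features
#'
#' For each branch: path length, order, contraction, Euclidean and path
#' distance from the branch's proximal topological point to the soma,
#' partition asymmetry and the four bifurcation angles (amplitude and tilt,
#' local and remote) at the branch's distal bifurcation. Branches ending in a
#' tip carry defined zeros for the bifurcation-specific entries.
#'
#' Tilt is the angle between the direction back toward the soma (the reversed
#' incoming parent direction) and each child direction, averaged over the two
#' children; amplitude is the angle between the two child directions. Local
#' variants use immediate child compartments, remote variants the vectors to
#' the next topological points.
#'
#' @param tree a valid [neuron_tree()].
#' @return data.frame with one row per branch and the 10 feature columns.
#' @export
branch_features <- function(tree) {
  branches <- branch_decomposition(tree)
  nodes <- tree$nodes
  xyz <- node_xyz(tree)
  kids <- children_index(tree)
  nkids <- lengths(kids)
  sr <- soma_row(tree)
  pd <- path_distance_all(tree)
  remote_pt <- remote_points(tree, kids, nkids)
  tips <- subtree_tips(tree, kids)

  rows <- lapply(branches, function(b) {
    pts <- xyz[b$rows, , drop = FALSE]
    plen <- polyline_length(pts)
    elen <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
    start <- b$rows[1L]; end <- b$rows[length(b$rows)]
    res <- c(br_length = plen, br_order = b$order,
             br_contraction = if (plen > 0) elen / plen else 0,
             bif_EucDist2soma = sqrt(sum((xyz[start, ] - xyz[sr, ])^2)),
             bif_PathDist2soma = pd[start],
             asymmetry = 0, ampl_local = 0, ampl_remote = 0,
             tilt_local = 0, tilt_remote = 0)
    ks <- kids[[end]]
    if (length(ks) >= 2L) {
      n1 <- tips[ks[1L]]; n2 <- tips[ks[2L]]
      res["asymmetry"] <- if (n1 + n2 > 2L) abs(n1 - n2) / (n1 + n2 - 2L) else 0
      v1 <- xyz[ks[1L], ] - xyz[end, ]; v2 <- xyz[ks[2L], ] - xyz[end, ]
      w1 <- remote_pt[ks[1L], ] - xyz[end, ]; w2 <- remote_pt[ks[2L], ] - xyz[end, ]
      res["ampl_local"] <- vec_angle(v1, v2)
      res["ampl_remote"] <- vec_angle(w1, w2)
      # direction back toward the soma: reversed chord of the incoming branch
      back_local <- xyz[b$rows[max(1L, length(b$rows) - 1L)], ] - xyz[end, ]
      back_remote <- xyz[start, ] - xyz[end, ]
      res["tilt_local"] <- mean(c(vec_angle(back_local, v1), vec_angle(back_local, v2)))
      res["tilt_remote"] <- mean(c(vec_angle(back_remote, w1), vec_angle(back_remote, w2)))
    }
    res
  })
  df <- as.data.frame(do.call(rbind, rows))
  df
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Full-morphology feature vector (47 dimensions)
#'
#' Seven global features (Stems, Branches, OverallWidth, OverallHeight,
#' OverallDepth, OverallVolume, Length) followed by the minimum, maximum, mean
#' and (population) standard deviation of each of the 10 per-branch features.
#'
#' @param tree a valid [neuron_tree()].
#' @return Named numeric vector of length 47.
#' @export
full_morphology_vector <- function(tree) {
  g <- global_features(tree)
  globals <- c(Stems = unname(g["Stems"]), Branches = unname(g["Branches"]),
               OverallWidth = unname(g["OverallWidth"]),
               OverallHeight = unname(g["OverallHeight"]),
               OverallDepth = unname(g["OverallDepth"]),
               OverallVolume = unname(g["Volume"]),
               Length = unname(g["Length"]))
  bf <- branch_features(tree)
  stats <- unlist(lapply(BRANCH_FEATURE_NAMES, function(nm) {
    x <- bf[[nm]]
    setNames(c(min(x), max(x), mean(x), pop_sd(x)),
             paste0(nm, c("_min", "_max", "_mean", "_std")))
  }))
  c(globals, stats)
}

#' PCA shape features (6 dimensions)
#'
#' Principal component analysis of the node coordinates in isotropic
#' micrometre space: the explained-variance percentages of the three
#' components (summing to 1) and the first principal axis normalized to unit
#' sum of absolute components, with the sign fixed so the largest-magnitude
#' component is positive.
#'
#' @param tree a [neuron_tree()] with at least 3 nodes.
#' @return Named numeric vector `pc_var_1..3`, `pc_axis_1..3`.
#' @export
pca_shape_features <- function(tree) {
  xyz <- node_xyz(tree)
  if (nrow(xyz) < 3L) stop("need >= 3 nodes for PCA shape features")
  p <- prcomp(xyz, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  pct <- v / sum(v)
  ax <- p$rotation[, 1L]
  imax <- which.max(abs(ax))
  if (ax[imax] < 0) ax <- -ax
  ax <- ax / sum(abs(ax))
  c(pc_var_1 = pct[1L], pc_var_2 = pct[2L], pc_var_3 = pct[3L],
    pc_axis_1 = unname(ax[1L]), pc_axis_2 = unname(ax[2L]),
    pc_axis_3 = unname(ax[3L]))
}

# the 18 global features retained for microenvironment analysis
MICROENV_GLOBAL_NAMES <- setdiff(GLOBAL_FEATURE_NAMES,
  c("Nodes", "SomaSurface", "AverageDiameter", "Surface"))

#' Microenvironment base vector (24 dimensions)
#'
#' 18 global features (the 22 minus Nodes, SomaSurface, AverageDiameter and
#' Surface) concatenated with the 6 PCA shape features.
#'
#' @param tree a valid [neuron_tree()].
#' @return Named numeric vector of length 24.
#' @export
microenv_base_vector <- function(tree) {
  g <- global_features(tree)
  c(g[MICROENV_GLOBAL_NAMES], pca_shape_features(tree))
}

#' Z-score a feature table
#'
#' Columns are centred and scaled to unit population standard deviation
#' (divisor n). Zero-variance columns map to all-zero with a warning.
#'
#' @param x numeric matrix or data.frame with >= 2 rows.
#' @return Matrix of the same shape.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to standardize")
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  zero <- s == 0
  if (any(zero)) {
    warning("zero-variance column(s) mapped to 0: ",
            paste(colnames(x)[zero], collapse = ", "))
    s[zero] <- 1
  }
  z <- sweep(sweep(x, 2L, mu), 2L, s, "/")
  z[, zero] <- 0
  z
}
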