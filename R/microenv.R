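# Dendritic microenvironments: a target neuron fused with its most similar
# spatial neighbors. Neighbor candidacy is spatial (soma distance <= D),
# ranking is morphological (Euclidean distance between z-scored 24-dim
# vectors), and fusion weights decay exponentially with soma distance.

soma_matrix <- function(population) {
  as.matrix(population$somata[, c("x", "y", "z")])
}

#' Calibrate the microenvironment radius from a population
#'
#' `D` is the median over all neurons of the Euclidean soma distance to the
#' 5th nearest neighbor. The whole-brain dendrite population this statistic
#' was designed for yields D = 249 um, which is the package default wherever
#' a radius is needed but no population is available.
#'
#' @param population list with a `somata` data.frame (columns x, y, z).
#' @param nn which neighbor rank to use (default 5).
#' @return Radius in micrometres.
#' @export
calibrate_radius <- function(population, nn = 5L) {
  pos <- soma_matrix(population)
  n <- nrow(pos)
  if (n < nn + 1L) stop("need at least ", nn + 1L, " neurons to calibrate")
  d <- as.matrix(stats::dist(pos))
  knn <- apply(d, 1L, function(r) sort(r)[nn + 1L]) # +1 skips self (0)
  median(knn)
}

#' Default microenvironment radius (um)
#' @export
DEFAULT_MICROENV_RADIUS <- 249

#' Find microenvironment neighbors of a target neuron
#'
#' Candidates are all somas within `D` of the target (excluded itself),
#' ranked by Euclidean distance between z-scored feature vectors (z-scores
#' over the whole population); the top `k` are returned. Ties break toward
#' the lower neuron id.
#'
#' @param target id of the target neuron (must be in `population$somata$id`).
#' @param population list with `somata` and `features` (rownames = ids).
#' @param D search radius (um).
#' @param k maximum number of neighbors.
#' @return data.frame with columns `id`, `soma_dist`, `feature_dist`,
#'   possibly empty.
#' @export
find_neighbors <- function(target, population, D = DEFAULT_MICROENV_RADIUS, k = 5L) {
  ids <- population$somata$id
  ti <- match(target, ids)
  if (is.na(ti)) stop("unknown target id: ", target)
  pos <- soma_matrix(population)
  z <- suppressWarnings(standardize(population$features))
  sd_all <- sqrt(rowSums(sweep(pos, 2L, pos[ti, ])^2))
  cand <- which(sd_all <= D & seq_along(ids) != ti)
  if (!length(cand))
    return(data.frame(id = integer(), soma_dist = numeric(), feature_dist = numeric()))
  fd <- sqrt(rowSums(sweep(z[cand, , drop = FALSE], 2L, z[ti, ])^2))
  ord <- order(fd, ids[cand])
  sel <- cand[ord][seq_len(min(k, length(cand)))]
  data.frame(id = ids[sel], soma_dist = sd_all[sel],
             feature_dist = fd[ord][seq_len(min(k, length(cand)))])
}

#' Fuse a target neuron with its neighbors into a microenvironment
#'
#' Weights are `w_i = exp(-d_i / D) / sum_j exp(-d_j / D)` over the target
#' (`d = 0`) and its neighbors; the fused feature vector is the weighted
#' average `F_M = sum_i w_i F_i`. Weights always sum to 1 and the fused
#' vector lies in the per-coordinate convex hull of the member vectors.
#'
#' @param target target neuron id.
#' @param neighbors data.frame as returned by [find_neighbors()].
#' @param population list with `somata` and `features`.
#' @param D microenvironment radius (um), > 0.
#' @return A `microenvironment`: list with `target`, `neighbors`, `d`, `D`,
#'   `weights`, `features` (fused vector) and `soma` (target position).
#' @export
fuse <- function(target, neighbors, population, D = DEFAULT_MICROENV_RADIUS) {
  stopifnot(D > 0)
  if (nrow(neighbors) && any(neighbors$soma_dist > D))
    stop("neighbor distance exceeds the microenvironment radius D")
  ids <- c(target, neighbors$id)
  d <- c(0, neighbors$soma_dist)
  rows <- match(as.character(ids), rownames(population$features))
  if (anyNA(rows)) stop("neuron id(s) missing from feature table")
  feats <- population$features[rows, , drop = FALSE]
  w <- exp(-d / D)
  w <- w / sum(w)
  fused <- colSums(feats * w)
  ti <- match(target, population$somata$id)
  structure(list(target = target, neighbors = neighbors$id, d = d, D = D,
                 weights = w, features = fused,
                 soma = unlist(population$somata[ti, c("x", "y", "z")])),
            class = "microenvironment")
}

#' Build all microenvironments of a population
#'
#' @param population list with `somata` and `features`.
#' @param D radius (um); `NULL` calibrates it with [calibrate_radius()].
#' @param k neighbor cap.
#' @return data.frame with one row per neuron: id, region, soma coordinates,
#'   `n_members`, and the fused feature columns.
#' @export
build_microenvironments <- function(population, D = NULL, k = 5L) {
  if (is.null(D)) D <- calibrate_radius(population)
  ids <- population$somata$id
  rows <- lapply(ids, function(i) {
    m <- fuse(i, find_neighbors(i, population, D, k), population, D)
    c(n_members = length(m$d), m$features)
  })
  fused <- do.call(rbind, rows)
  out <- cbind(population$somata, as.data.frame(fused))
  attr(out, "D") <- D
  out
}

# --- mRMR ------------------------------------------------------------------

# 3-bin discretization at mean +/- SD; columns that are already discrete
# (at most 3 distinct values) are used as-is
discretize3 <- function(x) {
  u <- unique(x)
  if (length(u) <= 3L) return(match(x, sort(u)))
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(2L, length(x)))
  cut(x, c(-Inf, m - s, m + s, Inf), labels = FALSE)
}

mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Greedy mRMR feature selection (MID scheme)
#'
#' Features are discretized into 3 bins at mean +/- SD. The first selected
#' feature maximizes mutual information with the labels; each subsequent
#' feature maximizes `MI(f; y) - mean MI(f; selected)`. Ties break toward the
#' earlier column.
#'
#' @param X numeric feature matrix or data.frame.
#' @param y class labels (>= 2 classes).
#' @param k number of features to select.
#' @return Character vector of selected feature names, in selection order.
#' @export
mrmr_select <- function(X, y, k = 3L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("need >= 2 classes")
  if (k > ncol(X)) stop("k exceeds the number of features")
  disc <- apply(X, 2L, discretize3)
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) mutual_information(disc[, j], y), numeric(1))
  selected <- integer(0)
  for (step in seq_len(k)) {
    if (length(selected) == 0L) {
      score <- rel
    } else {
      red <- vapply(seq_len(p), function(j)
        mean(vapply(selected, function(s)
          mutual_information(disc[, j], disc[, s]), numeric(1))), numeric(1))
      score <- rel - red
    }
    score[selected] <- -Inf
    selected <- c(selected, which.max(score))
  }
  colnames(X)[selected]
}

# --- RGB feature map -------------------------------------------------------

#' Render a 3-D RGB feature map of microenvironments
#'
#' Three selected features are mapped to the R, G, B channels of an atlas-grid
#' volume. Points in the right hemisphere (beyond the mid-sagittal z midline)
#' are mirrored to the left. Each channel is independently min-max scaled to
#' 0..255 (a single occupied value maps to 255).
#'
#' @param microenvs data.frame from [build_microenvironments()].
#' @param channels character vector of 3 feature column names.
#' @param spacing grid spacing (um), default 25.
#' @param dims optional grid dimensions; derived from the data if `NULL`.
#' @param mirror mirror right-hemisphere points across the z midline.
#' @return List of class `feature_map3d`: `array` (nx, ny, nz, 3), `channels`,
#'   `spacing`, `dims`.
#' @export
render_map <- function(microenvs, channels, spacing = 25, dims = NULL,
                       mirror = TRUE) {
  if (length(channels) != 3L) stop("exactly 3 channel features required")
  missing_f <- setdiff(channels, names(microenvs))
  if (length(missing_f)) stop("feature(s) absent: ", paste(missing_f, collapse = ", "))
  pos <- as.matrix(microenvs[, c("x", "y", "z")])
  if (is.null(dims)) dims <- pmax(1L, ceiling(apply(pos, 2L, max) / spacing))
  if (mirror) {
    zmid <- dims[3L] * spacing / 2
    right <- pos[, 3L] > zmid
    pos[right, 3L] <- 2 * zmid - pos[right, 3L]
  }
  idx <- pmin(matrix(rep(dims, each = nrow(pos)), ncol = 3L),
              pmax(1L, floor(pos / spacing) + 1L))
  lin <- (idx[, 3L] - 1L) * dims[1L] * dims[2L] + (idx[, 2L] - 1L) * dims[1L] + idx[, 1L]
  arr <- array(0, c(dims, 3L))
  for (ch in 1:3) {
    v <- microenvs[[channels[ch]]]
    agg <- tapply(v, lin, mean)
    vals <- as.numeric(agg)
    rng <- range(vals)
    scaled <- if (rng[2L] > rng[1L]) (vals - rng[1L]) / (rng[2L] - rng[1L]) * 255
              else rep(255, length(vals)) # degenerate scaling pinned to 255
    plane <- array(0, dims)
    plane[as.integer(names(agg))] <- scaled
    arr[, , , ch] <- plane
  }
  structure(list(array = arr, channels = channels, spacing = spacing,
                 dims = dims), class = "feature_map3d")
}

#' Maximum-intensity projection of a feature map section
#'
#' Projects a +/- `slab` um slab around the requested section centre along
#' one axis.
#'
#' @param map a `feature_map3d` from [render_map()].
#' @param axis 1, 2 or 3 (projection axis).
#' @param center section centre in um along the axis; defaults to the middle.
#' @param slab slab half-thickness (um), default 1000.
#' @return 3-channel 2-D array.
#' @export
mip_section <- function(map, axis = 3L, center = NULL, slab = 1000) {
  dims <- map$dims
  if (is.null(center)) center <- dims[axis] * map$spacing / 2
  lo <- max(1L, floor((center - slab) / map$spacing) + 1L)
  hi <- min(dims[axis], ceiling((center + slab) / map$spacing))
  sub <- switch(axis,
    map$array[lo:hi, , , , drop = FALSE],
    map$array[, lo:hi, , , drop = FALSE],
    map$array[, , lo:hi, , drop = FALSE])
  apply(sub, setdiff(1:3, axis) |> c(4L), max)
}

# --- path profiles ---------------------------------------------------------

#' Feature profiles along a path of regions or a polyline
#'
#' For a character path, returns the per-region mean and median of each
#' selected feature, in path order (regions with no microenvironments yield
#' `NA`). For a polyline path (matrix), microenvironments within `tube_radius`
#' of the path are binned by arc length. Pairwise Pearson correlations
#' between the feature mean-profiles are attached; correlations involving a
#' constant profile are flagged as `NA`.
#'
#' @param microenvs data.frame from [build_microenvironments()].
#' @param path character vector of region labels, or an (n x 3) polyline.
#' @param features feature column names to profile.
#' @param tube_radius polyline mode: inclusion radius (um).
#' @param n_bins polyline mode: number of arc-length bins.
#' @return List with `profile` (data.frame) and `correlations` (matrix).
#' @export
path_profile <- function(microenvs, path, features, tube_radius = 200,
                         n_bins = 20L) {
  if (is.character(path)) {
    if (!length(path)) stop("empty path")
    prof <- do.call(rbind, lapply(path, function(rg) {
      sub <- microenvs[microenvs$region == rg, features, drop = FALSE]
      if (!nrow(sub))
        return(data.frame(step = rg, t(setNames(rep(NA_real_, length(features)),
                                                features)), check.names = FALSE))
      data.frame(step = rg, t(colMeans(sub)), check.names = FALSE)
    }))
    med <- do.call(rbind, lapply(path, function(rg) {
      sub <- microenvs[microenvs$region == rg, features, drop = FALSE]
      if (!nrow(sub)) rep(NA_real_, length(features)) else apply(sub, 2L, median)
    }))
    colnames(med) <- paste0(features, "_median")
    prof <- cbind(prof, med)
  } else {
    path <- as.matrix(path)
    if (!nrow(path)) stop("empty path")
    dense <- resample_polyline(path, max(200L, n_bins * 10L))
    seg <- sqrt(rowSums((dense[-1L, ] - dense[-nrow(dense), ])^2))
    arc <- c(0, cumsum(seg))
    pos <- as.matrix(microenvs[, c("x", "y", "z")])
    nearest <- vapply(seq_len(nrow(pos)), function(i) {
      d2 <- rowSums(sweep(dense, 2L, pos[i, ])^2)
      j <- which.min(d2)
      c(sqrt(d2[j]), arc[j])
    }, numeric(2))
    keep <- nearest[1L, ] <= tube_radius
    bins <- cut(nearest[2L, keep], seq(0, max(arc), length.out = n_bins + 1L),
                include.lowest = TRUE, labels = FALSE)
    prof <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
      sub <- microenvs[keep, features, drop = FALSE][bins == b, , drop = FALSE]
      data.frame(step = (b - 0.5) * max(arc) / n_bins,
                 t(if (nrow(sub)) colMeans(sub) else
                   setNames(rep(NA_real_, length(features)), features)),
                 check.names = FALSE)
    }))
  }
  pm <- as.matrix(prof[, features, drop = FALSE])
  cc <- matrix(NA_real_, length(features), length(features),
               dimnames = list(features, features))
  for (i in seq_along(features)) for (j in seq_along(features)) {
    xi <- pm[, i]; xj <- pm[, j]
    ok <- stats::complete.cases(xi, xj)
    if (sum(ok) >= 3 && sd(xi[ok]) > 0 && sd(xj[ok]) > 0)
      cc[i, j] <- cor(xi[ok], xj[ok])
  }
  list(profile = prof, correlations = cc)
}

#' Cluster brain regions by microenvironment feature statistics
#'
#' Each region is summarized as the concatenation of the mean and (population)
#' variance of its microenvironment features; regions are clustered with
#' k-means under a fixed seed.
#'
#' @param microenvs data.frame from [build_microenvironments()].
#' @param features feature column names to use.
#' @param k number of clusters.
#' @param seed integer seed for k-means.
#' @param nstart k-means restarts (pinned default 10).
#' @return List with `clusters` (named integer vector per region) and
#'   `inertia` (total within-cluster sum of squares).
#' @export
cluster_regions <- function(microenvs, features, k = 6L, seed = 1L, nstart = 10L) {
  regions <- split(microenvs[, features, drop = FALSE], microenvs$region)
  small <- names(regions)[vapply(regions, nrow, integer(1)) < 2L]
  if (length(small)) {
    warning("region(s) with < 2 microenvironments excluded: ",
            paste(small, collapse = ", "))
    regions <- regions[!(names(regions) %in% small)]
  }
  vecs <- t(vapply(regions, function(df) {
    m <- as.matrix(df)
    c(colMeans(m), apply(m, 2L, function(x) mean((x - mean(x))^2)))
  }, numeric(2L * length(features))))
  if (k > nrow(vecs)) stop("k exceeds the number of usable regions")
  km <- with_seed(seed, safe_kmeans(vecs, k, nstart))
  list(clusters = setNames(km$cluster, rownames(vecs)), inertia = km$tot.withinss)
}
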