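# Axonal varicosity detection from intensity and radius profiles along the
# skeleton: candidates are coinciding peaks of the two profiles, filtered by
# a 1.5x radius gain over the surrounding axon and an 8-bit intensity floor
# of 120, then de-duplicated within a five-voxel radius.

trilinear <- function(img, p_um, voxel) {
  dims <- dim(img)
  # voxel centers sit at (i - 0.5) * voxel
  q <- p_um / voxel + 0.5
  q <- pmin(pmax(q, 1), dims)
  i0 <- pmin(floor(q), dims - 1L)
  f <- q - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    v <- v + w * img[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  v
}

#' Intensity and radius profiles along an axonal skeleton
#'
#' The axon is partitioned into consecutive `step`-um arc-length fragments.
#' At sub-voxel-spaced skeleton samples, intensity is the trilinear image
#' value and radius the half-width at half-maximum of the intensity
#' cross-section perpendicular to the local tangent (mean of 8 rays, capped
#' at `max_radius`).
#'
#' @param tree a [neuron_tree()] whose axon lies inside the image.
#' @param image 3-D intensity array.
#' @param voxel voxel size (um, isotropic).
#' @param step fragment length (um), default 20.
#' @param max_radius radius cap (um), default 10.
#' @return data.frame of class `fragment_profiles`: branch, fragment, arc
#'   (global um), branch_arc, x, y, z, intensity, radius; attribute `voxel`.
#' @export
fragment_profiles <- function(tree, image, voxel = 1, step = 20, max_radius = 10) {
  dims <- dim(image)
  ax_rows <- which(tree$nodes$type == SWC_AXON)
  pos_nodes <- node_xyz(tree, ax_rows)
  lim <- dims * voxel
  out_of <- which(apply(pos_nodes, 1L, function(p) any(p < 0) || any(p > lim)))
  if (length(out_of))
    stop("skeleton outside image: node id(s) ",
         paste(tree$nodes$id[ax_rows[out_of]], collapse = ", "))
  branches <- branch_decomposition(tree, types = SWC_AXON)
  spacing <- voxel
  global0 <- 0
  rows <- list()
  for (bi in seq_along(branches)) {
    pts <- node_xyz(tree, branches[[bi]]$rows)
    len <- polyline_length(pts)
    if (len <= 0) next
    k <- max(3L, ceiling(len / spacing) + 1L)
    sp <- resample_polyline(pts, k)
    arc <- seq(0, len, length.out = k)
    tang <- rbind(sp[2L, ] - sp[1L, ],
                  sp[3:k, ] - sp[1:(k - 2L), ],
                  sp[k, ] - sp[k - 1L, ])
    inten <- vapply(seq_len(k), function(i) trilinear(image, sp[i, ], voxel),
                    numeric(1))
    radius <- vapply(seq_len(k), function(i) {
      hwhm_radius(image, sp[i, ], tang[i, ], voxel, inten[i], max_radius)
    }, numeric(1))
    rows[[bi]] <- data.frame(branch = bi,
                             fragment = pmin(floor((global0 + arc) / step),
                                             ceiling((global0 + len) / step) - 1L) + 1L,
                             arc = global0 + arc, branch_arc = arc,
                             x = sp[, 1], y = sp[, 2], z = sp[, 3],
                             intensity = inten, radius = radius)
    global0 <- global0 + len
  }
  out <- do.call(rbind, rows)
  attr(out, "voxel") <- voxel
  attr(out, "step") <- step
  class(out) <- c("fragment_profiles", class(out))
  out
}

hwhm_radius <- function(img, p, tangent, voxel, center_val, max_radius) {
  if (center_val <= 0) return(0)
  uv <- perp_basis(unit(tangent))
  half <- center_val / 2
  rs <- seq(0, max_radius, by = voxel / 4)
  dirs <- lapply(seq(0, 7) * pi / 4, function(a)
    cos(a) * uv[, 1L] + sin(a) * uv[, 2L])
  mean(vapply(dirs, function(d) {
    prev <- center_val
    for (j in seq_along(rs)[-1L]) {
      v <- trilinear(img, p + rs[j] * d, voxel)
      if (v < half) {
        # linear interpolation between the last two ray samples
        return(rs[j - 1L] + (prev - half) / max(prev - v, 1e-12) * (rs[j] - rs[j - 1L]))
      }
      prev <- v
    }
    max_radius
  }, numeric(1)))
}

# smoothed running mean, window w (odd)
running_mean <- function(v, w = 5L) {
  if (length(v) < w) return(v)
  k <- (w - 1L) %/% 2L
  padded <- c(rep(v[1L], k), v, rep(v[length(v)], k))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[(k + 1L):(k + length(v))]
}

# indices of local maxima with prominence at least min_prom; plateaus
# report their centre sample
find_peaks <- function(v, min_prom) {
  n <- length(v)
  if (n < 3L) return(integer())
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) { # rise .. plateau .. fall
        peak <- (i + j) %/% 2L
        l <- i; while (l > 1L && v[l - 1L] <= v[peak]) l <- l - 1L
        r <- j; while (r < n && v[r + 1L] <= v[peak]) r <- r + 1L
        base <- max(min(v[l:peak]), min(v[peak:r]))
        if ((v[peak] - base) >= min_prom) out <- c(out, peak)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Detect putative axonal varicosities
#'
#' Candidates are intensity-profile local maxima coinciding (within
#' `coincide_tol` samples) with a radius-profile local maximum. A candidate
#' is kept when its peak radius is at least `gain` times the baseline radius
#' (median radius of the host fragment excluding +/- 2 um around the peak)
#' and its peak intensity exceeds `min_intensity`. Survivors are greedily
#' de-duplicated in descending intensity order within `dedup` voxels.
#'
#' @param profiles a `fragment_profiles` table from [fragment_profiles()].
#' @param gain radius gain threshold, default 1.5.
#' @param min_intensity 8-bit intensity floor, default 120.
#' @param dedup suppression radius in voxels, default 5.
#' @param coincide_tol peak coincidence tolerance in samples, default 2.
#' @param prominence peak prominence as a fraction of the branch profile
#'   range, default 0.05.
#' @param smooth_window running-mean window (samples) applied to both
#'   profiles before peak finding.
#' @return data.frame: x, y, z, arc, branch, branch_arc, intensity, radius.
#' @export
detect_varicosities <- function(profiles, gain = 1.5, min_intensity = 120,
                                dedup = 5, coincide_tol = 2L,
                                prominence = 0.05, smooth_window = 5L) {
  voxel <- attr(profiles, "voxel") %||% 1
  cand <- list()
  for (bi in unique(profiles$branch)) {
    pb <- profiles[profiles$branch == bi, ]
    iv <- running_mean(pb$intensity, smooth_window)
    rv <- running_mean(pb$radius, smooth_window)
    ip <- find_peaks(iv, prominence * max(diff(range(iv)), 1e-12))
    rp <- find_peaks(rv, prominence * max(diff(range(rv)), 1e-12))
    if (!length(ip) || !length(rp)) next
    for (i in ip) {
      if (!any(abs(rp - i) <= coincide_tol)) next
      frag <- pb$fragment[i]
      sel <- pb$fragment == frag & abs(pb$arc - pb$arc[i]) > 2
      baseline <- if (any(sel)) median(rv[sel]) else median(rv)
      if (baseline <= 0) baseline <- 1e-12
      if (rv[i] >= gain * baseline && iv[i] > min_intensity) {
        cand[[length(cand) + 1L]] <-
          data.frame(x = pb$x[i], y = pb$y[i], z = pb$z[i], arc = pb$arc[i],
                     branch = bi, branch_arc = pb$branch_arc[i],
                     intensity = iv[i], radius = rv[i])
      }
    }
  }
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      arc = numeric(), branch = integer(),
                      branch_arc = numeric(), intensity = numeric(),
                      radius = numeric())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$intensity, cand$arc), ]
  keep <- logical(nrow(cand))
  acc <- matrix(numeric(0), ncol = 3L)
  lim <- dedup * voxel
  for (i in seq_len(nrow(cand))) {
    p <- as.numeric(cand[i, c("x", "y", "z")])
    if (!nrow(acc) || all(sqrt(rowSums(sweep(acc, 2L, p)^2)) > lim)) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

# arc-length (graph) distance from arbitrary positions to the nearest
# axonal tip of the tree
dist_to_nearest_tip <- function(tree, positions) {
  kids <- children_index(tree)
  ax <- which(tree$nodes$type == SWC_AXON)
  ax_kids <- lapply(kids, function(k) k[tree$nodes$type[k] == SWC_AXON])
  tips <- ax[lengths(ax_kids)[ax] == 0L]
  g <- tree_graph(tree, weighted = TRUE)
  pos_nodes <- node_xyz(tree)
  nearest <- vapply(seq_len(nrow(positions)), function(i) {
    d2 <- rowSums(sweep(pos_nodes[ax, , drop = FALSE], 2L, positions[i, ])^2)
    ax[which.min(d2)]
  }, integer(1))
  offs <- sqrt(rowSums((pos_nodes[nearest, , drop = FALSE] - positions)^2))
  dm <- igraph::distances(g, v = unique(nearest), to = tips)
  apply(cbind(seq_along(nearest)), 1L, function(i) {
    min(dm[match(nearest[i], unique(nearest)), ]) + offs[i]
  })
}

#' Classify varicosities as terminaux (TEB) or en passant (EPB)
#'
#' A varicosity is TEB when its arc-length distance to the nearest axonal
#' tip is at most `eps` um, else EPB.
#'
#' @param varicosities data.frame with x, y, z columns.
#' @param tree the parent [neuron_tree()].
#' @param eps tip tolerance (um), default 2.
#' @return Character vector of `"TEB"` / `"EPB"`.
#' @export
classify_varicosity_type <- function(varicosities, tree, eps = 2) {
  if (!nrow(varicosities)) return(character())
  d <- dist_to_nearest_tip(tree, as.matrix(varicosities[, c("x", "y", "z")]))
  ifelse(d <= eps, "TEB", "EPB")
}

#' Per-branch varicosity statistics
#'
#' @param tree a valid [neuron_tree()].
#' @param varicosities data.frame with `branch` and `branch_arc` columns
#'   (as returned by [detect_varicosities()]), indices into the axonal
#'   branch decomposition.
#' @return List with `branches` (per-branch table: n, has_varicosity,
#'   curviness, is_terminal, length, quartile counts q1..q4) and `summary`
#'   (varicosity/null branch ratio, terminal vs bifurcating varicosity
#'   rates, B0/B1/B2 proportions, aggregate quartile ratios).
#' @export
branch_varicosity_stats <- function(tree, varicosities) {
  branches <- branch_decomposition(tree, types = SWC_AXON)
  nb <- length(branches)
  tab <- data.frame(branch = seq_len(nb), n = 0L, has_varicosity = FALSE,
                    length = NA_real_, curviness = NA_real_,
                    is_terminal = vapply(branches, `[[`, logical(1), "is_terminal"),
                    q1 = 0L, q2 = 0L, q3 = 0L, q4 = 0L)
  for (bi in seq_len(nb)) {
    pts <- node_xyz(tree, branches[[bi]]$rows)
    plen <- polyline_length(pts)
    elen <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
    tab$length[bi] <- plen
    tab$curviness[bi] <- if (elen > 0) plen / elen else Inf
    vs <- varicosities[varicosities$branch == bi, , drop = FALSE]
    tab$n[bi] <- nrow(vs)
    tab$has_varicosity[bi] <- nrow(vs) > 0L
    if (nrow(vs) && plen > 0) {
      frac <- pmin(pmax(vs$branch_arc / plen, 0), 1)
      q <- pmin(pmax(ceiling(frac * 4), 1L), 4L)
      for (qq in 1:4) tab[[paste0("q", qq)]][bi] <- sum(q == qq)
    }
  }
  # bifurcation classes over bifurcations whose both children are axonal
  child_of <- vapply(branches, function(b) {
    pb <- b$parent_branch
    if (is.null(pb) || is.na(pb)) NA_integer_ else pb
  }, integer(1))
  b_class <- integer(0)
  for (bi in seq_len(nb)) {
    ch <- which(child_of == bi)
    if (length(ch) == 2L)
      b_class <- c(b_class, sum(tab$has_varicosity[ch]))
  }
  nvb <- sum(tab$has_varicosity); nnb <- nb - nvb
  qtot <- colSums(tab[, c("q1", "q2", "q3", "q4")])
  summary <- list(
    varicosity_branches = nvb, null_branches = nnb,
    ratio = if (nnb > 0) nvb / nnb else Inf,
    terminal_rate = mean(tab$has_varicosity[tab$is_terminal]),
    bifurcating_rate = mean(tab$has_varicosity[!tab$is_terminal]),
    b_proportions = c(B0 = mean(b_class == 2L), B1 = mean(b_class == 1L),
                      B2 = mean(b_class == 0L)),
    quartile_ratios = if (sum(qtot) > 0) qtot / sum(qtot) else qtot)
  list(branches = tab, summary = summary)
}

#' Radial distribution of varicosities
#'
#' Path distances from the soma, normalized by the maximal varicosity
#' distance, histogrammed into `n_bins` fractions summing to 1.
#'
#' @param tree a valid [neuron_tree()].
#' @param varicosities data.frame with x, y, z columns.
#' @param n_bins histogram resolution.
#' @return List with `histogram` (fractions), `breaks`, `quartiles`
#'   (25/50/75% normalized positions) and `distances` (raw um).
#' @export
radial_distribution <- function(tree, varicosities, n_bins = 20L) {
  if (!nrow(varicosities)) stop("need >= 1 varicosity")
  pos <- as.matrix(varicosities[, c("x", "y", "z")])
  pd <- path_distance_all(tree)
  pn <- node_xyz(tree)
  d <- vapply(seq_len(nrow(pos)), function(i) {
    j <- which.min(rowSums(sweep(pn, 2L, pos[i, ])^2))
    pd[j]
  }, numeric(1))
  frac <- d / max(d)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- hist_fractions <- tabulate(pmin(pmax(ceiling(frac * n_bins), 1L), n_bins),
                                  nbins = n_bins)
  h <- h / sum(h)
  list(histogram = h, breaks = breaks,
       quartiles = quantile(frac, c(0.25, 0.5, 0.75), type = 7),
       distances = d)
}

#' Six-feature varicosity radar vectors for a set of neurons
#'
#' Raw features per neuron: F1 total count, F2 TEB ratio, F3 mean normalized
#' distance to soma, F4 varicosities per varicosity-branch, F5 fraction of
#' branches bearing varicosities, F6 mean spacing (um) between consecutive
#' varicosities ordered by distance to the soma. Each feature is min-max
#' scaled to 0..100 over the set; neurons with no varicosities are flagged
#' and excluded from scaling.
#'
#' @param varicosity_sets named list of per-neuron varicosity tables (with
#'   `branch` columns).
#' @param trees matching named list of [neuron_tree()].
#' @return List with `scaled` (matrix, 0..100), `raw`, and `excluded` ids.
#' @export
varicosity_radar <- function(varicosity_sets, trees) {
  stopifnot(length(varicosity_sets) == length(trees))
  nms <- names(varicosity_sets) %||% as.character(seq_along(varicosity_sets))
  raw <- t(vapply(seq_along(varicosity_sets), function(i) {
    vs <- varicosity_sets[[i]]; tr <- trees[[i]]
    if (!nrow(vs)) return(c(F1 = 0, F2 = NA, F3 = NA, F4 = NA, F5 = NA, F6 = NA))
    rd <- radial_distribution(tr, vs, n_bins = 4L)
    types <- classify_varicosity_type(vs, tr)
    branches <- branch_decomposition(tr, types = SWC_AXON)
    vb <- unique(vs$branch)
    ordered <- vs[order(rd$distances), ]
    spacing <- if (nrow(ordered) > 1L)
      mean(sqrt(rowSums((as.matrix(ordered[-1L, c("x", "y", "z")]) -
                         as.matrix(ordered[-nrow(ordered), c("x", "y", "z")]))^2)))
      else 0
    c(F1 = nrow(vs), F2 = mean(types == "TEB"),
      F3 = mean(rd$distances / max(rd$distances)),
      F4 = nrow(vs) / length(vb), F5 = length(vb) / length(branches),
      F6 = spacing)
  }, numeric(6)))
  rownames(raw) <- nms
  excluded <- nms[apply(raw, 1L, anyNA)]
  usable <- raw[!(nms %in% excluded), , drop = FALSE]
  scaled <- apply(usable, 2L, function(v) {
    rng <- range(v)
    if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L]) * 100 else rep(100, length(v))
  })
  if (is.null(dim(scaled))) scaled <- matrix(scaled, nrow = 1L,
                                             dimnames = list(rownames(usable), colnames(raw)))
  list(scaled = scaled, raw = raw, excluded = excluded)
}

#' Euclidean minimum spanning tree over varicosities (plus the soma)
#'
#' @param positions matrix (n x 3) of varicosity positions (n >= 2).
#' @param soma soma position (3-vector); vertex 0 of the tree.
#' @return data.frame edge list (`from`, `to`, `weight`; vertex 0 = soma)
#'   with attribute `total_weight`. Prim's algorithm, O(n^2).
#' @export
mst_varicosities <- function(positions, soma = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) stop("need >= 2 varicosities")
  pts <- if (is.null(soma)) positions else rbind(soma, positions)
  off <- if (is.null(soma)) 1L else 0L
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]; parent <- rep(1L, n)
  edges <- list()
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[[step]] <- c(parent[j], j)
    in_tree[j] <- TRUE
    upd <- which(!in_tree & d[j, ] < best)
    best[upd] <- d[j, upd]; parent[upd] <- j
  }
  e <- do.call(rbind, edges)
  out <- data.frame(from = e[, 1L] - (1L - off), to = e[, 2L] - (1L - off),
                    weight = d[e])
  attr(out, "total_weight") <- sum(out$weight)
  out
}

#' Precision and recall of a detection against planted ground truth
#'
#' Greedy one-to-one matching within `match_radius`, visiting detections in
#' descending intensity order.
#'
#' @param detections data.frame with x, y, z (and optionally intensity).
#' @param truth data.frame with x, y, z.
#' @param match_radius matching radius (um), default 2.
#' @return List with `precision`, `recall`, `matched`.
#' @export
evaluate_detection <- function(detections, truth, match_radius = 2) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0L) return(list(precision = NA_real_, recall = 0, matched = 0L))
  ord <- if ("intensity" %in% names(detections))
    order(-detections$intensity) else seq_len(nd)
  dp <- as.matrix(detections[, c("x", "y", "z")])
  tp <- as.matrix(truth[, c("x", "y", "z")])
  used <- logical(nt)
  matched <- 0L
  for (i in ord) {
    d <- sqrt(rowSums(sweep(tp, 2L, dp[i, ])^2))
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= match_radius) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(precision = matched / nd, recall = matched / nt, matched = matched)
}
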