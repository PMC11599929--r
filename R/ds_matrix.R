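# Cross-scale feature vectors and Diversity-and-Stereotypy (DS) matrices.
# A neuron's cross-scale vector concatenates z-scored feature blocks from
# five morphological scales (microenvironment, full morphology, arbors,
# primary-tract motif, varicosities); a DS matrix entry is the mean pairwise
# Pearson correlation of these vectors within (diagonal, stereotypy) or
# between (off-diagonal, diversity) neuron types.

CROSS_SCALE_ORDER <- c("microenviron", "fullMorpho", "arbor", "motif", "varicosity")

#' Transfer microenvironment features from a donor dendrite population
#'
#' The donor is the same-region dendrite whose z-scored L-Measure vector is
#' closest (Euclidean) to the target's; the transferred block is the donor's
#' microenvironment feature vector.
#'
#' @param target_features the target neuron's L-Measure vector.
#' @param target_region the target's soma region label.
#' @param donors list with `regions` (per-donor labels), `lmeasure`
#'   (donor L-Measure matrix) and `microenv` (donor microenvironment block).
#' @return List with `block` (the transferred row, or `NULL` when the region
#'   has no donors), `donor` (row index) and `missing` flag.
#' @export
transfer_microenv_features <- function(target_features, target_region, donors) {
  sel <- which(donors$regions == target_region)
  if (!length(sel)) {
    warning("no donor in region '", target_region, "'; block flagged missing")
    return(list(block = NULL, donor = NA_integer_, missing = TRUE))
  }
  z <- suppressWarnings(standardize(donors$lmeasure))
  zt <- (target_features - colMeans(donors$lmeasure)) /
    ifelse(apply(donors$lmeasure, 2L, pop_sd) > 0,
           apply(donors$lmeasure, 2L, pop_sd), 1)
  d <- sqrt(rowSums(sweep(z[sel, , drop = FALSE], 2L, zt)^2))
  best <- sel[which.min(d)]
  list(block = donors$microenv[best, ], donor = best, missing = FALSE)
}

#' Assemble cross-scale feature vectors for a population
#'
#' Blocks are z-scored per feature over the population and concatenated in
#' the fixed order microenviron, fullMorpho, arbor, motif, varicosity.
#' Neurons with any missing (NA) block entry are excluded.
#'
#' @param blocks named list of numeric matrices with identical rownames
#'   (neuron ids); names must cover `CROSS_SCALE_ORDER`.
#' @return Matrix of z-scored concatenated vectors; attribute `excluded`
#'   lists dropped neuron ids, attribute `block_columns` maps scales to
#'   column ranges.
#' @export
cross_scale_table <- function(blocks) {
  missing_b <- setdiff(CROSS_SCALE_ORDER, names(blocks))
  if (length(missing_b)) stop("missing block(s): ", paste(missing_b, collapse = ", "))
  ids <- rownames(blocks[[CROSS_SCALE_ORDER[1L]]])
  for (b in CROSS_SCALE_ORDER)
    if (!identical(rownames(blocks[[b]]), ids))
      stop("block '", b, "' rownames differ")
  full <- do.call(cbind, lapply(CROSS_SCALE_ORDER, function(b) {
    m <- as.matrix(blocks[[b]])
    colnames(m) <- paste(b, colnames(m) %||% seq_len(ncol(m)), sep = ".")
    m
  }))
  bad <- apply(full, 1L, anyNA)
  if (any(bad)) message("excluding ", sum(bad), " neuron(s) with missing blocks")
  kept <- full[!bad, , drop = FALSE]
  z <- suppressWarnings(standardize(kept))
  dims <- vapply(blocks, ncol, integer(1))[CROSS_SCALE_ORDER]
  ends <- cumsum(dims)
  block_cols <- Map(function(s, e) s:e, c(1L, head(ends, -1L) + 1L), ends)
  names(block_cols) <- CROSS_SCALE_ORDER
  attr(z, "excluded") <- ids[bad]
  attr(z, "block_columns") <- block_cols
  z
}

# mean Pearson correlation over row pairs of two matrices (or within one)
mean_pairwise_r <- function(A, B = NULL) {
  if (is.null(B)) {
    n <- nrow(A)
    if (n < 2L) return(c(r = NA_real_, n = 0))
    cc <- suppressWarnings(cor(t(A)))
    vals <- cc[upper.tri(cc)]
    c(r = mean(vals, na.rm = TRUE), n = length(vals))
  } else {
    cc <- suppressWarnings(cor(t(A), t(B)))
    c(r = mean(cc, na.rm = TRUE), n = length(cc))
  }
}

#' Diversity-and-Stereotypy matrix
#'
#' `s_UV` is the mean Pearson correlation over all cross-type neuron pairs
#' (off-diagonal) or all unordered within-type pairs excluding self-pairs
#' (diagonal).
#'
#' @param vectors matrix of cross-scale vectors (rows = neurons).
#' @param labels type label per neuron.
#' @return List of class `ds_matrix`: `S` (symmetric matrix), `counts`
#'   (pair counts per cell), `types`.
#' @export
ds_matrix <- function(vectors, labels) {
  vectors <- as.matrix(vectors)
  types <- sort(unique(as.character(labels)))
  k <- length(types)
  S <- matrix(NA_real_, k, k, dimnames = list(types, types))
  counts <- matrix(0, k, k, dimnames = list(types, types))
  small <- types[table(factor(labels, types)) < 2L]
  if (length(small))
    warning("type(s) with < 2 neurons have undefined diagonal: ",
            paste(small, collapse = ", "))
  for (i in seq_len(k)) for (j in i:k) {
    A <- vectors[labels == types[i], , drop = FALSE]
    if (i == j) {
      v <- mean_pairwise_r(A)
    } else {
      B <- vectors[labels == types[j], , drop = FALSE]
      v <- mean_pairwise_r(A, B)
    }
    S[i, j] <- S[j, i] <- v["r"]
    counts[i, j] <- counts[j, i] <- v["n"]
  }
  structure(list(S = S, counts = counts, types = types), class = "ds_matrix")
}

#' Distance between per-scale DS matrices
#'
#' `1 - Pearson` over the vectorized upper triangles (diagonal included) of
#' each pair of DS matrices; all matrices must share the same type set.
#'
#' @param ds_list named list of `ds_matrix` objects (or plain matrices).
#' @return Symmetric scale-by-scale distance matrix (NA when a matrix is
#'   constant).
#' @export
scale_distance <- function(ds_list) {
  mats <- lapply(ds_list, function(d) if (inherits(d, "ds_matrix")) d$S else as.matrix(d))
  tys <- lapply(mats, rownames)
  if (!all(vapply(tys, identical, logical(1), tys[[1L]])))
    stop("DS matrices must share one type set")
  vecs <- lapply(mats, function(m) m[upper.tri(m, diag = TRUE)])
  k <- length(vecs)
  out <- matrix(0, k, k, dimnames = list(names(ds_list), names(ds_list)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    xi <- vecs[[i]]; xj <- vecs[[j]]
    ok <- stats::complete.cases(xi, xj)
    out[i, j] <- if (sd(xi[ok]) > 0 && sd(xj[ok]) > 0)
      1 - cor(xi[ok], xj[ok]) else NA_real_
  }
  out
}

# population central moments: mean, sd, skewness (g1), excess kurtosis (g2)
moment_summary <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    return(c(mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_))
  c(mean = m, sd = sqrt(m2),
    skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2 - 3)
}

#' Moments of within-type pairwise correlation distributions
#'
#' For each type (and optionally each scale block), the mean, SD, skewness
#' and excess kurtosis of the distribution of within-type pairwise Pearson
#' correlations.
#'
#' @param vectors cross-scale matrix (rows = neurons).
#' @param labels type labels (each type should have >= 3 neurons).
#' @param block_columns optional named list of column index vectors (one per
#'   scale); defaults to the whole vector as one scale.
#' @return 3-D array type x scale x moment.
#' @export
intra_moments <- function(vectors, labels, block_columns = NULL) {
  vectors <- as.matrix(vectors)
  if (is.null(block_columns))
    block_columns <- attr(vectors, "block_columns") %||%
      list(all = seq_len(ncol(vectors)))
  types <- sort(unique(as.character(labels)))
  out <- array(NA_real_, c(length(types), length(block_columns), 4L),
               dimnames = list(types, names(block_columns),
                               c("mean", "sd", "skewness", "kurtosis")))
  for (ti in seq_along(types)) {
    A <- vectors[labels == types[ti], , drop = FALSE]
    if (nrow(A) < 2L) next
    for (bi in seq_along(block_columns)) {
      sub <- A[, block_columns[[bi]], drop = FALSE]
      cc <- suppressWarnings(cor(t(sub)))
      out[ti, bi, ] <- moment_summary(cc[upper.tri(cc)])
    }
  }
  out
}

#' Pairwise similarity as a function of soma distance
#'
#' All neuron pairs with soma distance at most `max_d` are binned by
#' distance; the per-bin mean and SD of the pairwise Pearson correlation and
#' the overall Pearson correlation between distance and similarity are
#' returned.
#'
#' @param vectors cross-scale matrix (rows = neurons).
#' @param somas soma positions (n x 3, um).
#' @param max_d maximum pair distance (um), default 4000.
#' @param n_bins number of distance bins.
#' @return List with `curve` (data.frame: d_mid, mean_r, sd_r, n) and
#'   `overall_correlation`.
#' @export
similarity_vs_distance <- function(vectors, somas, max_d = 4000, n_bins = 20L) {
  vectors <- as.matrix(vectors); somas <- as.matrix(somas)
  n <- nrow(vectors)
  if (n < 2L) stop("need >= 2 neurons")
  cc <- suppressWarnings(cor(t(vectors)))
  dd <- as.matrix(stats::dist(somas))
  ut <- upper.tri(dd)
  d <- dd[ut]; r <- cc[ut]
  keep <- d <= max_d & is.finite(r)
  if (!any(keep)) stop("no pairs within max_d")
  d <- d[keep]; r <- r[keep]
  bins <- cut(d, seq(0, max_d, length.out = n_bins + 1L),
              include.lowest = TRUE, labels = FALSE)
  curve <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bins == b
    data.frame(d_mid = (b - 0.5) * max_d / n_bins,
               mean_r = if (any(sel)) mean(r[sel]) else NA_real_,
               sd_r = if (sum(sel) > 1L) sd(r[sel]) else NA_real_,
               n = sum(sel))
  }))
  list(curve = curve, overall_correlation = cor(d, r))
}

# --- cross-scale block builders -------------------------------------------

#' Build the five cross-scale feature blocks for a set of neurons
#'
#' Convenience builder: full morphology (18 L-Measure globals), arbors (the
#' dendritic arbor plus two axonal arbors, 4 features each, ordered by
#' distance to soma), primary-tract motif descriptors (21), varicosity radar
#' features (6, from supplied per-neuron varicosity tables), and the
#' transferred microenvironment block (18) from a donor dendrite population.
#'
#' @param trees named list of [neuron_tree()].
#' @param donors donor population for [transfer_microenv_features()]; its
#'   `lmeasure` columns must match the 18 global features.
#' @param regions soma region per tree.
#' @param varicosity_sets named list of per-neuron varicosity tables.
#' @param seed integer seed (arborization k-means).
#' @return Named list of blocks suitable for [cross_scale_table()].
#' @export
cross_scale_blocks <- function(trees, donors, regions, varicosity_sets, seed = 1L) {
  ids <- names(trees) %||% as.character(seq_along(trees))
  fullm <- t(vapply(trees, function(tr) global_features(tr)[MICROENV_GLOBAL_NAMES],
                    numeric(18)))
  rownames(fullm) <- ids
  micro <- t(vapply(seq_along(trees), function(i) {
    tf <- transfer_microenv_features(fullm[i, ], regions[i], donors)
    if (tf$missing) rep(NA_real_, ncol(donors$microenv)) else as.numeric(tf$block)
  }, numeric(ncol(donors$microenv))))
  rownames(micro) <- ids
  arbor <- t(vapply(seq_along(trees), function(i) {
    arbor_block_vector(trees[[i]], seed = seed)
  }, numeric(12)))
  rownames(arbor) <- ids
  motif <- t(vapply(trees, motif_block_vector, numeric(21)))
  rownames(motif) <- ids
  vr <- varicosity_radar(varicosity_sets, trees)
  vari <- vr$raw
  rownames(vari) <- ids
  list(microenviron = micro, fullMorpho = fullm, arbor = arbor,
       motif = motif, varicosity = vari)
}

# dendritic arbor + two axonal arbors x {n_branch, volume, max_density,
# dist2soma}; axons are arborized to exactly two arbors for comparability
arbor_block_vector <- function(tree, seed = 1L) {
  n_ax <- sum(tree$nodes$type == SWC_AXON)
  arbs <- arborize(tree, k = min(2L, max(1L, n_ax)), seed = seed)
  ax <- Filter(function(a) a$kind == "axonal", arbs)
  de <- Filter(function(a) a$kind == "dendritic", arbs)
  feats <- lapply(ax, arbor_features, tree = tree)
  ord <- order(vapply(feats, `[[`, numeric(1), "dist2soma"))
  feats <- feats[ord]
  if (length(feats) == 1L) feats <- c(feats, feats) # degenerate single-arbor axon
  dfeat <- if (length(de)) arbor_features(de[[1L]], tree) else rep(NA_real_, 4)
  out <- c(dfeat, feats[[1L]], feats[[2L]])
  names(out) <- as.vector(outer(c("n_branch", "volume", "max_density", "dist2soma"),
                                c("dend", "ax1", "ax2"),
                                function(a, b) paste(b, a, sep = "_")))
  out
}

# 21 primary-tract descriptors: length, terminus distance, node-radius delta,
# straightness, midpoint (3), terminus (3), unit direction (3), 8-bin mean
# turning angle by arc-length octile
motif_block_vector <- function(tree) {
  tr <- primary_tract(tree)
  pts <- tr$points
  len <- polyline_length(pts)
  disp <- pts[nrow(pts), ] - pts[1L, ]
  term_d <- sqrt(sum(disp^2))
  rs <- resample_polyline(pts, 101L)
  mid <- rs[51L, ]
  v <- rs[-1L, ] - rs[-nrow(rs), ]
  ang <- vapply(seq_len(nrow(v) - 1L), function(i) vec_angle(v[i, ], v[i + 1L, ]),
                numeric(1))
  octile <- cut(seq_along(ang) / length(ang), seq(0, 1, 0.125),
                include.lowest = TRUE, labels = FALSE)
  hist8 <- vapply(1:8, function(b) {
    sel <- octile == b
    if (any(sel)) mean(ang[sel]) else 0
  }, numeric(1))
  dr <- if (!is.null(tr$radii)) tr$radii[length(tr$radii)] - tr$radii[1L] else 0
  out <- c(len, term_d, dr, if (len > 0) term_d / len else 0,
           mid, pts[nrow(pts), ], unit(disp), hist8)
  names(out) <- c("tract_length", "terminus_dist", "delta_radius_node",
                  "straightness", paste0("mid_", c("x", "y", "z")),
                  paste0("term_", c("x", "y", "z")),
                  paste0("dir_", c("x", "y", "z")), paste0("curv_q", 1:8))
  out
}
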