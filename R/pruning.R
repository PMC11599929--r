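# Segment-pruning filter suite for automated reconstructions: angle,
# crossover, soma and winding filters, each run independently on the raw
# tree; the cleaned tree is the node-level intersection of the four keeps,
# with orphaned fragments dropped and tiny results discarded.
#
# Angle conventions: branch angles are measured between the child-branch
# chord (oriented away from the soma) and the reversed parent chord (i.e.
# the direction back toward the soma), so a straight continuation scores
# 180 degrees and a sharp turn-back scores near 0; "excessive angle"
# (< 80 degrees) is a turn-back.

#' Pruning configuration
#'
#' @param voxel_size micrometres per voxel/pixel (converts the pixel-based
#'   thresholds).
#' @param angle_min minimum allowed child angle (deg), default 80.
#' @param radius_gain maximum child/parent mean-radius ratio, default 1.5.
#' @param crossover_window bifurcation-pair window (voxels), default 5.
#' @param mediocre turning-angle range treated as crossover-suspect (deg).
#' @param opposing mutual angle above which a suspect pair is removed (deg).
#' @param soma_area candidate-soma MIP area threshold (px^2), default 500.
#' @param soma_node_radius candidate node radius threshold (px), default 5.
#' @param soma_exclusion protected radius around the true soma (px).
#' @param winding_ratio maximum path/Euclid ratio at a tip, default 3.
#' @param min_nodes minimum surviving size, default 20.
#' @return List of class `prune_config`.
#' @export
prune_config <- function(voxel_size = 1, angle_min = 80, radius_gain = 1.5,
                         crossover_window = 5, mediocre = c(80, 100),
                         opposing = 150, soma_area = 500, soma_node_radius = 5,
                         soma_exclusion = 50, winding_ratio = 3, min_nodes = 20) {
  stopifnot(voxel_size > 0, angle_min > 0, radius_gain > 0, winding_ratio > 0)
  structure(as.list(environment()), class = "prune_config")
}

branch_chord <- function(tree, b) {
  xyz <- node_xyz(tree, b$rows)
  xyz[nrow(xyz), ] - xyz[1L, ]
}

# propagate branch-level removals to descendants; return removed node rows
removed_node_rows <- function(branches, removable) {
  removed <- logical(length(branches))
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    cur <- i
    while (!is.na(cur)) {
      if (removable[cur]) { removed[i] <- TRUE; break }
      cur <- branches[[cur]]$parent_branch
    }
  }
  unique(unlist(lapply(branches[removed], function(b) b$rows[-1L])))
}

# keep an ancestor-closed node subset and drop fragments without the soma
subset_tree <- function(tree, drop_rows) {
  keep <- setdiff(seq_len(nrow(tree$nodes)), drop_rows)
  sr <- soma_row(tree)
  if (!(sr %in% keep)) keep <- c(sr, keep)
  prow <- node_row(tree, tree$nodes$parent)
  keep_set <- logical(nrow(tree$nodes))
  keep_set[keep] <- TRUE
  # ancestor closure: a node survives only if its whole chain to the root does
  surv <- logical(nrow(tree$nodes))
  surv[sr] <- TRUE
  repeat {
    cand <- which(keep_set & !surv & !is.na(prow) &
                    surv[ifelse(is.na(prow), sr, prow)])
    if (!length(cand)) break
    surv[cand] <- TRUE
  }
  nodes <- tree$nodes[surv, , drop = FALSE]
  nodes$parent[!(nodes$parent %in% nodes$id)] <- -1L
  # only the soma may be a root
  nodes <- nodes[nodes$parent != -1L | nodes$id == tree$nodes$id[sr], , drop = FALSE]
  neuron_tree(nodes, tree$meta)
}

prune_result <- function(tree, pruned, removed_ids, filter) {
  structure(list(tree = pruned, removed = removed_ids, filter = filter,
                 input_nodes = nrow(tree$nodes)), class = "prune_result")
}

#' Angle/radius branch filter
#'
#' Removes (with descendants) any branch whose chord makes an angle below
#' `angle_min` with the direction of its parent branch (see the angle
#' convention above), or whose mean radius exceeds `radius_gain` times its
#' parent branch's mean radius.
#'
#' @param tree a valid [neuron_tree()].
#' @param cfg a [prune_config()].
#' @return A `prune_result` with the pruned tree and removed node ids.
#' @export
prune_angle <- function(tree, cfg = prune_config()) {
  branches <- branch_decomposition(tree)
  have_radii <- any(tree$nodes$radius > 0)
  if (!have_radii) warning("no radii present; radius rule skipped")
  removable <- logical(length(branches))
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    pb <- b$parent_branch
    if (is.na(pb)) next
    ang <- vec_angle(-branch_chord(tree, branches[[pb]]), branch_chord(tree, b))
    if (ang < cfg$angle_min) { removable[i] <- TRUE; next }
    if (have_radii) {
      rb <- mean(tree$nodes$radius[b$rows[-1L]])
      rp <- mean(tree$nodes$radius[branches[[pb]]$rows[-1L]])
      if (rp > 0 && rb > cfg$radius_gain * rp) removable[i] <- TRUE
    }
  }
  rows <- removed_node_rows(branches, removable)
  prune_result(tree, subset_tree(tree, rows), tree$nodes$id[rows], "angle")
}

#' Crossover filter
#'
#' Crossover sites are multifurcations (more than two children) and
#' ancestor/descendant bifurcation pairs within `crossover_window` voxels.
#' At a site, outgoing branches at a turning angle below `angle_min` to the
#' through-path are removed; branches in the `mediocre` angle range are
#' removed in pairs when two of them oppose each other by more than
#' `opposing` degrees (a crossing fiber read as two spurs).
#'
#' @inheritParams prune_angle
#' @return A `prune_result`.
#' @export
prune_crossover <- function(tree, cfg = prune_config()) {
  branches <- branch_decomposition(tree)
  kids <- children_index(tree)
  nkids <- lengths(kids)
  xyz <- node_xyz(tree)
  sr <- soma_row(tree)
  win <- cfg$crossover_window * cfg$voxel_size
  end_row <- vapply(branches, function(b) b$rows[length(b$rows)], integer(1))
  # sites: rows of the distal node at which suspect children attach
  multis <- which(nkids > 2L & seq_along(nkids) != sr)
  bifs <- which(nkids == 2L & seq_along(nkids) != sr)
  pair_sites <- list()
  for (v in bifs) {
    anc <- bifs[vapply(bifs, function(u) {
      if (u == v) return(FALSE)
      d <- sqrt(sum((xyz[u, ] - xyz[v, ])^2))
      d <= win && u %in% ancestors_of(tree, v)
    }, logical(1))]
    for (u in anc) pair_sites[[length(pair_sites) + 1L]] <- c(u, v)
  }
  removable <- logical(length(branches))
  eval_site <- function(site_rows) {
    cand <- which(vapply(branches, function(b)
      b$rows[1L] %in% site_rows, logical(1)))
    if (length(cand) < 2L) return()
    # incoming direction at the proximal site node
    prox <- site_rows[1L]
    inc_branch <- which(end_row == prox)
    inc <- if (length(inc_branch)) branch_chord(tree, branches[[inc_branch[1L]]])
           else xyz[prox, ] - xyz[sr, ]
    theta <- vapply(cand, function(i)
      vec_angle(-inc, branch_chord(tree, branches[[i]])), numeric(1))
    # the straightest continuation is the through-path: never removed
    through <- cand[which.max(theta)]
    for (ci in seq_along(cand)) {
      if (cand[ci] == through) next
      if (theta[ci] < cfg$angle_min) removable[cand[ci]] <<- TRUE
    }
    med <- cand[theta >= cfg$mediocre[1L] & theta <= cfg$mediocre[2L] &
                  cand != through]
    if (length(med) >= 2L) {
      for (a in seq_along(med)) for (b in seq_along(med)) {
        if (a >= b) next
        mut <- vec_angle(branch_chord(tree, branches[[med[a]]]),
                         branch_chord(tree, branches[[med[b]]]))
        if (mut > cfg$opposing) removable[c(med[a], med[b])] <<- TRUE
      }
    }
  }
  for (v in multis) eval_site(v)
  for (p in pair_sites) eval_site(p)
  rows <- removed_node_rows(branches, removable)
  prune_result(tree, subset_tree(tree, rows), tree$nodes$id[rows], "crossover")
}

ancestors_of <- function(tree, row) {
  prow <- node_row(tree, tree$nodes$parent)
  out <- integer()
  cur <- prow[row]
  while (!is.na(cur)) { out <- c(out, cur); cur <- prow[cur] }
  out
}

#' Secondary-soma filter
#'
#' Candidate somas are nodes (or groups of nodes within the crossover
#' window) with radius above `soma_node_radius` px whose summed xy-disc area
#' exceeds `soma_area` px^2, excluding anything within `soma_exclusion` px
#' of the true soma. For each candidate, the tree path between the true soma
#' and the candidate is segmented at bifurcations, and each segment is scored
#' by its length-weighted deviation angle toward each end (the angle between
#' the segment direction and the radial line pointing away from that soma at
#' the segment's nearer end: a neurite grown from a soma deviates little from
#' its own radial direction). The path is cut at the first segment whose
#' deviation integral leading to the candidate is lower than the one leading
#' to the true soma (the candidate-side subtree is removed); the candidate
#' node group itself is always removed.
#'
#' @inheritParams prune_angle
#' @return A `prune_result`.
#' @export
prune_soma <- function(tree, cfg = prune_config()) {
  nodes <- tree$nodes
  xyz <- node_xyz(tree)
  sr <- soma_row(tree)
  vx <- cfg$voxel_size
  rad_px <- nodes$radius / vx
  d2soma <- sqrt(rowSums(sweep(xyz, 2L, xyz[sr, ])^2)) / vx
  cand_nodes <- which(rad_px > cfg$soma_node_radius & d2soma > cfg$soma_exclusion &
                        seq_len(nrow(nodes)) != sr)
  removable_rows <- integer()
  if (length(cand_nodes)) {
    # single-linkage grouping within the crossover window
    groups <- list()
    assigned <- rep(NA_integer_, length(cand_nodes))
    for (i in seq_along(cand_nodes)) {
      if (!is.na(assigned[i])) next
      g <- i
      repeat {
        near <- which(is.na(assigned) & vapply(seq_along(cand_nodes), function(j)
          any(sqrt(rowSums(sweep(xyz[cand_nodes[g], , drop = FALSE], 2L,
                                 xyz[cand_nodes[j], ])^2)) / vx <=
                cfg$crossover_window), logical(1)))
        near <- setdiff(near, g)
        if (!length(near)) break
        assigned[near] <- length(groups) + 1L
        g <- c(g, near)
      }
      assigned[g] <- length(groups) + 1L
      groups[[length(groups) + 1L]] <- cand_nodes[g]
    }
    kids <- children_index(tree)
    nkids <- lengths(kids)
    for (g in groups) {
      area <- sum(pi * rad_px[g]^2)
      if (area <= cfg$soma_area) next
      cand <- g[which.max(rad_px[g])]
      # node path soma -> candidate, segmented at tree bifurcations
      path <- c(rev(ancestors_of(tree, cand)), cand)
      bounds <- unique(c(1L, which(nkids[path] >= 2L), length(path)))
      bounds <- sort(bounds[bounds < length(path)])
      segs <- Map(function(a, b) path[a:b], bounds,
                  c(bounds[-1L], length(path)))
      # deviation of a segment toward a soma: angle between the segment
      # chord (oriented soma -> candidate) and the radial direction away
      # from that soma at the segment's nearer end, weighted by length
      dev <- function(seg, target) {
        p0 <- xyz[seg[1L], ]; p1 <- xyz[seg[length(seg)], ]
        nearer <- if (sum((p0 - target)^2) <= sum((p1 - target)^2)) p0 else p1
        radial <- nearer - target
        w <- polyline_length(xyz[seg, , drop = FALSE])
        w * vec_angle(p1 - p0, radial)
      }
      dev_soma <- vapply(segs, dev, numeric(1), target = xyz[sr, ])
      dev_cand <- vapply(segs, dev, numeric(1), target = xyz[cand, ])
      # a segment belongs to the candidate when its deviation integral
      # leading to the candidate is lower than the one leading to the soma
      cut_at <- NA_integer_
      for (k in seq_along(segs)) {
        to_soma <- sum(dev_soma[seq_len(k)])
        to_cand <- sum(dev_cand[k:length(segs)])
        if (to_cand < to_soma) { cut_at <- k; break }
      }
      sub_rows <- integer()
      if (!is.na(cut_at)) {
        cut_row <- segs[[cut_at]][2L]
        sub_rows <- c(cut_row, descendants_of(tree, cut_row))
      }
      # the putative soma group itself is always removed
      for (cn in g) sub_rows <- c(sub_rows, cn, descendants_of(tree, cn))
      removable_rows <- union(removable_rows, sub_rows)
    }
  }
  prune_result(tree, subset_tree(tree, removable_rows),
               nodes$id[removable_rows], "soma")
}

descendants_of <- function(tree, row) {
  kids <- children_index(tree)
  out <- integer()
  stack <- kids[[row]]
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  out
}

#' Winding filter
#'
#' Removes terminal branches whose tip has a path/Euclidean distance ratio
#' to the soma strictly greater than `winding_ratio` (a tip coincident with
#' the soma counts as infinite), together with descendants.
#'
#' @inheritParams prune_angle
#' @return A `prune_result`.
#' @export
prune_winding <- function(tree, cfg = prune_config()) {
  branches <- branch_decomposition(tree)
  pd <- path_distance_all(tree)
  xyz <- node_xyz(tree)
  sr <- soma_row(tree)
  removable <- vapply(branches, function(b) {
    if (!b$is_terminal) return(FALSE)
    tip <- b$rows[length(b$rows)]
    eu <- sqrt(sum((xyz[tip, ] - xyz[sr, ])^2))
    ratio <- if (eu == 0) Inf else pd[tip] / eu
    ratio > cfg$winding_ratio
  }, logical(1))
  rows <- removed_node_rows(branches, removable)
  prune_result(tree, subset_tree(tree, rows), tree$nodes$id[rows], "winding")
}

#' Run all four pruning filters and intersect their keeps
#'
#' Each filter runs independently on the input tree; a node survives only if
#' every filter keeps it. Fragments disconnected from the soma are dropped,
#' and a result with fewer than `min_nodes` nodes is discarded entirely.
#'
#' @inheritParams prune_angle
#' @return List of class `prune_result_all`: `tree` (possibly `NULL` when
#'   discarded), `discarded`, `removed_by_filter`.
#' @export
apply_all <- function(tree, cfg = prune_config()) {
  results <- list(angle = prune_angle(tree, cfg),
                  crossover = prune_crossover(tree, cfg),
                  soma = prune_soma(tree, cfg),
                  winding = prune_winding(tree, cfg))
  removed_ids <- unique(unlist(lapply(results, `[[`, "removed")))
  pruned <- subset_tree(tree, node_row(tree, removed_ids))
  discarded <- nrow(pruned$nodes) < cfg$min_nodes
  structure(list(tree = if (discarded) NULL else pruned,
                 discarded = discarded,
                 removed_by_filter = lapply(results, `[[`, "removed")),
            class = "prune_result_all")
}
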