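# Independent brute-force re-implementation of the morphometric feature
# definitions, written from the textual definitions with naive id-indexed
# recursion (no code shared with the package implementation). Used only as
# a test oracle.

or_children <- function(tree) {
  ids <- tree$nodes$id
  out <- lapply(ids, function(i) ids[tree$nodes$parent == i])
  names(out) <- as.character(ids)
  out
}

or_pos <- function(tree, id) {
  r <- which(tree$nodes$id == id)
  c(tree$nodes$x[r], tree$nodes$y[r], tree$nodes$z[r])
}

or_radius <- function(tree, id) tree$nodes$radius[tree$nodes$id == id]
or_parent <- function(tree, id) tree$nodes$parent[tree$nodes$id == id]
or_soma <- function(tree) tree$nodes$id[tree$nodes$type == 1][1]

or_angle <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  acos(max(-1, min(1, sum(a * b) / na / nb))) * 180 / pi
}

or_pathdist <- function(tree, id) {
  d <- 0
  while (or_parent(tree, id) != -1) {
    p <- or_parent(tree, id)
    d <- d + sqrt(sum((or_pos(tree, id) - or_pos(tree, p))^2))
    id <- p
  }
  d
}

# branches as id chains from one topological point to the next
or_branches <- function(tree) {
  kids <- or_children(tree)
  soma <- or_soma(tree)
  out <- list()
  walk <- function(start, first, ord, parent_idx) {
    chain <- c(start, first)
    cur <- first
    while (length(kids[[as.character(cur)]]) == 1) {
      cur <- kids[[as.character(cur)]][1]
      chain <- c(chain, cur)
    }
    idx <- length(out) + 1
    out[[idx]] <<- list(chain = chain, order = ord, parent_idx = parent_idx,
                        terminal = length(kids[[as.character(cur)]]) == 0)
    for (k in kids[[as.character(cur)]]) walk(cur, k, ord + 1, idx)
  }
  for (k in kids[[as.character(soma)]]) walk(soma, k, 1, NA)
  out
}

or_chain_pathlen <- function(tree, chain) {
  s <- 0
  for (i in seq_along(chain)[-1])
    s <- s + sqrt(sum((or_pos(tree, chain[i]) - or_pos(tree, chain[i - 1]))^2))
  s
}

# next topological point walking distally from a node
or_remote <- function(tree, id) {
  kids <- or_children(tree)
  while (length(kids[[as.character(id)]]) == 1) id <- kids[[as.character(id)]][1]
  or_pos(tree, id)
}

or_tip_count <- function(tree, id) {
  kids <- or_children(tree)
  ks <- kids[[as.character(id)]]
  if (length(ks) == 0) return(1)
  sum(vapply(ks, function(k) or_tip_count(tree, k), numeric(1)))
}

or_hausdorff <- function(tree) {
  P <- as.matrix(tree$nodes[, c("x", "y", "z")])
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  diagl <- sqrt(sum((hi - lo)^2))
  if (diagl <= 0) return(0)
  ss <- diagl / 4 / 2^(0:7)
  NN <- sapply(ss, function(s) {
    keys <- apply(floor(t(t(P) - lo) / s), 1, paste, collapse = "/")
    length(unique(keys))
  })
  xx <- log(1 / ss); yy <- log(NN)
  sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
}

oracle_global_features <- function(tree) {
  nodes <- tree$nodes
  kids <- or_children(tree)
  soma <- or_soma(tree)
  nkid <- vapply(as.character(nodes$id), function(i) length(kids[[i]]), numeric(1))
  bifs <- nodes$id[nkid >= 2 & nodes$id != soma]
  branches <- or_branches(tree)

  edge_surface <- edge_volume <- total_len <- 0
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (p == -1) next
    h <- sqrt(sum((or_pos(tree, nodes$id[i]) - or_pos(tree, p))^2))
    r1 <- or_radius(tree, p); r2 <- nodes$radius[i]
    total_len <- total_len + h
    edge_surface <- edge_surface + pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2)
    edge_volume <- edge_volume + pi * h * (r1^2 + r1 * r2 + r2^2) / 3
  }

  contr <- frag <- c()
  for (b in branches) {
    pl <- or_chain_pathlen(tree, b$chain)
    el <- sqrt(sum((or_pos(tree, b$chain[length(b$chain)]) -
                      or_pos(tree, b$chain[1]))^2))
    if (pl > 0) contr <- c(contr, el / pl)
    frag <- c(frag, length(b$chain) - 1)
  }

  pdr <- al <- ar <- c()
  for (b in bifs) {
    ks <- kids[[as.character(b)]]
    rb <- or_radius(tree, b)
    if (rb > 0) for (k in ks) pdr <- c(pdr, or_radius(tree, k) / rb)
    v1 <- or_pos(tree, ks[1]) - or_pos(tree, b)
    v2 <- or_pos(tree, ks[2]) - or_pos(tree, b)
    al <- c(al, or_angle(v1, v2))
    ar <- c(ar, or_angle(or_remote(tree, ks[1]) - or_pos(tree, b),
                         or_remote(tree, ks[2]) - or_pos(tree, b)))
  }

  eud <- apply(as.matrix(nodes[, c("x", "y", "z")]), 1, function(p)
    sqrt(sum((p - or_pos(tree, soma))^2)))
  pds <- vapply(nodes$id, function(i) or_pathdist(tree, i), numeric(1))

  c(Nodes = nrow(nodes),
    SomaSurface = 4 * pi * or_radius(tree, soma)^2,
    Stems = length(kids[[as.character(soma)]]),
    Bifurcations = length(bifs),
    Branches = length(branches),
    Tips = sum(nkid == 0 & nodes$id != soma),
    OverallWidth = max(nodes$x) - min(nodes$x),
    OverallHeight = max(nodes$y) - min(nodes$y),
    OverallDepth = max(nodes$z) - min(nodes$z),
    AverageDiameter = mean(2 * nodes$radius),
    Length = total_len,
    Surface = edge_surface,
    Volume = edge_volume,
    MaxEuclideanDistance = max(eud),
    MaxPathDistance = max(pds),
    MaxBranchOrder = max(vapply(branches, function(b) b$order, numeric(1)), 0),
    AverageContraction = if (length(contr)) mean(contr) else 0,
    AverageFragmentation = if (length(frag)) mean(frag) else 0,
    AverageParentDaughterRatio = if (length(pdr)) mean(pdr) else 0,
    AverageBifurcationAngleLocal = if (length(al)) mean(al) else 0,
    AverageBifurcationAngleRemote = if (length(ar)) mean(ar) else 0,
    HausdorffDimension = or_hausdorff(tree))
}

oracle_branch_features <- function(tree) {
  branches <- or_branches(tree)
  kids <- or_children(tree)
  soma <- or_soma(tree)
  rows <- lapply(branches, function(b) {
    chain <- b$chain
    pl <- or_chain_pathlen(tree, chain)
    last <- chain[length(chain)]
    el <- sqrt(sum((or_pos(tree, last) - or_pos(tree, chain[1]))^2))
    res <- c(br_length = pl, br_order = b$order,
             br_contraction = if (pl > 0) el / pl else 0,
             bif_EucDist2soma = sqrt(sum((or_pos(tree, chain[1]) -
                                            or_pos(tree, soma))^2)),
             bif_PathDist2soma = or_pathdist(tree, chain[1]),
             asymmetry = 0, ampl_local = 0, ampl_remote = 0,
             tilt_local = 0, tilt_remote = 0,
             .first = chain[1], .last = last)
    ks <- kids[[as.character(last)]]
    if (length(ks) >= 2) {
      n1 <- or_tip_count(tree, ks[1]); n2 <- or_tip_count(tree, ks[2])
      res["asymmetry"] <- if (n1 + n2 > 2) abs(n1 - n2) / (n1 + n2 - 2) else 0
      pe <- or_pos(tree, last)
      v1 <- or_pos(tree, ks[1]) - pe; v2 <- or_pos(tree, ks[2]) - pe
      w1 <- or_remote(tree, ks[1]) - pe; w2 <- or_remote(tree, ks[2]) - pe
      res["ampl_local"] <- or_angle(v1, v2)
      res["ampl_remote"] <- or_angle(w1, w2)
      bl <- or_pos(tree, chain[max(1, length(chain) - 1)]) - pe
      br <- or_pos(tree, chain[1]) - pe
      res["tilt_local"] <- (or_angle(bl, v1) + or_angle(bl, v2)) / 2
      res["tilt_remote"] <- (or_angle(br, w1) + or_angle(br, w2)) / 2
    }
    res
  })
  as.data.frame(do.call(rbind, rows))
}
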