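#' @importFrom stats median quantile prcomp kmeans hclust as.dist cor sd runif
#'   rnorm rlnorm rpois rbinom approx aggregate cutree optim var
#' @importFrom utils head tail read.table write.table combn
NULL

# SWC type codes used throughout: 1 soma, 2 axon, 3 basal dendrite,
# 4 apical dendrite. Other codes are preserved but flagged by validate().
SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_BASAL <- 3L
SWC_APICAL <- 4L

#' Construct a neuron tree
#'
#' A `neuron_tree` is the package's central container: a rooted tree of SWC
#' nodes with coordinates in micrometres (CCF convention: x anterior-posterior,
#' y dorsal-ventral, z left-right), per-node radii and structure-type labels.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent` (parent id, `-1` for the root).
#' @param meta optional named list of metadata (neuron id, brain id, soma
#'   region, s-type, projection class, layer).
#' @return An object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes, meta = list()) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes)))
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  nodes <- nodes[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id))
    stop("duplicated node ids: ", paste(nodes$id[duplicated(nodes$id)], collapse = ", "))
  if (any(nodes$radius < 0)) stop("negative radius")
  if (any(nodes$parent == nodes$id)) stop("node cannot be its own parent")
  dangling <- nodes$parent != -1L & !(nodes$parent %in% nodes$id)
  if (any(dangling))
    stop("structural error: node(s) ", paste(nodes$id[dangling], collapse = ", "),
         " reference absent parent id(s) ", paste(nodes$parent[dangling], collapse = ", "))
  structure(list(nodes = nodes, meta = meta), class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  n <- nrow(x$nodes)
  tab <- table(factor(x$nodes$type, levels = 1:4,
                      labels = c("soma", "axon", "basal", "apical")))
  cat(sprintf("neuron_tree: %d nodes (%s)\n", n,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# row index of a node id (vectorized)
node_row <- function(tree, ids) match(ids, tree$nodes$id)

# list of integer vectors: children row indices per node row
children_index <- function(tree) {
  n <- nrow(tree$nodes)
  prow <- node_row(tree, tree$nodes$parent)
  kids <- vector("list", n)
  ok <- which(!is.na(prow))
  if (length(ok)) {
    sp <- split(ok, prow[ok])
    kids[as.integer(names(sp))] <- sp
  }
  kids
}

root_row <- function(tree) which(tree$nodes$parent == -1L)

soma_row <- function(tree) {
  r <- which(tree$nodes$type == SWC_SOMA)
  if (length(r) == 0L) r <- root_row(tree)
  r[1L]
}

node_xyz <- function(tree, rows = seq_len(nrow(tree$nodes))) {
  as.matrix(tree$nodes[rows, c("x", "y", "z")])
}

#' Read an SWC reconstruction
#'
#' Parses the standard whitespace-delimited 7-column SWC dialect
#' (id, type, x, y, z, radius, parent; `#` comments). Coordinates are taken
#' as micrometres. Multiple soma points are collapsed to the first soma node
#' (children re-parented), with a warning.
#'
#' @param path path to an SWC file.
#' @param meta optional metadata list attached to the tree.
#' @return A [neuron_tree()].
#' @export
read_swc <- function(path, meta = list()) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no data lines in ", path)
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected 7 columns, got %d",
                 idx[bad[1L]], path, lengths(parts)[bad[1L]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop(sprintf("parse error at line %d of %s: non-numeric field", idx[bad], path))
  }
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]))
  soma_rows <- which(nodes$type == SWC_SOMA)
  if (length(soma_rows) > 1L) {
    warning("multiple soma points; collapsed to the first (id ",
            nodes$id[soma_rows[1L]], ")")
    keep_id <- nodes$id[soma_rows[1L]]
    drop_ids <- nodes$id[soma_rows[-1L]]
    nodes$parent[nodes$parent %in% drop_ids] <- keep_id
    nodes <- nodes[!(nodes$id %in% drop_ids), ]
    nodes$parent[nodes$id == keep_id] <- -1L
  }
  neuron_tree(nodes, meta)
}

#' Write an SWC reconstruction
#'
#' Nodes are written in ascending id order with a header comment recording the
#' tool version and the micrometre/CCF coordinate convention, so that
#' `read_swc(write_swc(tree))` round-trips the node table exactly.
#'
#' @param tree a [neuron_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  nodes <- tree$nodes[order(tree$nodes$id), ]
  ver <- as.character(utils::packageVersion("morphoscales"))
  header <- c(sprintf("# generated by morphoscales %s", ver),
              "# coordinates in um (CCF frame: x AP, y DV, z LR)",
              "# id type x y z radius parent")
  body <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                  nodes$id, nodes$type, nodes$x, nodes$y, nodes$z,
                  nodes$radius, nodes$parent)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Validate a reconstruction against the six structural criteria
#'
#' Checks (1) single soma, (2) single connected graph, (3) no loop,
#' (4) no duplicated compartments, (5) bifurcation-only branching outside the
#' soma, and (6) consistent dendrite/axon labels along each branch.
#'
#' @param tree a [neuron_tree()].
#' @return A `validation_report`: list of per-criterion results, each with
#'   `pass` and `offending` node ids, plus overall `valid`.
#' @export
validate <- function(tree) {
  nodes <- tree$nodes
  res <- list()

  soma_ids <- nodes$id[nodes$type == SWC_SOMA]
  res$single_soma <- list(pass = length(soma_ids) == 1L,
                          offending = if (length(soma_ids) == 1L) integer() else soma_ids)

  g <- tree_graph(tree)
  comp <- igraph::components(g)
  res$connected <- list(pass = comp$no <= 1L,
                        offending = if (comp$no <= 1L) integer() else
                          nodes$id[comp$membership != comp$membership[root_row(tree)[1L]]])

  # loop check: walk parents from every node; a revisit inside one walk is a cycle
  prow <- node_row(tree, nodes$parent)
  n <- nrow(nodes)
  loop_ids <- integer()
  state <- integer(n) # 0 unseen, 1 in progress, 2 done
  for (i in seq_len(n)) {
    j <- i
    chain <- integer()
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      chain <- c(chain, j)
      j <- prow[j]
    }
    if (!is.na(j) && state[j] == 1L) loop_ids <- c(loop_ids, nodes$id[j])
    state[chain] <- 2L
  }
  res$no_loop <- list(pass = length(loop_ids) == 0L, offending = unique(loop_ids))

  key <- paste(nodes$x, nodes$y, nodes$z, nodes$parent)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  res$no_duplicates <- list(pass = !any(dup), offending = nodes$id[dup])

  kids <- children_index(tree)
  nkids <- lengths(kids)
  multi <- which(nkids > 2L & nodes$type != SWC_SOMA)
  res$bifurcation_only <- list(pass = length(multi) == 0L, offending = nodes$id[multi])

  # label consistency: each non-soma child must share its non-soma parent's type
  bad_lbl <- which(!is.na(prow) & nodes$type != SWC_SOMA &
                     nodes$type[ifelse(is.na(prow), 1L, prow)] != SWC_SOMA &
                     nodes$type != nodes$type[ifelse(is.na(prow), 1L, prow)])
  res$consistent_labels <- list(pass = length(bad_lbl) == 0L, offending = nodes$id[bad_lbl])

  res$valid <- all(vapply(res[1:6], function(r) r$pass, logical(1)))
  class(res) <- "validation_report"
  res
}

#' @export
print.validation_report <- function(x, ...) {
  for (nm in setdiff(names(x), "valid")) {
    cat(sprintf("%-20s %s", nm, if (x[[nm]]$pass) "PASS" else "FAIL"))
    if (!x[[nm]]$pass)
      cat("  [", paste(utils::head(x[[nm]]$offending, 10L), collapse = ", "), "]")
    cat("\n")
  }
  cat("overall:", if (x$valid) "valid" else "INVALID", "\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
report_json <- function(report, path = NULL) {
  obj <- lapply(unclass(report)[setdiff(names(report), "valid")],
                function(r) list(pass = r$pass, offending = as.integer(r$offending)))
  obj$valid <- report$valid
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

tree_graph <- function(tree, weighted = FALSE) {
  nodes <- tree$nodes
  prow <- node_row(tree, nodes$parent)
  e <- which(!is.na(prow))
  el <- rbind(prow[e], e)
  g <- igraph::graph_from_edgelist(matrix(t(el), ncol = 2L), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(nodes) - igraph::vcount(g)))
  if (weighted) {
    w <- sqrt((nodes$x[e] - nodes$x[prow[e]])^2 +
              (nodes$y[e] - nodes$y[prow[e]])^2 +
              (nodes$z[e] - nodes$z[prow[e]])^2)
    igraph::E(g)$weight <- w
  }
  g
}

#' Decompose a tree into branches
#'
#' A branch is the chain of nodes between two topological points (soma,
#' bifurcation, or tip), inclusive of both endpoints. Branch order counts from
#' the soma outward with stems = 1.
#'
#' @param tree a valid [neuron_tree()].
#' @param types optional SWC type codes to restrict to (e.g. `2` for axon);
#'   the soma is always allowed as a branch origin.
#' @return A list of branches; each has `rows` (node row indices, proximal to
#'   distal), `ids`, `order`, `is_terminal`, `parent_branch` (index or NA) and
#'   `type` (SWC code of the branch's distal node).
#' @export
branch_decomposition <- function(tree, types = NULL) {
  v <- validate(tree)
  if (!v$no_loop$pass || !v$single_soma$pass)
    stop("refusing to decompose an invalid tree (loop or soma criterion failed)")
  nodes <- tree$nodes
  kids <- children_index(tree)
  if (!is.null(types)) {
    keep <- nodes$type %in% c(SWC_SOMA, types)
    kids <- lapply(kids, function(k) k[keep[k]])
    kids[!keep] <- list(integer())
  }
  sr <- soma_row(tree)
  nkids <- lengths(kids)
  branches <- list()
  # stack of (start row, first child row, order, parent branch index)
  stack <- lapply(kids[[sr]], function(k) list(start = sr, first = k, order = 1L, pb = NA_integer_))
  while (length(stack)) {
    it <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    chain <- c(it$start, it$first)
    cur <- it$first
    while (nkids[cur] == 1L) {
      cur <- kids[[cur]][1L]
      chain <- c(chain, cur)
    }
    bi <- length(branches) + 1L
    branches[[bi]] <- list(rows = chain, ids = nodes$id[chain], order = it$order,
                           is_terminal = nkids[cur] == 0L,
                           parent_branch = it$pb, type = nodes$type[cur])
    for (k in rev(kids[[cur]]))
      stack[[length(stack) + 1L]] <- list(start = cur, first = k,
                                          order = it$order + 1L, pb = bi)
  }
  branches
}

# per-node cumulative path distance from the soma (um), NA for disconnected
path_distance_all <- function(tree) {
  nodes <- tree$nodes
  prow <- node_row(tree, nodes$parent)
  n <- nrow(nodes)
  step <- rep(0, n)
  e <- which(!is.na(prow))
  step[e] <- sqrt((nodes$x[e] - nodes$x[prow[e]])^2 +
                  (nodes$y[e] - nodes$y[prow[e]])^2 +
                  (nodes$z[e] - nodes$z[prow[e]])^2)
  dist <- rep(NA_real_, n)
  sr <- soma_row(tree)
  dist[sr] <- 0
  # nodes are not guaranteed topologically sorted: iterate until settled
  repeat {
    todo <- which(is.na(dist) & !is.na(prow) & !is.na(dist[ifelse(is.na(prow), sr, prow)]))
    if (!length(todo)) break
    dist[todo] <- dist[prow[todo]] + step[todo]
  }
  dist
}

#' Path and Euclidean distance from the soma to a node
#'
#' @param tree a [neuron_tree()].
#' @param node node id.
#' @return Distance in micrometres.
#' @export
path_distance <- function(tree, node) {
  r <- node_row(tree, node)
  if (anyNA(r)) stop("unknown node id: ", paste(node[is.na(r)], collapse = ", "))
  path_distance_all(tree)[r]
}

#' @rdname path_distance
#' @export
euclid_distance <- function(tree, node) {
  r <- node_row(tree, node)
  if (anyNA(r)) stop("unknown node id: ", paste(node[is.na(r)], collapse = ", "))
  sr <- soma_row(tree)
  sqrt((tree$nodes$x[r] - tree$nodes$x[sr])^2 +
       (tree$nodes$y[r] - tree$nodes$y[sr])^2 +
       (tree$nodes$z[r] - tree$nodes$z[sr])^2)
}

#' Total arc length of a polyline
#' @param pts numeric matrix of ordered points (n x 3).
#' @return Sum of consecutive segment lengths.
#' @export
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Resample a polyline at uniform arc-length spacing
#'
#' @param points numeric matrix (n x 3) of ordered polyline vertices.
#' @param n number of output points (>= 2); endpoints are preserved exactly.
#' @return An `n` x 3 matrix of points on the polyline at equal arc-length
#'   spacing.
#' @export
resample_polyline <- function(points, n) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || n < 2L) stop("need >= 2 points and n >= 2")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate zero-length polyline")
  # collapse zero-length segments for interpolation
  keep <- c(TRUE, seg > 0)
  s <- s[keep]; points <- points[keep, , drop = FALSE]
  target <- seq(0, total, length.out = n)
  out <- vapply(1:3, function(d) approx(s, points[, d], xout = target)$y,
                numeric(n))
  out <- matrix(out, nrow = n)
  out[1L, ] <- points[1L, ]
  out[n, ] <- points[nrow(points), ]
  out
}
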