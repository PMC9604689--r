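# Weighted graphs over voxels, node collapsing, MST and path cuts.
#
# A weighted_graph is a list with fields
#   nodes : sorted integer vector of node identifiers
#   u, v  : integer edge endpoints (u < v), referring to `nodes` values
#   w     : numeric edge weights (>= 0)
#   shape : optional (M, N, L) when nodes are voxel ids
# Spanning trees and cut forests reuse the same representation (classes
# "spanning_tree" / "cut_forest" prepended).

new_weighted_graph <- function(nodes, u, v, w, shape = NULL,
                               class = "weighted_graph") {
  uu <- pmin(u, v); vv <- pmax(u, v)
  structure(list(nodes = sort(unique(as.integer(nodes))),
                 u = as.integer(uu), v = as.integer(vv), w = as.numeric(w),
                 shape = shape),
            class = class)
}

#' Construct a weighted graph from an edge list
#'
#' @param u,v Integer edge endpoints.
#' @param w Numeric nonnegative edge weights.
#' @param nodes Node identifiers (defaults to the endpoints' union).
#' @return A \code{weighted_graph} object.
#' @export
weighted_graph <- function(u, v, w, nodes = union(u, v)) {
  if (length(u) != length(v) || length(u) != length(w))
    stop("`u`, `v`, `w` must have equal length", call. = FALSE)
  if (any(w < 0)) stop("edge weights must be nonnegative", call. = FALSE)
  if (any(u == v)) stop("self-loops are not allowed", call. = FALSE)
  new_weighted_graph(nodes, u, v, w)
}

#' @export
print.weighted_graph <- function(x, ...) {
  kind <- class(x)[1L]
  cat(sprintf("<%s> %d nodes, %d edges", kind, length(x$nodes), length(x$u)))
  if (!is.null(x$shape)) cat(" on grid ", paste(x$shape, collapse = "x"), sep = "")
  cat("\n")
  invisible(x)
}

#' Build the 6-connected voxel adjacency graph
#'
#' One node per voxel; edges join voxels at unit squared Euclidean distance
#' (6-connectivity); the weight of an edge is the absolute intensity
#' difference of the voxels it connects. For an (M, N, L) grid the edge
#' count is 3MNL - MN - NL - ML.
#'
#' @param vol A preprocessed 3D intensity array.
#' @return A \code{weighted_graph} (subclass \code{"voxel_graph"}) whose
#'   nodes are the column-major linear voxel indices
#'   \code{1 + i + j*M + k*M*N}.
#' @export
build_adjacency_graph <- function(vol) {
  check_volume(vol)
  shape <- dim(vol)
  if (any(shape < 2L))
    stop("every grid dimension must be >= 2 to build an adjacency graph",
         call. = FALSE)
  e <- grid_edge_ids(shape)
  new_weighted_graph(seq_len(prod(shape)), e$u, e$v, abs(vol[e$u] - vol[e$v]),
                     shape = shape, class = c("voxel_graph", "weighted_graph"))
}

#' Collapse a node set onto a single representative
#'
#' Implements the three-step contraction: (1) edges with both endpoints in
#' \code{H} are discarded; (2) in every remaining edge, endpoints belonging
#' to \code{H} are replaced by the representative \code{h}; (3) all nodes of
#' \code{H} except \code{h} are removed. Parallel edges created by the
#' replacement are reduced to their minimum-weight representative, which
#' leaves the minimum spanning tree unchanged.
#'
#' @param g A \code{weighted_graph}.
#' @param H Node subset to collapse (nonempty, within \code{g$nodes}).
#' @param h Representative node; must be an element of \code{H}.
#' @return A \code{weighted_graph} with \code{length(g$nodes) - length(H) + 1}
#'   nodes and no self-loops.
#' @export
collapse_nodes <- function(g, H, h) {
  H <- unique(as.integer(H))
  h <- as.integer(h)
  if (!(h %in% H)) stop("`h` must be a member of `H`", call. = FALSE)
  if (!all(H %in% g$nodes)) stop("`H` must be a subset of the graph's nodes",
                                 call. = FALSE)
  top <- max(g$nodes)
  map <- integer(top); map[g$nodes] <- g$nodes; map[H] <- h
  u2 <- map[g$u]; v2 <- map[g$v]
  keep <- u2 != v2                                  # drop internal edges
  u2 <- u2[keep]; v2 <- v2[keep]; w2 <- g$w[keep]
  uu <- pmin(u2, v2); vv <- pmax(u2, v2)
  # min-weight reduction of parallel edges
  key <- as.numeric(uu) * (top + 1) + vv
  o <- order(key, w2)
  first <- !duplicated(key[o])
  sel <- o[first]
  new_weighted_graph(setdiff(g$nodes, setdiff(H, h)), uu[sel], vv[sel], w2[sel],
                     shape = g$shape)
}

as_igraph <- function(g) {
  iu <- match(g$u, g$nodes); iv <- match(g$v, g$nodes)
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
  if (length(iu)) {
    ig <- igraph::add_edges(ig, rbind(iu, iv))
    igraph::E(ig)$weight <- g$w
  }
  ig
}

#' Minimum spanning tree of a weighted graph
#'
#' Returns a spanning tree of least total edge weight. Edges are first put
#' in canonical order (weight, then endpoint pair) so the result is
#' deterministic under ties.
#'
#' @param g A connected \code{weighted_graph}.
#' @return A \code{spanning_tree} (a \code{weighted_graph} subclass with
#'   \code{length(nodes) - 1} edges).
#' @export
minimum_spanning_tree <- function(g) {
  o <- order(g$w, g$u, g$v)
  gs <- new_weighted_graph(g$nodes, g$u[o], g$v[o], g$w[o], shape = g$shape)
  ig <- as_igraph(gs)
  comp <- igraph::components(ig)
  if (comp$no != 1L)
    stop("graph is disconnected (", comp$no,
         " components); a spanning tree requires a connected graph",
         call. = FALSE)
  mt <- igraph::mst(ig, weights = igraph::E(ig)$weight)
  el <- igraph::as_edgelist(mt, names = FALSE)
  new_weighted_graph(gs$nodes, gs$nodes[el[, 1L]], gs$nodes[el[, 2L]],
                     igraph::E(mt)$weight, shape = gs$shape,
                     class = c("spanning_tree", "weighted_graph"))
}

#' Unique path between two nodes of a tree
#'
#' @param tree A \code{spanning_tree} or \code{cut_forest}.
#' @param u,v Node identifiers present in the tree.
#' @return Integer vector of node ids from \code{u} to \code{v} inclusive;
#'   \code{integer(0)} when \code{u == v}; \code{NULL} when \code{u} and
#'   \code{v} lie in different components.
#' @export
tree_path <- function(tree, u, v) {
  if (!(u %in% tree$nodes) || !(v %in% tree$nodes))
    stop("both endpoints must be nodes of the tree", call. = FALSE)
  if (u == v) return(integer(0))
  ig <- as_igraph(tree)
  sp <- suppressWarnings(igraph::shortest_paths(
    ig, from = match(u, tree$nodes), to = match(v, tree$nodes),
    weights = NA, output = "vpath"))
  p <- as.integer(sp$vpath[[1L]])
  if (length(p) == 0L) return(NULL)
  tree$nodes[p]
}

#' Remove the maximum-weight edge on the path between two nodes
#'
#' Finds the unique path joining \code{u} and \code{v} in the tree/forest
#' and deletes its heaviest edge, splitting their shared component in two.
#' When several path edges share the maximum weight, the one closest to
#' \code{u} is removed.
#'
#' @param forest A \code{spanning_tree} or \code{cut_forest}.
#' @param u,v Node identifiers currently in the same component.
#' @return A \code{cut_forest} with the edge removed; the removed edges so
#'   far are recorded in the \code{removed} field.
#' @export
cut_max_edge <- function(forest, u, v) {
  path <- tree_path(forest, u, v)
  if (is.null(path))
    stop("nodes ", u, " and ", v, " are already in different components",
         call. = FALSE)
  if (length(path) < 2L)
    stop("cannot cut a path between a node and itself", call. = FALSE)
  pu <- pmin(path[-length(path)], path[-1L])
  pv <- pmax(path[-length(path)], path[-1L])
  idx <- match(paste(pu, pv), paste(forest$u, forest$v))
  wmax <- max(forest$w[idx])
  drop_on_path <- which(forest$w[idx] == wmax)[1L]   # tie: nearest to u
  drop <- idx[drop_on_path]
  removed <- rbind(if (!is.null(forest$removed)) forest$removed,
                   data.frame(u = forest$u[drop], v = forest$v[drop],
                              w = forest$w[drop]))
  out <- new_weighted_graph(forest$nodes, forest$u[-drop], forest$v[-drop],
                            forest$w[-drop], shape = forest$shape,
                            class = c("cut_forest", "weighted_graph"))
  out$removed <- removed
  out
}

#' Connected-component membership of a graph or forest
#'
#' @param g A \code{weighted_graph}.
#' @return Integer vector of component labels (1-based), named by node id.
#' @export
graph_components <- function(g) {
  comp <- igraph::components(as_igraph(g))
  stats::setNames(as.integer(comp$membership), g$nodes)
}

#' Export a graph as a weighted edge-list CSV
#'
#' @param g A \code{weighted_graph}.
#' @param path Output CSV path (columns \code{u, v, w}).
#' @return The path, invisibly.
#' @export
write_edge_list <- function(g, path) {
  utils::write.csv(data.frame(u = g$u, v = g$v, w = g$w), path,
                   row.names = FALSE)
  invisible(path)
}
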