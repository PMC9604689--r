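# Internal helpers shared across modules.

# Voxel coordinates are 0-based triples (i, j, k) with 0 <= i < M etc., matching
# the indexing used throughout the method's description. Node identifiers are
# 1-based linear indices in R's native column-major order:
#   id = 1 + i + j*M + k*M*N
# so that labels reshape back onto the volume with a single dim<- assignment.

coords_to_ids <- function(coords, shape) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  1L + coords[, 1L] + coords[, 2L] * shape[1L] + coords[, 3L] * shape[1L] * shape[2L]
}

ids_to_coords <- function(ids, shape) {
  ids0 <- ids - 1L
  i <- ids0 %% shape[1L]
  j <- (ids0 %/% shape[1L]) %% shape[2L]
  k <- ids0 %/% (shape[1L] * shape[2L])
  cbind(i = as.integer(i), j = as.integer(j), k = as.integer(k))
}

check_volume <- function(vol, arg = "vol") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(sprintf("`%s` must be a 3D array, got %s dimension(s)", arg,
                 if (is.array(vol)) length(dim(vol)) else "no"), call. = FALSE)
  invisible(vol)
}

in_bounds <- function(coords, shape) {
  coords[, 1L] >= 0L & coords[, 1L] < shape[1L] &
    coords[, 2L] >= 0L & coords[, 2L] < shape[2L] &
    coords[, 3L] >= 0L & coords[, 3L] < shape[3L]
}

# 6-neighbour voxel pairs of a full (M, N, L) grid, as linear node ids.
# Returns list(u, v) with u < v; one entry per grid edge along each axis.
grid_edge_ids <- function(shape) {
  M <- shape[1L]; N <- shape[2L]; L <- shape[3L]
  idx <- array(seq_len(M * N * L), dim = shape)
  u1 <- idx[-M, , , drop = FALSE]; v1 <- idx[-1L, , , drop = FALSE]
  u2 <- idx[, -N, , drop = FALSE]; v2 <- idx[, -1L, , drop = FALSE]
  u3 <- idx[, , -L, drop = FALSE]; v3 <- idx[, , -1L, drop = FALSE]
  list(u = c(u1, u2, u3), v = c(v1, v2, v3))
}

# Label 6-connected components of a logical 3D mask. Returns an integer array
# (0 outside the mask, component id inside) plus component sizes.
label_components <- function(mask) {
  check_volume(mask, "mask")
  shape <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, dim = shape)
  if (length(fg) == 0L)
    return(list(labels = lab, sizes = integer(0)))
  map <- integer(prod(shape))          # full-grid id -> foreground index
  map[fg] <- seq_along(fg)
  e <- grid_edge_ids(shape)
  keep <- mask[e$u] & mask[e$v]
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(map[e$u[keep]], map[e$v[keep]]))
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  list(labels = lab, sizes = as.integer(comp$csize))
}
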