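# Seed sampling: the three mutually disjoint coordinate sets
#   TB  - points inside the brain
#   TNB - points inside non-brain head tissue
#   TBG - points in the background
# All coordinates are 0-based (i, j, k) matrices with one row per point.

pull_points <- function(edges, delta) {
  co <- cbind(edges$i, edges$j, edges$k)
  ax <- edges$axis + 1L
  # +sign * delta moves from the surface into the foreground for both
  # transition directions (the recorded voxel is the foreground-side one)
  co[cbind(seq_len(nrow(co)), ax)] <-
    co[cbind(seq_len(nrow(co)), ax)] + edges$sign * as.integer(delta)
  co
}

#' Sample seed points inside the brain (TB)
#'
#' Keeps surface edge points on the superior side of the selection line,
#' pulls each inward by \code{delta1} voxels along its detection axis, and
#' discards pulled points farther from the centroid of the pulled cloud than
#' \code{distance_factor} times the maximum centroid distance. The filter
#' restricts the points to the brain and removes points near the skull.
#'
#' @param edges An \code{edge_points} object (surface of the hole-filled
#'   head).
#' @param vol The preprocessed intensity volume (used for bounds).
#' @param selection_line Axis-0 index; only edge points on the chosen side
#'   are brain-seed candidates.
#' @param delta1 Pull distance in voxels (default 15 at the 128-grid scale).
#' @param distance_factor Centroid-distance cutoff factor (default 0.75).
#' @param direction \code{"above"} (default) keeps points with axis-0 index
#'   strictly below \code{selection_line} (the superior side in standard
#'   orientation); \code{"below"} keeps the other side.
#' @return Integer matrix of 0-based (i, j, k) coordinates.
#' @export
sample_brain_points <- function(edges, vol, selection_line, delta1 = 15L,
                                distance_factor = 0.75,
                                direction = c("above", "below")) {
  direction <- match.arg(direction)
  check_volume(vol)
  shape <- dim(vol)
  if (!is.numeric(selection_line) || selection_line < 0 || selection_line > shape[1L])
    stop("`selection_line` must lie within the axis-0 extent", call. = FALSE)
  if (delta1 < 1L) stop("`delta1` must be >= 1", call. = FALSE)
  keep <- if (direction == "above") edges$i < selection_line else edges$i > selection_line
  cand <- edges[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no edge points on the '", direction, "' side of selection line ",
         selection_line, "; check orientation and line placement", call. = FALSE)
  pulled <- pull_points(cand, delta1)
  pulled <- pulled[in_bounds(pulled, shape), , drop = FALSE]
  if (nrow(pulled) == 0L)
    stop("all brain candidates left the volume after the delta1 pull", call. = FALSE)
  centroid <- colMeans(pulled)
  d <- sqrt(rowSums((pulled - rep(centroid, each = nrow(pulled)))^2))
  pulled <- pulled[d <= distance_factor * max(d), , drop = FALSE]
  unique_coords(pulled)
}

#' Sample seed points in non-brain tissue (TNB)
#'
#' Pulls every surface edge point inward by \code{delta2} voxels along its
#' detection axis; pulled points landing on zero intensity are removed.
#' With \code{delta2} large enough to pass the bright outer tissue, the
#' points land in the dark interface between brain and skull, which is what
#' lets the tree cut separate the brain cleanly.
#'
#' @param edges An \code{edge_points} object.
#' @param vol The preprocessed intensity volume.
#' @param delta2 Pull distance in voxels (default 1).
#' @return Integer matrix of 0-based (i, j, k) coordinates.
#' @export
sample_nonbrain_points <- function(edges, vol, delta2 = 1L) {
  check_volume(vol)
  if (nrow(edges) == 0L)
    stop("no edge points supplied for non-brain sampling", call. = FALSE)
  if (delta2 < 1L) stop("`delta2` must be >= 1", call. = FALSE)
  pulled <- pull_points(edges, delta2)
  pulled <- pulled[in_bounds(pulled, dim(vol)), , drop = FALSE]
  if (nrow(pulled)) {
    val <- vol[pulled + 1L]
    pulled <- pulled[val != 0, , drop = FALSE]
  }
  if (nrow(pulled) == 0L)
    stop("all pulled non-brain points landed on zero intensity; ",
         "reduce `delta2` or revisit thresholding", call. = FALSE)
  unique_coords(pulled)
}

#' Sample background seed points (TBG)
#'
#' Candidates are all zero voxels of the hole-filled binary head volume
#' (which always include the zero voxels on the six boundary faces);
#' \code{n_background} of them are drawn uniformly at random without
#' replacement. Sampling uses the current RNG state; seed it (or run inside
#' [gubs()]) for reproducibility.
#'
#' @param closed A hole-filled binary volume ([fill_holes()] output).
#' @param n_background Number of points to draw (default 20000); if the pool
#'   is smaller, all zero voxels are returned.
#' @return Integer matrix of 0-based (i, j, k) coordinates.
#' @export
sample_background_points <- function(closed, n_background = 20000L) {
  check_volume(closed)
  if (n_background < 1L) stop("`n_background` must be >= 1", call. = FALSE)
  pool <- which(closed == 0)
  if (length(pool) == 0L)
    stop("no zero voxels available for background sampling", call. = FALSE)
  ids <- if (length(pool) <= n_background) pool else sample(pool, n_background)
  ids_to_coords(ids, dim(closed))
}

unique_coords <- function(co) {
  storage.mode(co) <- "integer"
  colnames(co) <- c("i", "j", "k")
  co[!duplicated(co), , drop = FALSE]
}

#' Validate and assemble the three seed sets
#'
#' Enforces the seed-set contract: the three sets must be pairwise disjoint
#' and their union a strict subset of the voxel grid. Coordinates occurring
#' in more than one set are removed from the lower-precedence set
#' (brain > nonbrain > background).
#'
#' @param brain,nonbrain,background Integer matrices of 0-based (i, j, k)
#'   coordinates.
#' @param shape The (M, N, L) grid dimensions.
#' @return An object of class \code{"seed_sets"}: a list with elements
#'   \code{brain}, \code{nonbrain}, \code{background} (coordinate matrices)
#'   and \code{shape}.
#' @export
validate_seed_sets <- function(brain, nonbrain, background, shape) {
  sets <- list(brain = unique_coords(brain), nonbrain = unique_coords(nonbrain),
               background = unique_coords(background))
  ids <- lapply(sets, function(s) {
    if (nrow(s) && !all(in_bounds(s, shape)))
      stop("seed coordinates out of bounds", call. = FALSE)
    coords_to_ids(s, shape)
  })
  ids$nonbrain <- setdiff(ids$nonbrain, ids$brain)
  ids$background <- setdiff(ids$background, c(ids$brain, ids$nonbrain))
  for (region in names(ids)) {
    if (length(ids[[region]]) == 0L)
      stop("seed set '", region, "' is empty after collision resolution",
           call. = FALSE)
  }
  if (length(ids$brain) + length(ids$nonbrain) + length(ids$background) >= prod(shape))
    stop("seed sets cover the whole grid; they must be a strict subset",
         call. = FALSE)
  structure(list(brain = ids_to_coords(ids$brain, shape),
                 nonbrain = ids_to_coords(ids$nonbrain, shape),
                 background = ids_to_coords(ids$background, shape),
                 shape = shape),
            class = "seed_sets")
}

#' @export
print.seed_sets <- function(x, ...) {
  cat(sprintf("Seed sets on a %s grid: %d brain (TB), %d non-brain (TNB), %d background (TBG)\n",
              paste(x$shape, collapse = "x"),
              nrow(x$brain), nrow(x$nonbrain), nrow(x$background)))
  invisible(x)
}

#' Write seed sets to CSV
#'
#' One row per seed with columns \code{region, i, j, k} (0-based), for
#' expert inspection or semi-automated reseeding.
#'
#' @param seeds A \code{seed_sets} object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_seed_sets <- function(seeds, path) {
  df <- do.call(rbind, lapply(c("brain", "nonbrain", "background"), function(r)
    data.frame(region = r, seeds[[r]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
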