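#' Graph-based brain segmentation of a 3D head volume
#'
#' Fits the full unsupervised segmentation: the preprocessed volume is turned
#' into a 6-connected voxel adjacency graph weighted by absolute intensity
#' differences; seed voxels sampled in the brain (TB), the non-brain head
#' tissue (TNB) and the background (TBG) are each collapsed onto a random
#' representative; the minimum spanning tree of the collapsed graph is cut
#' twice - first the heaviest edge on the path joining the brain and
#' non-brain representatives, then the heaviest edge on the path joining the
#' non-brain and background representatives - and the three resulting
#' components become the class labels (0 background, 1 non-brain, 2 brain).
#'
#' @param vol A 3D intensity array (raw, or already preprocessed if
#'   \code{preprocess = FALSE}).
#' @param selection_line Axis-0 index separating the superior head surface
#'   used for brain seeding; chosen by inspection for real data. Defaults to
#'   \code{floor(0.45 * M)}, a heuristic starting point only.
#' @param delta1 Brain pull distance in voxels (default 15, the value used
#'   with 128-voxel grids).
#' @param delta2 Non-brain pull distance in voxels (default 1). For volumes
#'   that are not thresholded, a larger \code{delta2} that reaches past the
#'   bright scalp/skull into the dark interface gives the cleanest cuts.
#' @param threshold Optional preprocessing threshold in \[0, 1); values below
#'   it are zeroed. \code{NULL} (default) skips thresholding.
#' @param target_shape Optional resize target, e.g. \code{c(128, 128, 128)};
#'   \code{NULL} keeps the input grid.
#' @param min_object_size Small-object removal cutoff (default 64 voxels).
#' @param distance_factor Centroid-distance filter factor for brain seeds
#'   (default 0.75).
#' @param n_background Number of background seeds (default 20000).
#' @param axes Axes for surface edge detection (default \code{0}).
#' @param direction Side of the selection line used for brain seeding
#'   (\code{"above"} = smaller axis-0 indices, the default).
#' @param seed Integer RNG seed controlling background sampling and the
#'   choice of representatives; fixed seed + fixed parameters give a
#'   bit-identical segmentation.
#' @param preprocess If \code{TRUE} (default) run the standard preprocessing
#'   chain first.
#' @param profile Optional named parameter profile (\code{"oasis"},
#'   \code{"ibsr"}, \code{"bw"}); explicit arguments win over the profile.
#' @return An object of class \code{"gubs"} with components \code{labels}
#'   (integer 3D array in \{0, 1, 2\}), \code{volume} (the preprocessed
#'   intensities), \code{seeds}, \code{representatives}, \code{cut_edges},
#'   \code{params} and \code{call}.
#' @examples
#' ph <- generate_phantom(shape = c(32, 32, 32), seed = 1)
#' fit <- gubs(ph$volume, selection_line = 14, delta1 = 4, delta2 = 1,
#'             n_background = 1000, seed = 1)
#' table(fit$labels)
#' @export
gubs <- function(vol, selection_line = NULL, delta1 = 15L, delta2 = 1L,
                 threshold = NULL, target_shape = NULL, min_object_size = 64L,
                 distance_factor = 0.75, n_background = 20000L, axes = 0L,
                 direction = "above", seed = 1L, preprocess = TRUE,
                 profile = NULL) {
  cl <- match.call()
  if (!is.null(profile)) {
    prof <- gubs_profile(profile)
    supplied <- names(cl)[-1L]
    for (p in names(prof)) if (!(p %in% supplied)) assign(p, prof[[p]])
  }
  check_volume(vol)
  set.seed(as.integer(seed))
  if (preprocess)
    vol <- preprocess_volume(vol, target_shape = target_shape,
                             threshold = threshold,
                             min_object_size = min_object_size)
  shape <- dim(vol)
  if (is.null(selection_line)) {
    selection_line <- floor(0.45 * shape[1L])
    message("selection_line not given; using heuristic ", selection_line,
            " (0.45 * M) - inspect the volume to place it properly")
  }

  closed <- fill_holes(binarize(vol))
  edges <- detect_edge_points(closed, axes = axes)
  tb <- sample_brain_points(edges, vol, selection_line, delta1,
                            distance_factor, direction)
  tnb <- sample_nonbrain_points(edges, vol, delta2)
  tbg <- sample_background_points(closed, n_background)
  seeds <- validate_seed_sets(tb, tnb, tbg, shape)

  g <- build_adjacency_graph(vol)
  vb_set <- coords_to_ids(seeds$brain, shape)
  vnb_set <- coords_to_ids(seeds$nonbrain, shape)
  vbg_set <- coords_to_ids(seeds$background, shape)
  reps <- c(brain = sample(vb_set, 1L), nonbrain = sample(vnb_set, 1L),
            background = sample(vbg_set, 1L))

  g <- collapse_nodes(g, vb_set, reps["brain"])
  g <- collapse_nodes(g, vnb_set, reps["nonbrain"])
  g <- collapse_nodes(g, vbg_set, reps["background"])

  tree <- minimum_spanning_tree(g)
  forest <- cut_max_edge(tree, reps["brain"], reps["nonbrain"])
  forest <- cut_max_edge(forest, reps["nonbrain"], reps["background"])

  labels <- labels_from_forest(forest, seeds, reps, shape)
  structure(list(labels = labels, volume = vol, seeds = seeds,
                 representatives = reps, cut_edges = forest$removed,
                 params = list(selection_line = selection_line,
                               delta1 = delta1, delta2 = delta2,
                               threshold = threshold,
                               target_shape = target_shape,
                               min_object_size = min_object_size,
                               distance_factor = distance_factor,
                               n_background = n_background, axes = axes,
                               direction = direction, seed = seed,
                               preprocess = preprocess),
                 call = cl),
            class = "gubs")
}

#' Reconstruct the label volume from a cut forest
#'
#' Assigns every voxel the class of the component containing it (brain 2,
#' non-brain 1, background 0, read off from the components holding the three
#' representatives) and gives the seed voxels that were collapsed away the
#' label of their representative, then reshapes to the input grid.
#'
#' @param forest A \code{cut_forest} with exactly three components.
#' @param seeds The validated \code{seed_sets}.
#' @param reps Named vector \code{c(brain=, nonbrain=, background=)} of
#'   representative node ids, each in a distinct component.
#' @param shape The (M, N, L) grid dimensions.
#' @return Integer 3D label array in \{0, 1, 2\}.
#' @export
labels_from_forest <- function(forest, seeds, reps, shape) {
  comp <- graph_components(forest)
  n_comp <- max(comp)
  if (n_comp != 3L)
    stop("expected exactly 3 components after the two cuts, found ", n_comp,
         call. = FALSE)
  rc <- comp[match(reps[c("brain", "nonbrain", "background")], forest$nodes)]
  if (anyDuplicated(rc))
    stop("representatives share a component; the cuts failed to separate the regions",
         call. = FALSE)
  class_of <- integer(3L)
  class_of[rc] <- c(2L, 1L, 0L)
  lab <- integer(prod(shape))
  lab[forest$nodes] <- class_of[comp]
  lab[coords_to_ids(seeds$brain, shape)] <- class_of[rc[1L]]
  lab[coords_to_ids(seeds$nonbrain, shape)] <- class_of[rc[2L]]
  lab[coords_to_ids(seeds$background, shape)] <- class_of[rc[3L]]
  array(lab, dim = shape)
}

#' Extract the binary brain mask from a fit
#'
#' @param fit A \code{gubs} object.
#' @return Logical 3D array, \code{TRUE} on brain voxels.
#' @export
brain_mask <- function(fit) {
  stopifnot(inherits(fit, "gubs"))
  fit$labels == 2L
}

#' @export
print.gubs <- function(x, ...) {
  sz <- tabulate(x$labels + 1L, nbins = 3L)
  cat("Graph-based brain segmentation\n")
  cat(sprintf("  grid: %s (%d voxels)\n", paste(dim(x$labels), collapse = "x"),
              length(x$labels)))
  cat(sprintf("  brain: %d  non-brain: %d  background: %d voxels\n",
              sz[3L], sz[2L], sz[1L]))
  cat(sprintf("  seeds: %d TB / %d TNB / %d TBG; cut edge weights: %s\n",
              nrow(x$seeds$brain), nrow(x$seeds$nonbrain),
              nrow(x$seeds$background),
              paste(signif(x$cut_edges$w, 4), collapse = ", ")))
  invisible(x)
}

#' Summarize a segmentation, optionally against a ground truth
#'
#' @param object A \code{gubs} object.
#' @param truth Optional ground-truth labels (3-class array or binary brain
#'   mask); when given, the six overlap metrics of the brain class are
#'   reported.
#' @param ... Unused.
#' @return A list of class \code{"summary.gubs"}.
#' @export
summary.gubs <- function(object, truth = NULL, ...) {
  sz <- tabulate(object$labels + 1L, nbins = 3L)
  out <- list(shape = dim(object$labels),
              class_voxels = c(background = sz[1L], nonbrain = sz[2L],
                               brain = sz[3L]),
              params = object$params, metrics = NULL)
  if (!is.null(truth))
    out$metrics <- evaluate_segmentation(object, truth)
  structure(out, class = "summary.gubs")
}

#' @export
print.summary.gubs <- function(x, ...) {
  cat("Segmentation summary (", paste(x$shape, collapse = "x"), " grid)\n",
      sep = "")
  print(x$class_voxels)
  cat(sprintf("selection line %s, delta1 %d, delta2 %d, threshold %s, seed %d\n",
              x$params$selection_line, x$params$delta1, x$params$delta2,
              if (is.null(x$params$threshold)) "none" else x$params$threshold,
              x$params$seed))
  if (!is.null(x$metrics)) {
    cat("overlap with ground truth (brain class):\n")
    print(x$metrics)
  }
  invisible(x)
}

#' Plot an axial/coronal/sagittal slice of a segmentation
#'
#' Shows the intensity slice with the segmentation labels alongside.
#'
#' @param x A \code{gubs} object.
#' @param slice Slice index along \code{axis} (1-based; default middle).
#' @param axis Axis (1, 2 or 3) to slice along (default 3).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, \code{x}.
#' @export
plot.gubs <- function(x, slice = NULL, axis = 3L, ...) {
  d <- dim(x$labels)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  pick <- function(a) switch(axis, a[slice, , ], a[, slice, ], a[, , slice])
  old <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  graphics::image(pick(x$volume), col = grey.colors(128, 0, 1),
                  main = "intensity", axes = FALSE, ...)
  graphics::image(pick(x$labels), zlim = c(0, 2),
                  col = c("black", "orange", "firebrick"),
                  main = "labels (bg / non-brain / brain)", axes = FALSE, ...)
  invisible(x)
}
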