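#' Read a 3D volume from disk
#'
#' Reads a T1-weighted head volume (or any 3D scalar grid) from NIfTI
#' (\code{.nii}, \code{.nii.gz}) or from a serialized R array (\code{.rds}).
#' Intensities are returned unmodified as a plain 3D array.
#'
#' @param path Path to an existing \code{.nii}, \code{.nii.gz} or \code{.rds}
#'   file containing a 3D array.
#' @return A numeric 3D array.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  vol <- if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    readRDS(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    unclass(as.array(RNifti::readNifti(path)))
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .rds): ", path,
         call. = FALSE)
  }
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("volume in ", path, " is not 3D (found ",
         paste(dim(vol), collapse = "x"), ")", call. = FALSE)
  storage.mode(vol) <- "double"
  vol
}

#' Write a 3D volume to disk
#'
#' @param vol A 3D array.
#' @param path Output path ending in \code{.nii}, \code{.nii.gz} or \code{.rds}.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  check_volume(vol)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(vol, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(vol), path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Resize a 3D volume to a target grid
#'
#' Resamples the volume onto a new grid using pixel-centre alignment.
#' Trilinear interpolation is the default for intensity volumes; it cannot
#' overshoot, so a volume scaled to \[0, 1\] stays in \[0, 1\]. Use
#' \code{method = "nearest"} for label volumes.
#'
#' @param vol A 3D array.
#' @param target_shape Integer triple of strictly positive output dimensions,
#'   e.g. \code{c(128, 128, 128)}.
#' @param method \code{"trilinear"} (default) or \code{"nearest"}.
#' @return A 3D array with \code{dim == target_shape}.
#' @export
resize_volume <- function(vol, target_shape, method = c("trilinear", "nearest")) {
  check_volume(vol)
  method <- match.arg(method)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(is.na(target_shape)) || any(target_shape < 1L))
    stop("`target_shape` must be three strictly positive integers", call. = FALSE)
  src <- dim(vol)
  if (identical(src, target_shape)) return(vol)

  # pixel-centre mapping: x_src = (x_tgt + 0.5) * src/tgt - 0.5, clamped
  ax <- lapply(1:3, function(a) {
    x <- (seq_len(target_shape[a]) - 0.5) * src[a] / target_shape[a] - 0.5
    x <- pmin(pmax(x, 0), src[a] - 1)
    if (method == "nearest") {
      i0 <- as.integer(round(x))
      list(i0 = i0, i1 = i0, f = rep(0, length(x)))
    } else {
      i0 <- pmin(as.integer(floor(x)), src[a] - 1L)
      list(i0 = i0, i1 = pmin(i0 + 1L, src[a] - 1L), f = x - i0)
    }
  })

  M <- target_shape[1L]; N <- target_shape[2L]; L <- target_shape[3L]
  gi <- rep.int(seq_len(M), N * L)
  gj <- rep.int(rep(seq_len(N), each = M), L)
  gk <- rep(seq_len(L), each = M * N)
  fi <- ax[[1]]$f[gi]; fj <- ax[[2]]$f[gj]; fk <- ax[[3]]$f[gk]

  corner <- function(ii, jj, kk) {
    vol[cbind(ii[gi] + 1L, jj[gj] + 1L, kk[gk] + 1L)]
  }
  i0 <- ax[[1]]$i0; i1 <- ax[[1]]$i1
  j0 <- ax[[2]]$i0; j1 <- ax[[2]]$i1
  k0 <- ax[[3]]$i0; k1 <- ax[[3]]$i1

  out <- corner(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk)
  if (method == "trilinear") {
    out <- out +
      corner(i1, j0, k0) * fi       * (1 - fj) * (1 - fk) +
      corner(i0, j1, k0) * (1 - fi) * fj       * (1 - fk) +
      corner(i0, j0, k1) * (1 - fi) * (1 - fj) * fk +
      corner(i1, j1, k0) * fi       * fj       * (1 - fk) +
      corner(i1, j0, k1) * fi       * (1 - fj) * fk +
      corner(i0, j1, k1) * (1 - fi) * fj       * fk +
      corner(i1, j1, k1) * fi       * fj       * fk
  }
  array(out, dim = target_shape)
}

#' Scale intensities to \[0, 1\] column-wise
#'
#' Min-max scaling applied independently to each axis-0 column: for every
#' (j, k) the column values \code{A[, j, k]} are mapped to
#' \code{(A - min) / (max - min)}. Columns whose range does not exceed
#' \code{near_constant_epsilon} (e.g. all-background columns) keep a divisor
#' of 1, so constants map to 0 rather than dividing by ~0.
#'
#' @param vol A 3D array.
#' @param near_constant_epsilon Ranges at or below this are treated as
#'   constant (default \code{1e-12}).
#' @return A 3D array with all values in \[0, 1\].
#' @export
scale_intensities <- function(vol, near_constant_epsilon = 1e-12) {
  check_volume(vol)
  shape <- dim(vol)
  m <- matrix(vol, nrow = shape[1L])        # columns are (j, k) pairs
  rng <- apply(m, 2L, range)
  scale <- rng[2L, ] - rng[1L, ]
  scale[scale <= near_constant_epsilon] <- 1
  out <- sweep(sweep(m, 2L, rng[1L, ], "-"), 2L, scale, "/")
  array(out, dim = shape)
}

#' Remove small connected components of the nonzero support
#'
#' Any 6-connected component of the nonzero voxels with fewer than
#' \code{min_object_size} voxels is set to 0. Used to clear speckle outside
#' the head so that the background is a single clean region.
#'
#' @param vol A 3D array.
#' @param min_object_size Components below this voxel count are removed
#'   (default 64).
#' @return A 3D array with small components zeroed.
#' @export
remove_small_objects <- function(vol, min_object_size = 64L) {
  check_volume(vol)
  min_object_size <- as.integer(min_object_size)
  if (is.na(min_object_size) || min_object_size < 1L)
    stop("`min_object_size` must be >= 1", call. = FALSE)
  lab <- label_components(vol != 0)
  if (length(lab$sizes) == 0L) return(vol)
  drop <- which(lab$sizes < min_object_size)
  if (length(drop)) vol[lab$labels %in% drop] <- 0
  vol
}

#' Zero out intensities below a threshold
#'
#' Sets all values strictly below \code{threshold} to 0, disconnecting the
#' brain from surrounding tissue across dark, thin interfaces. Intended for
#' volumes already scaled to \[0, 1\].
#'
#' @param vol A 3D array with values in \[0, 1\].
#' @param threshold Real in \[0, 1); values \code{< threshold} become 0.
#' @return The thresholded 3D array.
#' @export
apply_threshold <- function(vol, threshold) {
  check_volume(vol)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold >= 1)
    stop("`threshold` must be a single value in [0, 1)", call. = FALSE)
  vol[vol < threshold] <- 0
  vol
}

#' Standard preprocessing chain
#'
#' Applies, in order: resize (when \code{target_shape} is non-NULL),
#' column-wise intensity scaling, small-object removal, and optional
#' thresholding.
#'
#' @param vol A 3D array.
#' @param target_shape Integer triple or NULL to keep the input grid.
#' @param threshold Real in \[0, 1) or NULL to skip thresholding.
#' @param min_object_size Passed to [remove_small_objects()].
#' @param near_constant_epsilon Passed to [scale_intensities()].
#' @return The preprocessed 3D array.
#' @export
preprocess_volume <- function(vol, target_shape = NULL, threshold = NULL,
                              min_object_size = 64L,
                              near_constant_epsilon = 1e-12) {
  check_volume(vol)
  if (!is.null(target_shape)) vol <- resize_volume(vol, target_shape)
  vol <- scale_intensities(vol, near_constant_epsilon)
  vol <- remove_small_objects(vol, min_object_size)
  if (!is.null(threshold)) vol <- apply_threshold(vol, threshold)
  vol
}
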