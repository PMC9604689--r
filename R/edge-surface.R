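#' Binarize a volume
#'
#' Voxels with intensity strictly greater than zero become 1, all others 0.
#'
#' @param vol A 3D array.
#' @return A 3D integer array with values in \{0, 1\}.
#' @export
binarize <- function(vol) {
  check_volume(vol)
  out <- array(0L, dim = dim(vol))
  out[vol > 0] <- 1L
  out
}

# Shift a logical 3D array by one voxel along `axis` in direction `dir`,
# padding with `fill`.
shift_mask <- function(mask, axis, dir, fill) {
  d <- dim(mask)
  out <- array(fill, dim = d)
  src <- dst <- list(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]))
  n <- d[axis]
  if (n < 2L) return(out)
  if (dir > 0L) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1L) }
  else          { dst[[axis]] <- 1:(n - 1L); src[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# 3D dilation/erosion with the full 3x3x3 structuring element.
dilate3 <- function(mask) {
  acc <- mask
  for (axis in 1:3) {
    acc <- acc | shift_mask(acc, axis, +1L, FALSE) | shift_mask(acc, axis, -1L, FALSE)
  }
  acc
}

erode3 <- function(mask) {
  acc <- mask
  for (axis in 1:3) {
    acc <- acc & shift_mask(acc, axis, +1L, TRUE) & shift_mask(acc, axis, -1L, TRUE)
  }
  acc
}

#' Fill holes in a binary volume
#'
#' Binary closing (3x3x3 structuring element) followed by interior-cavity
#' filling: any background component not reachable from the volume boundary
#' by 6-connected background steps is set to foreground. The original
#' foreground is never shrunk.
#'
#' @param binary A 3D array with values in \{0, 1\} (or logical).
#' @return A 3D integer array in \{0, 1\} with enclosed cavities filled.
#' @export
fill_holes <- function(binary) {
  check_volume(binary)
  mask <- binary > 0
  closed <- erode3(dilate3(mask)) | mask          # closing, never shrinking
  # cavity filling: background components that do not touch the boundary
  lab <- label_components(!closed)
  if (length(lab$sizes)) {
    d <- dim(closed)
    boundary <- unique(c(
      lab$labels[c(1L, d[1L]), , ], lab$labels[, c(1L, d[2L]), ],
      lab$labels[, , c(1L, d[3L])]))
    interior <- setdiff(seq_along(lab$sizes), boundary)
    if (length(interior)) closed[lab$labels %in% interior] <- TRUE
  }
  out <- array(0L, dim = dim(closed))
  out[closed] <- 1L
  out
}

#' Detect discrete 3D edge-like points of a binary volume
#'
#' Computes the forward difference \eqn{\epsilon = B(x') - B(x)} between
#' consecutive voxels along each requested axis and records a point wherever
#' \eqn{\epsilon = \pm 1}. The recorded coordinate is the foreground-side
#' voxel of each transition (the voxel with value 1), together with the
#' detection axis and the sign of the difference, so downstream sampling can
#' pull each point inward unambiguously.
#'
#' @param binary A 3D array with values in \{0, 1\}.
#' @param axes Integer subset of \code{c(0, 1, 2)}; axes along which the
#'   forward difference is taken (default \code{0}, the axis the selection
#'   line is defined on).
#' @return An object of class \code{"edge_points"}: a data frame with
#'   0-based columns \code{i, j, k}, plus \code{axis} (0/1/2) and
#'   \code{sign} (+1/-1), carrying the source shape as an attribute.
#' @export
detect_edge_points <- function(binary, axes = 0L) {
  check_volume(binary)
  axes <- sort(unique(as.integer(axes)))
  if (length(axes) == 0L || any(is.na(axes)) || any(axes < 0L | axes > 2L))
    stop("`axes` must be a non-empty subset of {0, 1, 2}", call. = FALSE)
  shape <- dim(binary)
  pieces <- vector("list", length(axes))
  for (n in seq_along(axes)) {
    a <- axes[n]
    d <- shape[a + 1L]
    if (d < 2L) { pieces[[n]] <- NULL; next }
    lo <- hi <- list(seq_len(shape[1L]), seq_len(shape[2L]), seq_len(shape[3L]))
    lo[[a + 1L]] <- 1:(d - 1L); hi[[a + 1L]] <- 2:d
    eps <- binary[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] -
      binary[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    hit <- which(eps != 0L)
    if (length(hit) == 0L) { pieces[[n]] <- NULL; next }
    dd <- shape; dd[a + 1L] <- d - 1L
    co <- arrayInd(hit, dd) - 1L                 # 0-based, at first voxel of pair
    sg <- as.integer(eps[hit])
    # foreground-side voxel: forward neighbour when the step enters foreground
    co[, a + 1L] <- co[, a + 1L] + as.integer(sg == 1L)
    pieces[[n]] <- data.frame(i = co[, 1L], j = co[, 2L], k = co[, 3L],
                              axis = a, sign = sg)
  }
  pts <- do.call(rbind, pieces)
  if (is.null(pts))
    pts <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      axis = integer(0), sign = integer(0))
  rownames(pts) <- NULL
  structure(pts, source_shape = shape, class = c("edge_points", "data.frame"))
}

#' @export
print.edge_points <- function(x, ...) {
  cat(sprintf("Edge points: %d transitions on a %s grid (axes: %s)\n",
              nrow(x), paste(attr(x, "source_shape"), collapse = "x"),
              paste(sort(unique(x$axis)), collapse = ", ")))
  invisible(x)
}
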