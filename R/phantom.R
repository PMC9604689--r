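#' Generate a synthetic concentric head phantom with ground truth
#'
#' Builds the simplest geometry that exercises every stage of the pipeline:
#' a medium-bright spherical brain core, a dark thin shell around it (the
#' CSF/dura analog that connects brain to skull in real heads), a bright
#' thin outer shell (scalp/skull analog) and exactly-zero background.
#' Optional Gaussian noise is added to the tissue voxels (the background
#' stays zero) and clipped to \[0, 1\]. Ground-truth labels are 0
#' background, 1 non-brain (gap plus shell), 2 brain.
#'
#' @param shape Integer triple of grid dimensions (default \code{c(64, 64, 64)}).
#' @param brain_radius_frac Brain core radius as a fraction of half the
#'   smallest dimension (default 0.8; brains fill most of the skull).
#' @param gap_thickness Thickness in voxels of the dark interface
#'   (default 1).
#' @param shell_thickness Thickness in voxels of the bright outer shell
#'   (default 1).
#' @param intensities Named numeric vector of tissue means,
#'   \code{c(background = 0, gap = 0.15, brain = 0.55, shell = 0.9)};
#'   requires \code{0 < gap < brain <= 1} and \code{0 < shell <= 1}.
#' @param noise_sigma Standard deviation of additive Gaussian tissue noise
#'   (default 0).
#' @param ellipticity Length-3 axis stretch factors for an ellipsoidal
#'   variant (default \code{c(1, 1, 1)}, spherical).
#' @param seed Optional RNG seed used when \code{noise_sigma > 0}.
#' @return An object of class \code{"gubs_phantom"}: a list with
#'   \code{volume} (numeric 3D array), \code{labels} (integer 3D array in
#'   \{0, 1, 2\}) and \code{params}.
#' @examples
#' ph <- generate_phantom(shape = c(32, 32, 32))
#' table(ph$labels)
#' @export
generate_phantom <- function(shape = c(64L, 64L, 64L), brain_radius_frac = 0.8,
                             gap_thickness = 1, shell_thickness = 1,
                             intensities = c(background = 0, gap = 0.15,
                                             brain = 0.55, shell = 0.9),
                             noise_sigma = 0, ellipticity = c(1, 1, 1),
                             seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("`shape` must be three dimensions of at least 8 voxels", call. = FALSE)
  need <- c("background", "gap", "brain", "shell")
  if (!all(need %in% names(intensities)))
    stop("`intensities` must name background, gap, brain and shell", call. = FALSE)
  iz <- intensities[need]
  if (!(iz["gap"] > 0 && iz["gap"] < iz["brain"] && iz["brain"] <= 1 &&
        iz["shell"] > 0 && iz["shell"] <= 1))
    stop("intensity means must satisfy 0 < gap < brain <= 1 and 0 < shell <= 1",
         call. = FALSE)
  if (gap_thickness < 1 || shell_thickness < 1)
    stop("gap and shell must be at least one voxel thick", call. = FALSE)

  r_brain <- brain_radius_frac * min(shape) / 2
  r_gap <- r_brain + gap_thickness
  r_shell <- r_gap + shell_thickness
  if (r_shell >= min(shape / ellipticity) / 2 - 0.5)
    stop("radii exceed the volume: shrink `brain_radius_frac` or the shells",
         call. = FALSE)

  ctr <- (shape - 1) / 2
  di <- ((seq_len(shape[1L]) - 1 - ctr[1L]) / ellipticity[1L])^2
  dj <- ((seq_len(shape[2L]) - 1 - ctr[2L]) / ellipticity[2L])^2
  dk <- ((seq_len(shape[3L]) - 1 - ctr[3L]) / ellipticity[3L])^2
  d <- sqrt(outer(outer(di, dj, "+"), dk, "+"))

  labels <- array(0L, dim = shape)
  labels[d < r_shell] <- 1L
  labels[d < r_brain] <- 2L

  vol <- array(iz["background"], dim = shape)
  vol[d < r_shell] <- iz["shell"]
  vol[d < r_gap] <- iz["gap"]
  vol[d < r_brain] <- iz["brain"]

  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    tissue <- labels > 0L
    vol[tissue] <- pmin(pmax(vol[tissue] +
                               stats::rnorm(sum(tissue), 0, noise_sigma), 0), 1)
  }

  structure(list(volume = vol, labels = labels,
                 params = list(shape = shape,
                               brain_radius_frac = brain_radius_frac,
                               gap_thickness = gap_thickness,
                               shell_thickness = shell_thickness,
                               intensities = iz, noise_sigma = noise_sigma,
                               ellipticity = ellipticity, seed = seed,
                               r_brain = r_brain, r_gap = r_gap,
                               r_shell = r_shell)),
            class = "gubs_phantom")
}

#' @export
print.gubs_phantom <- function(x, ...) {
  p <- x$params
  cat(sprintf("Head phantom %s: core r=%.1f, gap %.0f vox, shell %.0f vox, noise sigma %.3g\n",
              paste(p$shape, collapse = "x"), p$r_brain, p$gap_thickness,
              p$shell_thickness, p$noise_sigma))
  invisible(x)
}

#' Write a phantom and its ground truth as a NIfTI pair
#'
#' @param phantom A \code{gubs_phantom}.
#' @param volume_path,labels_path Output NIfTI paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_phantom <- function(phantom, volume_path, labels_path) {
  write_volume(phantom$volume, volume_path)
  write_volume(phantom$labels + 0, labels_path)
  invisible(c(volume_path, labels_path))
}
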