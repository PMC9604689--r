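#' Named parameter profiles for common cohorts
#'
#' Returns the parameter set tuned for the three public T1-weighted cohorts
#' the method was developed on, at the standard 128-cube working grid:
#' \describe{
#'   \item{oasis}{threshold 0.32, selection line 60, delta1 15, delta2 1}
#'   \item{ibsr}{threshold 0.25, selection line 65, delta1 15, delta2 1}
#'   \item{bw}{no threshold (good tissue contrast), selection line 35,
#'     delta1 15, delta2 3}
#' }
#' All profiles resize to 128x128x128 and use 20000 background seeds.
#'
#' @param name One of \code{"oasis"}, \code{"ibsr"}, \code{"bw"}.
#' @return Named list of [gubs()] arguments.
#' @export
gubs_profile <- function(name) {
  base <- list(target_shape = c(128L, 128L, 128L), delta1 = 15L,
               n_background = 20000L)
  prof <- switch(tolower(name),
    oasis = list(threshold = 0.32, selection_line = 60L, delta2 = 1L),
    ibsr = list(threshold = 0.25, selection_line = 65L, delta2 = 1L),
    bw = list(threshold = NULL, selection_line = 35L, delta2 = 3L),
    stop("unknown profile '", name, "' (expected oasis, ibsr or bw)",
         call. = FALSE))
  utils::modifyList(base, prof, keep.null = TRUE)
}
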