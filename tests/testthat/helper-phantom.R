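# Shared phantom fixtures and the segmentation parameters matched to them.
# The 64-cube phantom is the standard test subject; parameters are the
# 64-grid analogues of the published 128-grid settings (selection line just
# under half the axis extent, pull distances halved).

phantom64 <- function(noise_sigma = 0, seed = NULL) {
  generate_phantom(shape = c(64L, 64L, 64L), noise_sigma = noise_sigma,
                   seed = seed)
}

gubs_fit64 <- function(vol, seed = 7L) {
  gubs(vol, selection_line = 29L, delta1 = 8L, delta2 = 1L,
       n_background = 5000L, seed = seed)
}

phantom32 <- function(noise_sigma = 0, seed = NULL) {
  generate_phantom(shape = c(32L, 32L, 32L), noise_sigma = noise_sigma,
                   seed = seed)
}

gubs_fit32 <- function(vol, seed = 7L) {
  gubs(vol, selection_line = 14L, delta1 = 4L, delta2 = 1L,
       n_background = 1000L, seed = seed)
}
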