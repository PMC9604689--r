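test_that("brain sampling pulls inward, applies the 0.75 distance filter, and handles singletons", {
  ph <- phantom32()
  closed <- fill_holes(binarize(ph$volume))
  ep <- detect_edge_points(closed, axes = 0L)

  tb <- sample_brain_points(ep, ph$volume, selection_line = 14, delta1 = 4)
  pulled_all <- tb                                   # returned survivors
  centroid_all <- NULL
  # recompute the filter independently: pull candidates by hand
  cand <- ep[ep$i < 14, ]
  co <- cbind(cand$i, cand$j, cand$k)
  co[cbind(seq_len(nrow(co)), cand$axis + 1L)] <-
    co[cbind(seq_len(nrow(co)), cand$axis + 1L)] + cand$sign * 4L
  inb <- co[, 1] >= 0 & co[, 1] < 32 & co[, 2] >= 0 & co[, 2] < 32 &
    co[, 3] >= 0 & co[, 3] < 32
  co <- co[inb, , drop = FALSE]
  ctr <- colMeans(co)
  d <- sqrt(rowSums((co - rep(ctr, each = nrow(co)))^2))
  keep <- unique(co[d <= 0.75 * max(d), , drop = FALSE])
  expect_equal(nrow(tb), nrow(keep))
  expect_true(all(sqrt(rowSums((tb - rep(ctr, each = nrow(tb)))^2)) <=
                    0.75 * max(d) + 1e-9))

  # singleton candidate set: the single point survives (distance 0)
  one <- ep[ep$i < 14, ][1, , drop = FALSE]
  attr(one, "source_shape") <- attr(ep, "source_shape")
  tb1 <- sample_brain_points(one, ph$volume, selection_line = 14, delta1 = 4)
  expect_equal(nrow(tb1), 1L)
  expect_equal(unname(tb1[1, one$axis + 1L] - c(one$i, one$j, one$k)[one$axis + 1L]),
               one$sign * 4L)

  expect_error(sample_brain_points(ep, ph$volume, selection_line = 0, delta1 = 4),
               "no edge points")
})

test_that("non-brain sampling removes zero-intensity landings and errors on empty input", {
  ph <- phantom32()
  closed <- fill_holes(binarize(ph$volume))
  ep <- detect_edge_points(closed, axes = 0L)
  tnb <- sample_nonbrain_points(ep, ph$volume, delta2 = 1)
  expect_true(all(ph$volume[tnb + 1L] != 0))
  # on the phantom every survivor sits in non-brain tissue (shell or gap)
  expect_true(all(ph$labels[tnb + 1L] == 1L))

  # a volume where every pull lands on zero: two-slab binary with empty middle
  vol <- array(0, dim = c(8, 8, 8))
  vol[c(1, 8), , ] <- 1
  bin <- binarize(vol)
  ep2 <- detect_edge_points(bin, axes = 0L)
  expect_error(sample_nonbrain_points(ep2, vol, delta2 = 1), "zero intensity")

  empty <- detect_edge_points(array(1L, c(4, 4, 4)), axes = 0L)
  expect_error(sample_nonbrain_points(empty, vol, delta2 = 1), "no edge points")
})

test_that("background sampling draws distinct zero voxels, reproducibly, and truncates small pools", {
  ph <- phantom32()
  closed <- fill_holes(binarize(ph$volume))

  set.seed(99)
  bg <- sample_background_points(closed, n_background = 2000)
  expect_equal(nrow(bg), 2000L)
  expect_equal(nrow(unique(bg)), 2000L)
  expect_true(all(closed[bg + 1L] == 0L))

  set.seed(99)
  bg2 <- sample_background_points(closed, n_background = 2000)
  expect_identical(bg, bg2)

  tiny <- array(1L, dim = c(4, 4, 4))
  tiny[c(1, 5, 9, 33, 62)] <- 0L
  out <- sample_background_points(tiny, n_background = 2000)
  expect_equal(nrow(out), 5L)
  expect_error(sample_background_points(array(1L, c(3, 3, 3)), 10), "no zero voxels")
})

test_that("background inclusion frequency is uniform across the pool", {
  closed <- array(1L, dim = c(6, 6, 6))
  closed[1:3, , ] <- 0L     # 108-voxel pool
  n_draw <- 30L; n_rep <- 400L
  hits <- numeric(6^3)
  for (s in seq_len(n_rep)) {
    set.seed(s)
    bg <- sample_background_points(closed, n_background = n_draw)
    ids <- bg[, 1] + bg[, 2] * 6 + bg[, 3] * 36 + 1
    hits[ids] <- hits[ids] + 1
  }
  p <- n_draw / 108
  freq <- hits[closed == 0L] / n_rep
  # binomial standard error with a generous 5-sigma band
  expect_true(all(abs(freq - p) < 5 * sqrt(p * (1 - p) / n_rep)))
  expect_true(all(hits[closed == 1L] == 0))
})

test_that("seed-set validation enforces disjointness with brain > nonbrain > background precedence", {
  shape <- c(6L, 6L, 6L)
  brain <- rbind(c(1, 1, 1), c(2, 2, 2))
  nonbrain <- rbind(c(3, 3, 3), c(2, 2, 2))     # collides with brain
  background <- rbind(c(0, 0, 0), c(3, 3, 3))   # collides with nonbrain
  ss <- validate_seed_sets(brain, nonbrain, background, shape)
  expect_equal(nrow(ss$brain), 2L)
  expect_equal(ss$nonbrain, matrix(c(3L, 3L, 3L), 1, dimnames = list(NULL, c("i", "j", "k"))))
  expect_equal(ss$background, matrix(c(0L, 0L, 0L), 1, dimnames = list(NULL, c("i", "j", "k"))))

  # disjoint sets come back unchanged (up to deduplication)
  ss2 <- validate_seed_sets(brain, rbind(c(4, 4, 4)), rbind(c(5, 5, 5)), shape)
  expect_equal(nrow(ss2$brain) + nrow(ss2$nonbrain) + nrow(ss2$background), 4L)

  # a set emptied by collision resolution is an error naming the region
  expect_error(validate_seed_sets(brain, rbind(c(1, 1, 1)), background, shape),
               "nonbrain")

  # covering the whole grid violates strict inclusion
  all_co <- as.matrix(expand.grid(i = 0:5, j = 0:5, k = 0:5))
  expect_error(validate_seed_sets(all_co[1:2, ], all_co[3:4, ], all_co[-(1:4), ],
                                  shape), "strict subset")
})

test_that("seed CSV export writes one row per seed with region labels", {
  ss <- validate_seed_sets(rbind(c(1, 1, 1)), rbind(c(2, 2, 2)),
                           rbind(c(0, 0, 0), c(3, 3, 3)), c(5L, 5L, 5L))
  f <- tempfile(fileext = ".csv")
  write_seed_sets(ss, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 4L)
  expect_equal(sort(unique(df$region)), c("background", "brain", "nonbrain"))
})
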