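test_that("voxel adjacency graph has the grid node/edge counts and intensity-difference weights", {
  vol <- array(runif(8), dim = c(2, 2, 2))
  g <- build_adjacency_graph(vol)
  expect_equal(length(g$nodes), 8L)
  expect_equal(length(g$u), 12L)          # 3MNL - MN - NL - ML = 24 - 12

  M <- 3; N <- 4; L <- 5
  g2 <- build_adjacency_graph(array(runif(M * N * L), dim = c(M, N, L)))
  expect_equal(length(g2$u), 3 * M * N * L - M * N - N * L - M * L)
  # every edge joins voxels at squared distance 1
  cu <- arrayInd(g2$u, c(M, N, L)); cv <- arrayInd(g2$v, c(M, N, L))
  expect_true(all(rowSums((cu - cv)^2) == 1))

  const <- build_adjacency_graph(array(0.4, dim = c(3, 3, 3)))
  expect_true(all(const$w == 0))
})

test_that("a 2x1x1-style pair yields a single edge of weight |difference|", {
  # use a 2x2x1-extended grid and check the axis-0 pair weight directly
  vol <- array(c(0.2, 0.7, 0.2, 0.7), dim = c(2, 2, 1))
  expect_error(build_adjacency_graph(vol), "dimension")
  vol3 <- array(c(0.2, 0.7), dim = c(2, 1, 1))
  expect_error(build_adjacency_graph(vol3), "dimension")
  g <- weighted_graph(u = 1L, v = 2L, w = abs(0.2 - 0.7))
  expect_equal(g$w, 0.5)
})

test_that("collapse reproduces the hand-traced triangle and path cases", {
  # triangle a-b (1), b-c (2), a-c (3); collapse {a,b} onto a
  tri <- weighted_graph(u = c(1L, 2L, 1L), v = c(2L, 3L, 3L), w = c(1, 2, 3))
  col <- collapse_nodes(tri, H = c(1L, 2L), h = 1L)
  expect_equal(col$nodes, c(1L, 3L))
  expect_equal(length(col$u), 1L)
  expect_equal(col$w, 2)                       # min of the parallel pair {2, 3}
  expect_true(all(col$u != col$v))

  # path u-v-x, H = {u, v}, h = u: v's edge re-homed to u
  pth <- weighted_graph(u = c(1L, 2L), v = c(2L, 3L), w = c(0.5, 0.8))
  col2 <- collapse_nodes(pth, H = c(1L, 2L), h = 1L)
  expect_equal(col2$nodes, c(1L, 3L))
  expect_equal(cbind(col2$u, col2$v, col2$w), cbind(1, 3, 0.8))

  # singleton collapse is the identity (up to edge ordering)
  col3 <- collapse_nodes(tri, H = 2L, h = 2L)
  expect_equal(col3$nodes, tri$nodes)
  o1 <- order(col3$u, col3$v); o2 <- order(tri$u, tri$v)
  expect_equal(cbind(col3$u, col3$v, col3$w)[o1, ],
               cbind(tri$u, tri$v, tri$w)[o2, ])

  expect_error(collapse_nodes(tri, H = c(1L, 2L), h = 3L), "member")
})

test_that("collapse node count, self-loop absence and MST invariance hold on random graphs", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:7, 1)
    e <- random_connected_graph(n, extra = 4L)
    g <- weighted_graph(e$u, e$v, e$w, nodes = 1:n)
    H <- sample(1:n, sample(2:3, 1))
    col <- collapse_nodes(g, H, H[1])
    expect_equal(length(col$nodes), n - length(H) + 1L)
    expect_true(all(col$u != col$v))
    expect_true(all(!duplicated(paste(col$u, col$v))))
  }
})

test_that("MST matches the triangle case and brute-force enumeration on random graphs", {
  tri <- weighted_graph(u = c(1L, 2L, 1L), v = c(2L, 3L, 3L), w = c(1, 2, 3))
  t <- minimum_spanning_tree(tri)
  expect_s3_class(t, "spanning_tree")
  expect_equal(sort(t$w), c(1, 2))
  expect_equal(length(t$u), 2L)

  eq <- weighted_graph(u = c(1L, 2L, 3L, 1L), v = c(2L, 3L, 4L, 4L),
                       w = rep(0.7, 4))
  te <- minimum_spanning_tree(eq)
  expect_equal(sum(te$w), 3 * 0.7)

  set.seed(31)
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    e <- random_connected_graph(n, extra = 4L)
    g <- weighted_graph(e$u, e$v, e$w, nodes = 1:n)
    t <- minimum_spanning_tree(g)
    expect_equal(length(t$u), n - 1L)
    expect_equal(sum(t$w), enumerate_mst_weight(e, n))
  }

  disc <- weighted_graph(u = 1L, v = 2L, w = 1, nodes = 1:3)
  expect_error(minimum_spanning_tree(disc), "disconnected")
})

test_that("tree paths agree with a BFS oracle and handle endpoints", {
  pth <- minimum_spanning_tree(weighted_graph(u = c(1L, 2L), v = c(2L, 3L),
                                              w = c(1, 1)))
  expect_equal(tree_path(pth, 1L, 3L), c(1L, 2L, 3L))
  expect_equal(tree_path(pth, 1L, 1L), integer(0))
  expect_error(tree_path(pth, 1L, 9L), "nodes of the tree")

  set.seed(41)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    e <- random_tree_edges(n)
    t <- minimum_spanning_tree(weighted_graph(e$u, e$v, e$w, nodes = 1:n))
    ends <- sample(1:n, 2)
    expect_equal(tree_path(t, ends[1], ends[2]),
                 bfs_path(e, n, ends[1], ends[2]))
  }
})

test_that("cut_max_edge removes the heaviest path edge with the u-side tie-break", {
  # chain a-b (0.1), b-c (0.9), c-d (0.3)
  chain <- minimum_spanning_tree(weighted_graph(u = c(1L, 2L, 3L),
                                                v = c(2L, 3L, 4L),
                                                w = c(0.1, 0.9, 0.3)))
  f <- cut_max_edge(chain, 1L, 4L)
  expect_s3_class(f, "cut_forest")
  expect_equal(f$removed$w, 0.9)
  comp <- graph_components(f)
  expect_equal(comp[["1"]], comp[["2"]])
  expect_equal(comp[["3"]], comp[["4"]])
  expect_false(comp[["1"]] == comp[["4"]])

  # equal maxima: the edge nearer the first argument is removed
  tie <- minimum_spanning_tree(weighted_graph(u = c(1L, 2L, 3L),
                                              v = c(2L, 3L, 4L),
                                              w = c(0.5, 0.2, 0.5)))
  f1 <- cut_max_edge(tie, 1L, 4L)
  expect_equal(unlist(f1$removed[c("u", "v")], use.names = FALSE), c(1L, 2L))
  f2 <- cut_max_edge(tie, 4L, 1L)
  expect_equal(unlist(f2$removed[c("u", "v")], use.names = FALSE), c(3L, 4L))

  # cutting already-separated endpoints errors
  expect_error(cut_max_edge(f, 1L, 4L), "different components")
})

test_that("min-weight parallel-edge reduction preserves MST total weight versus a multigraph oracle", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    base <- random_connected_graph(n, extra = 2L)
    # duplicate a few edges with different weights to force parallels
    dup <- base[sample(nrow(base), 2), ]
    dup$w <- round(stats::runif(2, 0.1, 5), 2)
    multi <- rbind(base, dup)
    # reduction route: singleton collapse triggers parallel-edge reduction
    g <- weighted_graph(multi$u, multi$v, multi$w, nodes = 1:n)
    red <- collapse_nodes(g, H = 1L, h = 1L)
    expect_true(all(!duplicated(paste(red$u, red$v))))
    t <- minimum_spanning_tree(red)
    expect_equal(sum(t$w), enumerate_mst_weight(multi, n))
  }
})
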