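# Independent oracles used to cross-check the implementation. These are
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the package internals.

# ---- graph oracles ---------------------------------------------------------

# union-find used only inside the enumeration oracle
uf_new <- function(n) seq_len(n)
uf_find <- function(p, x) { while (p[x] != x) x <- p[x]; x }

# is the edge subset `sel` (rows of edges) a spanning tree of nodes 1..n?
is_spanning_tree <- function(edges, sel, n) {
  if (length(sel) != n - 1L) return(FALSE)
  p <- uf_new(n)
  for (r in sel) {
    a <- uf_find(p, edges$u[r]); b <- uf_find(p, edges$v[r])
    if (a == b) return(FALSE)
    p[a] <- b
  }
  TRUE
}

# minimum spanning tree total weight by exhaustive enumeration over all
# (n-1)-subsets of the edge list; works on multigraphs as-is.
enumerate_mst_weight <- function(edges, n) {
  m <- nrow(edges)
  best <- Inf
  for (sel in utils::combn(m, n - 1L, simplify = FALSE)) {
    if (is_spanning_tree(edges, sel, n)) best <- min(best, sum(edges$w[sel]))
  }
  best
}

# random connected simple graph on n nodes (random tree + extra edges)
random_connected_graph <- function(n, extra = 3L) {
  u <- integer(0); v <- integer(0)
  for (i in 2:n) { u <- c(u, sample.int(i - 1L, 1L)); v <- c(v, i) }
  for (e in seq_len(extra)) {
    cand <- sample.int(n, 2L)
    a <- min(cand); b <- max(cand)
    if (!any(u == a & v == b)) { u <- c(u, a); v <- c(v, b) }
  }
  data.frame(u = u, v = v, w = round(stats::runif(length(u), 0.1, 5), 2))
}

# random tree on n nodes with random weights
random_tree_edges <- function(n) {
  u <- integer(0); v <- integer(0)
  for (i in 2:n) { u <- c(u, sample.int(i - 1L, 1L)); v <- c(v, i) }
  data.frame(u = u, v = v, w = stats::runif(n - 1L))
}

# breadth-first-search path between u and v on an undirected edge list
bfs_path <- function(edges, n, from, to) {
  if (from == to) return(integer(0))
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$u[r]; b <- edges$v[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  prev <- rep(NA_integer_, n)
  queue <- from; seen <- rep(FALSE, n); seen[from] <- TRUE
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    if (x == to) break
    for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; prev[y] <- x; queue <- c(queue, y) }
  }
  if (!seen[to]) return(NULL)
  path <- to
  while (path[1L] != from) path <- c(prev[path[1L]], path)
  path
}

# ---- volume oracles --------------------------------------------------------

# pure-R flood fill labelling of the nonzero support, 6-connectivity
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      co <- arrayInd(x, d)
      for (axis in 1:3) for (s in c(-1L, 1L)) {
        nb <- co; nb[axis] <- nb[axis] + s
        if (nb[axis] < 1L || nb[axis] > d[axis]) next
        id <- nb[1L] + (nb[2L] - 1L) * d[1L] + (nb[3L] - 1L) * d[1L] * d[2L]
        if (mask[id] && lab[id] == 0L) { lab[id] <- cur; stack <- c(stack, id) }
      }
    }
  }
  lab
}

# exhaustive scan of 6-adjacent (foreground, background) pairs along the
# requested axes; returns the transition count
pair_scan_count <- function(binary, axes = 0:2) {
  d <- dim(binary)
  count <- 0L
  for (a in axes) {
    ax <- a + 1L
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
      co <- c(i, j, k)
      if (co[ax] == d[ax]) next
      nb <- co; nb[ax] <- nb[ax] + 1L
      if (binary[co[1L], co[2L], co[3L]] != binary[nb[1L], nb[2L], nb[3L]])
        count <- count + 1L
    }
  }
  count
}
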