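# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation, kept separate from the package's own algorithms.

# exact transportation LP via boot::simplex (two-phase dense simplex);
# the redundant last demand constraint is dropped to keep the system
# full-rank
lp_transport_oracle <- function(p, q, C) {
  n <- length(p)
  A1 <- matrix(0, n, n * n)
  A2 <- matrix(0, n, n * n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    v <- (j - 1L) * n + i
    A1[i, v] <- 1
    A2[j, v] <- 1
  }
  A <- rbind(A1, A2)[-(2L * n), , drop = FALSE]
  sol <- boot::simplex(a = as.vector(C), A3 = A, b3 = c(p, q)[-(2L * n)],
                       maxi = FALSE)
  unname(sol$value)
}

# 1-D closed form on a unit-edge path: sum over edges of |CDF difference|
cdf_path_emd <- function(p, q) {
  sum(abs(cumsum(p - q)[-length(p)]))
}

# seeded random connected graph with unit edge lengths; returns the
# shortest-path matrix
random_connected_metric <- function(n, p_edge = 0.6) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::components(g)$no == 1L) break
  }
  igraph::distances(g)
}

# brute-force all-simple-paths shortest distance (independent of igraph's
# Dijkstra); edge lengths in `len` matrix, Inf where no edge
brute_shortest <- function(len) {
  n <- nrow(len)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  recurse <- function(path, acc) {
    u <- path[length(path)]
    s <- path[1L]
    if (acc < best[s, u]) best[s, u] <<- acc
    for (v in seq_len(n)) {
      if (is.finite(len[u, v]) && !(v %in% path))
        recurse(c(path, v), acc + len[u, v])
    }
  }
  for (s in seq_len(n)) recurse(s, 0)
  best
}

# connected components of the threshold graph d <= t
threshold_components_oracle <- function(points, t) {
  n <- nrow(points)
  if (n == 0L) return(list())
  D <- as.matrix(stats::dist(points))
  adj <- D <= t
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  grp <- igraph::components(gr)$membership
  unname(split(rownames(points), grp))
}

# stationary distribution by long power iteration
power_stationary <- function(P, iters = 10000L) {
  x <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) x <- as.vector(x %*% P)
  x
}

# literal two-step normalization of the adapted diffusion kernel
adapted_markov_oracle <- function(W) {
  D <- diag(1 / rowSums(W))
  Wt <- D %*% W %*% D
  Dt <- diag(1 / rowSums(Wt))
  Dt %*% Wt
}

# canonical partition string for comparing clusterings
canon_partition <- function(cl) {
  paste(sort(vapply(cl, function(x) paste(sort(x), collapse = ","), "")),
        collapse = ";")
}

# ARI between two labelings given as named vectors
ari_of <- function(pred, truth) {
  mclust::adjustedRandIndex(pred[names(truth)], truth)
}

# plain numeric matrix of an expr_matrix (drops class and scale attribute)
vals <- function(m) {
  a <- unclass(m)
  attr(a, "scale") <- NULL
  a
}

# random points on a seeded circle
circle_points <- function(n, seed) {
  set.seed(seed)
  th <- stats::runif(n, 0, 2 * pi)
  pts <- cbind(cos(th), sin(th))
  rownames(pts) <- sprintf("p%03d", seq_len(n))
  pts
}
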