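#' Per-component node distributions of a sample
#'
#' Interprets a sample's non-negative expression vector as probability mass
#' over the network's nodes, separately for each connected component (mass
#' cannot flow between components). Two constructions are available:
#' `density` divides each component's values (plus pseudocount) by their sum;
#' `invariant_measure` takes the stationary distribution of an
#' expression-attracted random walk on the component, where a walker at node
#' u steps to neighbor v with probability proportional to the target's
#' value, (x_v + pseudocount) / sum over neighbors w of (x_w + pseudocount).
#' The walk is made lazy (self-loop probability 1/2) so bipartite components
#' still have a unique stationary distribution.
#'
#' @param sample_values named non-negative numeric vector; names must all be
#'   network genes. Network genes absent from the vector carry mass 0.
#' @param g a [gene_network()].
#' @param mode `"density"` or `"invariant_measure"`.
#' @param pseudocount non-negative value added to every node before
#'   normalization; the escape hatch for all-zero components.
#' @param on_empty `"error"` (default) aborts on a component whose total
#'   mass is zero with pseudocount 0; `"flag"` marks it empty instead (an
#'   empty component compares as 0 against another empty component and is
#'   incomparable with a non-empty one).
#' @return A `node_distribution`: list with `masses` (per-component vectors
#'   summing to 1) and `empty` (per-component logical).
#' @export
to_distribution <- function(sample_values, g,
                            mode = c("density", "invariant_measure"),
                            pseudocount = 0, on_empty = c("error", "flag")) {
  mode <- match.arg(mode)
  on_empty <- match.arg(on_empty)
  stopifnot(is_gene_network(g))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (any(sample_values < 0) || any(!is.finite(sample_values)))
    stop("sample values must be finite and non-negative")
  nm <- names(sample_values)
  if (is.null(nm)) stop("sample values must be named by gene")
  extra <- setdiff(nm, network_nodes(g))
  if (length(extra))
    stop("sample has genes not in the network: ", paste(extra, collapse = ", "))
  x <- stats::setNames(numeric(length(network_nodes(g))), network_nodes(g))
  x[nm] <- sample_values
  comps <- network_components(g)
  masses <- vector("list", length(comps))
  empty <- logical(length(comps))
  for (k in seq_along(comps)) {
    genes <- comps[[k]]
    xk <- x[genes] + pseudocount
    if (sum(xk) == 0) {
      if (on_empty == "error")
        stop(if (mode == "density") "empty component distribution"
             else "walk undefined", " (component ", k,
             " has zero total mass and pseudocount 0)")
      empty[k] <- TRUE
      masses[[k]] <- stats::setNames(rep(NA_real_, length(genes)), genes)
      next
    }
    if (mode == "density" || length(genes) == 1L) {
      masses[[k]] <- xk / sum(xk)
    } else {
      masses[[k]] <- stationary_walk(xk, igraph::induced_subgraph(g$graph, genes))
    }
  }
  structure(list(masses = masses, empty = empty), class = "node_distribution")
}

# stationary distribution of the lazy expression-attracted walk on one
# connected component; xk already includes the pseudocount
stationary_walk <- function(xk, sub) {
  genes <- names(xk)
  A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)[genes, genes]
  P <- A * rep(xk, each = length(xk))     # P[u, v] propto A[u, v] * x[v]
  rs <- rowSums(P)
  if (any(rs == 0))
    stop("walk undefined (a node's whole neighborhood has zero mass)")
  P <- P / rs
  P <- 0.5 * diag(length(xk)) + 0.5 * P   # lazy: kills bipartite periodicity
  # left eigenvector: solve pi (P - I) = 0 with sum(pi) = 1
  M <- rbind(t(P) - diag(length(xk)), rep(1, length(xk)))
  pi_ <- qr.solve(M, c(rep(0, length(xk)), 1))
  pi_[pi_ < 0 & pi_ > -1e-12] <- 0
  stats::setNames(pi_ / sum(pi_), genes)
}

#' Earth Mover's Distance between two mass distributions on one component
#'
#' Solves the transportation problem min sum T_ij ground_ij subject to
#' rowSums(T) = p, colSums(T) = q, T >= 0, by successive shortest augmenting
#' paths with node potentials on the bipartite supply/demand network (exact
#' min-cost flow). Mass common to p and q is cancelled first, which is
#' optimal whenever `ground` is a metric (zero diagonal, triangle
#' inequality), as shortest-path ground metrics always are.
#'
#' @param p,q non-negative mass vectors of equal length summing to the same
#'   total (tolerance 1e-6); probability vectors in normal use.
#' @param ground square matrix of pairwise node distances.
#' @return The optimal transport cost (non-negative scalar).
#' @export
emd_component <- function(p, q, ground) {
  p <- as.numeric(p); q <- as.numeric(q)
  ground <- as.matrix(ground)
  n <- length(p)
  if (length(q) != n || nrow(ground) != n || ncol(ground) != n)
    stop("p, q and ground have inconsistent sizes")
  if (any(p < 0) || any(q < 0)) stop("negative mass")
  if (any(!is.finite(p)) || any(!is.finite(q)) || any(!is.finite(ground)))
    stop("masses and ground distances must be finite")
  if (abs(sum(p) - sum(q)) > 1e-6)
    stop("total masses differ: ", sum(p), " vs ", sum(q))
  common <- pmin(p, q)
  a <- p - common
  b <- q - common
  si <- which(a > 0)
  di <- which(b > 0)
  if (!length(si) || !length(di)) return(0)
  ssp_transport(a[si], b[di], ground[si, di, drop = FALSE])
}

# successive shortest paths with potentials on the dense bipartite
# transportation network; a, b strictly positive, sum(a) == sum(b)
ssp_transport <- function(a, b, C) {
  ns <- length(a); nd <- length(b)
  N <- ns + nd
  X <- matrix(0, ns, nd)
  phi <- numeric(N)
  arem <- a; brem <- b
  tol <- max(sum(a), 1) * 1e-13
  guard <- 0L
  while (sum(arem) > tol) {
    guard <- guard + 1L
    if (guard > 4L * N * N) stop("transport solver failed to converge")
    dist <- rep(Inf, N); pred <- rep(NA_integer_, N); done <- rep(FALSE, N)
    dist[which(arem > tol)] <- 0
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      if (u <= ns) {
        v <- ns + seq_len(nd)
        rc <- C[u, ] + phi[u] - phi[v]        # reduced cost, >= 0 invariant
        nd2 <- dist[u] + pmax(rc, 0)
        upd <- !done[v] & nd2 < dist[v]
        dist[v[upd]] <- nd2[upd]; pred[v[upd]] <- u
      } else {
        j <- u - ns
        has <- which(X[, j] > tol)
        if (length(has)) {
          rc <- -C[has, j] + phi[u] - phi[has]
          nd2 <- dist[u] + pmax(rc, 0)
          upd <- !done[has] & nd2 < dist[has]
          dist[has[upd]] <- nd2[upd]; pred[has[upd]] <- u
        }
      }
    }
    targets <- which(brem > tol)
    t <- targets[which.min(dist[ns + targets])] + ns
    if (!is.finite(dist[t])) stop("transport infeasible (disconnected instance)")
    phi <- phi + pmin(dist, dist[t])
    # trace path and find bottleneck
    path <- t; u <- t
    while (!is.na(pred[u])) { u <- pred[u]; path <- c(u, path) }
    delta <- min(arem[path[1L]], brem[t - ns])
    if (length(path) > 2L)
      for (k in seq(2L, length(path) - 1L, by = 2L))   # demand->supply backward arcs
        delta <- min(delta, X[path[k + 1L], path[k] - ns])
    for (k in seq(1L, length(path) - 1L, by = 2L)) {
      i <- path[k]; j <- path[k + 1L] - ns
      X[i, j] <- X[i, j] + delta
      if (k + 2L <= length(path)) {
        i2 <- path[k + 2L]
        X[i2, j] <- X[i2, j] - delta
      }
    }
    arem[path[1L]] <- arem[path[1L]] - delta
    brem[t - ns] <- brem[t - ns] - delta
  }
  sum(X * C)
}

#' Quantized Hungarian cross-check of the transport cost
#'
#' Discretizes both distributions into K equal mass units (largest-remainder
#' rounding) and solves the resulting K x K assignment problem with the
#' Hungarian algorithm. Converges to [emd_component()] as K grows; intended
#' for validation, not production use.
#'
#' @inheritParams emd_component
#' @param K number of mass units.
#' @return Approximate transport cost.
#' @export
emd_hungarian <- function(p, q, ground, K = 200L) {
  if (!requireNamespace("clue", quietly = TRUE))
    stop("emd_hungarian needs the 'clue' package")
  quantize <- function(w) {
    w <- w / sum(w)
    base <- floor(w * K)
    rem <- w * K - base
    short <- K - sum(base)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      base[add] <- base[add] + 1L
    }
    rep(seq_along(w), base)
  }
  ip <- quantize(p); iq <- quantize(q)
  cost <- as.matrix(ground)[ip, iq, drop = FALSE]
  sol <- clue::solve_LSAP(cost)
  sum(cost[cbind(seq_len(K), sol)]) / K
}

#' Wasserstein sample distance with direct-sum amalgamation
#'
#' Combines per-component Earth Mover's Distances into one sample-to-sample
#' distance as the root sum of squares sqrt(sum_c d_c^2). Components empty
#' in both samples contribute 0; a component empty in exactly one sample is
#' incomparable.
#'
#' @param a,b `node_distribution`s over the same network.
#' @param ground a [ground_metric()] for that network.
#' @return Non-negative scalar distance.
#' @export
sample_distance <- function(a, b, ground) {
  if (length(a$masses) != length(b$masses) || length(a$masses) != length(ground))
    stop("distributions and ground metric have different component structure")
  total <- 0
  for (k in seq_along(ground)) {
    if (a$empty[k] && b$empty[k]) next
    if (xor(a$empty[k], b$empty[k]))
      stop("incomparable supports (component ", k, " empty in exactly one sample)")
    total <- total + emd_component(a$masses[[k]], b$masses[[k]], ground[[k]])^2
  }
  sqrt(total)
}

#' Pairwise Wasserstein distance matrix among samples
#'
#' Converts every sample of a raw-scale expression matrix into
#' per-component node distributions and computes all pairwise direct-sum
#' Wasserstein-1 distances. Each unordered pair is solved once; the matrix
#' is symmetric with a zero diagonal by construction.
#'
#' @param m raw-scale [expr_matrix()] whose genes all belong to `g`.
#' @param g a [gene_network()].
#' @inheritParams to_distribution
#' @return A `sample_dist`: symmetric numeric matrix with sample ids as
#'   dimnames.
#' @export
distance_matrix <- function(m, g, mode = c("density", "invariant_measure"),
                            pseudocount = 0) {
  mode <- match.arg(mode)
  stopifnot(is_expr_matrix(m), is_gene_network(g))
  if (expr_scale(m) != "raw")
    stop("distance_matrix consumes raw non-negative values, not z-scores")
  gm <- ground_metric(g)
  samples <- colnames(m)
  dists <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    dists[[s]] <- tryCatch(
      to_distribution(unclass(m)[, s], g, mode = mode, pseudocount = pseudocount),
      error = function(e) stop("sample '", samples[s], "': ", conditionMessage(e),
                               call. = FALSE))
  }
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(samples, samples))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        D[i, j] <- D[j, i] <- sample_distance(dists[[i]], dists[[j]], gm)
      }
    }
  }
  structure(D, class = c("sample_dist", "matrix", "array"))
}

#' @export
print.sample_dist <- function(x, ...) {
  cat(sprintf("<sample_dist> %d samples; range [%.4g, %.4g]\n",
              nrow(x), min(x), max(x)))
  invisible(x)
}

#' Read/write a sample distance matrix as TSV
#'
#' Sample ids appear as both the header row and the first column.
#'
#' @param D a `sample_dist` matrix.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  out <- cbind(sample = rownames(D),
               format(unclass(D), digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  rownames(D) <- df[[1L]]
  storage.mode(D) <- "double"
  structure(D, class = c("sample_dist", "matrix", "array"))
}
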