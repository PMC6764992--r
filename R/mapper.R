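#' Nearest-neighbor closeness-centrality filter
#'
#' Builds the symmetrized k-nearest-neighbor graph of the embedded points
#' with Euclidean edge lengths and returns per-point closeness centrality
#' f(i) = (N - 1) / sum_j d_graph(i, j). Central points of the cloud score
#' high, peripheral points low, making this a good general-purpose Mapper
#' filter when no control cohort or progression variable is available.
#'
#' @param points numeric matrix, samples in rows (e.g. diffusion
#'   coordinates), rownames = sample ids.
#' @param k neighbor count, `1 <= k < N`.
#' @return A `filter_values` numeric vector named by sample, with a
#'   `provenance` attribute.
#' @export
centrality_filter <- function(points, k = 5L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < number of points")
  D <- as.matrix(stats::dist(points))
  if (all(D[upper.tri(D)] == 0)) stop("degenerate metric: all points coincide")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)                     # symmetrize: union of kNN relations
  W <- ifelse(adj, D, 0)
  gr <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  dg <- igraph::distances(gr)
  if (any(!is.finite(dg)))
    stop("k-nearest-neighbor graph is disconnected; increase k")
  f <- (n - 1) / rowSums(dg)
  names(f) <- rownames(points)
  structure(f, provenance = "centrality", class = "filter_values")
}

#' Smallest k whose symmetrized k-nearest-neighbor graph is connected
#'
#' Closeness centrality needs finite graph distances, i.e. a connected
#' neighbor graph; this returns the minimal k achieving that, the
#' parameter-free default for [centrality_filter()].
#'
#' @param points samples x M coordinate matrix.
#' @return Integer k, `1 <= k < N`.
#' @export
connected_knn_k <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  for (k in seq_len(n - 1L)) {
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- seq_len(n)[-i][order(D[i, -i])[seq_len(k)]]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(gr)$no == 1L) return(k)
  }
  n - 1L
}

#' Mahalanobis deviation-from-control filter
#'
#' Distance of each sample from the control cohort's mean, scaled by the
#' control covariance: f(s) = sqrt((s - mu_C)' Sigma_C^-1 (s - mu_C)).
#' Suitable when the control set is large relative to the embedding
#' dimension; an optional ridge stabilizes a near-singular covariance.
#'
#' @param points samples x M coordinate matrix.
#' @param control control samples x M coordinate matrix, more rows than
#'   M + 1.
#' @param ridge non-negative value added to the covariance diagonal.
#' @return A `filter_values` vector.
#' @export
mahalanobis_filter <- function(points, control, ridge = 0) {
  points <- as.matrix(points); control <- as.matrix(control)
  M <- ncol(points)
  if (ncol(control) != M) stop("points and control must share dimension")
  if (nrow(control) <= M + 1L)
    stop("control cohort too small relative to the embedding dimension")
  mu <- colMeans(control)
  nc <- nrow(control)
  # population (1/n) covariance, matching the package's sigma convention
  S <- stats::cov(control) * (nc - 1) / nc + diag(ridge, M)
  if (rcond_ok(S) < 1e-12)
    stop("singular control covariance; supply a positive ridge")
  f <- sqrt(stats::mahalanobis(points, mu, S))
  names(f) <- rownames(points)
  structure(f, provenance = "mahalanobis", class = "filter_values")
}

rcond_ok <- function(S) {
  tryCatch(1 / kappa(S, exact = TRUE), error = function(e) 0)
}

#' Wrap user-supplied filter values
#'
#' @param f named finite numeric vector (e.g. an experimentally determined
#'   degree of progression).
#' @return A `filter_values` vector with provenance `"user"`.
#' @export
user_filter <- function(f) {
  if (is.null(names(f)) || any(!is.finite(f)))
    stop("filter values must be finite and named by sample")
  structure(as.numeric(stats::setNames(f, names(f))), names = names(f),
            provenance = "user", class = "filter_values")
}

#' Overlapping interval cover of the filter range
#'
#' Splits \[min f, max f\] into `n_f` base intervals of width
#' l = range / n_f and widens each by g*l/2 on both sides (clipped to the
#' full range), so consecutive intervals overlap by fraction `g` of the
#' base width. Membership is closed on both ends; with g < 1 every point
#' falls in one or two intervals.
#'
#' @param f a `filter_values` vector.
#' @param n_f number of bins, >= 1.
#' @param g overlap fraction in \[0, 1).
#' @return A `mapper_cover`: data.frame with columns `bin`, `lo`, `hi`.
#' @export
build_cover <- function(f, n_f, g = 0.5) {
  if (n_f < 1L) stop("n_f must be >= 1")
  if (g < 0 || g >= 1) stop("overlap fraction g must lie in [0, 1)")
  lo <- min(f); hi <- max(f)
  if (lo == hi && n_f > 1L) stop("filter has no range")
  l <- (hi - lo) / n_f
  i <- seq_len(n_f) - 1L
  cover <- data.frame(bin = i,
                      lo = pmax(lo + i * l - g * l / 2, lo),
                      hi = pmin(lo + (i + 1L) * l + g * l / 2, hi))
  if (n_f == 1L) { cover$lo <- lo; cover$hi <- hi }
  structure(cover, class = c("mapper_cover", "data.frame"))
}

#' Single-linkage clustering of one slice
#'
#' Cuts the single-linkage dendrogram on Euclidean distances at height `t`;
#' equivalently, the clusters are the connected components of the graph
#' joining points at distance <= t.
#'
#' @param points coordinate matrix of the slice's samples (rownames = ids).
#' @param t positive linkage threshold.
#' @return List of character vectors of sample ids (deterministic order);
#'   empty slice gives an empty list.
#' @export
slice_cluster <- function(points, t) {
  if (t <= 0) stop("threshold t must be positive")
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(list())
  ids <- rownames(points)
  if (n == 1L) return(list(ids))
  hc <- stats::hclust(stats::dist(points), method = "single")
  # cutree at height t keeps merges with height <= t (closed boundary)
  grp <- stats::cutree(hc, h = t)
  unname(split(ids, grp))
}

#' Nerve of the per-slice clusterings
#'
#' One node per slice-cluster; an edge joins clusters from distinct bins
#' sharing at least `min_overlap` samples; optionally records 2-simplices
#' for triples of clusters with a common sample.
#'
#' @param clusters list over bins; each element a list of character vectors
#'   of sample ids (as from [slice_cluster()]).
#' @param f a `filter_values` vector (for per-node mean filter values).
#' @param min_overlap minimum shared-sample count for an edge.
#' @param triangles record 2-simplices for triple overlaps.
#' @return A `mapper_complex`: list with `nodes` (data.frame: id, bin,
#'   size, mean_filter), `members` (list of sample-id vectors), `edges`
#'   (data.frame: from, to, overlap), optionally `triangles`.
#' @export
nerve <- function(clusters, f = NULL, min_overlap = 1L, triangles = FALSE) {
  nodes <- list(); members <- list()
  for (b in seq_along(clusters)) {
    for (cl in clusters[[b]]) {
      members[[length(members) + 1L]] <- cl
      nodes[[length(nodes) + 1L]] <-
        data.frame(bin = b - 1L, size = length(cl),
                   mean_filter = if (is.null(f)) NA_real_ else mean(f[cl]))
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes)
           else data.frame(bin = integer(), size = integer(),
                           mean_filter = numeric())
  nodes <- cbind(id = seq_len(nrow(nodes)), nodes)
  edges <- data.frame(from = integer(), to = integer(), overlap = integer())
  tri <- list()
  nn <- nrow(nodes)
  if (nn > 1L) {
    for (i in seq_len(nn - 1L)) {
      for (j in seq(i + 1L, nn)) {
        if (nodes$bin[i] == nodes$bin[j]) next
        ov <- length(intersect(members[[i]], members[[j]]))
        if (ov >= min_overlap)
          edges <- rbind(edges, data.frame(from = i, to = j, overlap = ov))
      }
    }
    if (triangles && nrow(edges) >= 3L) {
      for (i in seq_len(nn - 2L)) for (j in seq(i + 1L, nn - 1L)) for (k in seq(j + 1L, nn)) {
        common <- Reduce(intersect, members[c(i, j, k)])
        pairs_ok <- has_edge(edges, i, j) && has_edge(edges, j, k) &&
          has_edge(edges, i, k)
        if (length(common) >= min_overlap && pairs_ok)
          tri[[length(tri) + 1L]] <- c(i, j, k)
      }
    }
  }
  structure(list(nodes = nodes, members = members, edges = edges,
                 triangles = tri), class = "mapper_complex")
}

has_edge <- function(edges, a, b) {
  any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
}

#' @export
print.mapper_complex <- function(x, ...) {
  cat(sprintf("<mapper_complex> %d nodes, %d edges across %d bins\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$bin))))
  invisible(x)
}

#' Run the Mapper algorithm
#'
#' Slices the point cloud by the filter function with an overlapping
#' interval cover, single-linkage clusters each slice at threshold `t`, and
#' builds the nerve of the resulting clusters.
#'
#' @param points samples x M coordinate matrix, rownames = sample ids.
#' @param f a `filter_values` vector covering all samples.
#' @param n_f number of filter bins.
#' @param g overlap fraction in \[0, 1).
#' @param t single-linkage threshold.
#' @param min_overlap minimum shared samples for a nerve edge.
#' @param triangles record 2-simplices.
#' @return A `mapper_complex` (with the cover attached as attribute
#'   `cover`).
#' @export
mapper <- function(points, f, n_f, g = 0.5, t, min_overlap = 1L,
                   triangles = FALSE) {
  points <- as.matrix(points)
  ids <- rownames(points)
  if (is.null(ids)) stop("points must have sample ids as rownames")
  if (!all(ids %in% names(f))) stop("every sample needs a filter value")
  fv <- f[ids]
  cover <- build_cover(fv, n_f, g)
  clusters <- lapply(seq_len(nrow(cover)), function(b) {
    inb <- ids[fv >= cover$lo[b] & fv <= cover$hi[b]]
    slice_cluster(points[inb, , drop = FALSE], t)
  })
  out <- nerve(clusters, f = fv, min_overlap = min_overlap,
               triangles = triangles)
  attr(out, "cover") <- cover
  out
}

#' Serialize a Mapper complex as JSON or GraphML
#'
#' @param cx a `mapper_complex`.
#' @param path output path.
#' @export
write_mapper_json <- function(cx, path) {
  obj <- list(
    nodes = lapply(seq_len(nrow(cx$nodes)), function(i) list(
      id = cx$nodes$id[i], bin = cx$nodes$bin[i], size = cx$nodes$size[i],
      mean_filter = cx$nodes$mean_filter[i], samples = cx$members[[i]])),
    edges = cx$edges,
    triangles = cx$triangles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapper_json
#' @export
write_mapper_graphml <- function(cx, path) {
  gr <- mapper_igraph(cx)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

# 1-skeleton as an igraph object; vertex names are node ids as characters
mapper_igraph <- function(cx) {
  gr <- igraph::make_empty_graph(n = nrow(cx$nodes), directed = FALSE)
  igraph::V(gr)$name <- as.character(cx$nodes$id)
  igraph::V(gr)$size <- cx$nodes$size
  igraph::V(gr)$bin <- cx$nodes$bin
  if (nrow(cx$edges))
    gr <- igraph::add_edges(gr, rbind(cx$edges$from, cx$edges$to))
  gr
}
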