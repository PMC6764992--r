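#' Decompose a Mapper 1-skeleton into linear paths
#'
#' Nodes of degree >= 3 (branch points) and isolated nodes are breakpoints.
#' The edge set is split into maximal simple paths whose interior nodes
#' have degree 2; components that are pure cycles (every node degree 2) are
#' cut at their smallest node id and recorded with a cycle flag. Paths are
#' ordered by total sample count descending — the largest is the "core",
#' the rest branches — with ties broken by smallest node id, so the
#' decomposition is deterministic.
#'
#' @param cx a `mapper_complex`.
#' @return A `state_graph`: list with `nodes`, `members`, `edges` (from the
#'   complex), `branch_nodes` (ids of degree >= 3), `paths` (list of
#'   ordered node-id vectors), `is_cycle` (per path), `degree`.
#' @export
decompose_paths <- function(cx) {
  n <- nrow(cx$nodes)
  deg <- integer(n)
  adj <- vector("list", n)
  ne <- nrow(cx$edges)
  cx$edges$from <- as.integer(cx$edges$from)
  cx$edges$to <- as.integer(cx$edges$to)
  for (e in seq_len(ne)) {
    a <- cx$edges$from[e]; b <- cx$edges$to[e]
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  used <- rep(FALSE, ne)
  paths <- list(); is_cycle <- logical()
  breakpoint <- deg != 2L
  # walk chains out of every breakpoint endpoint
  for (v in which(breakpoint & deg > 0L)) {
    for (r in seq_len(nrow(adj[[v]]))) {
      e <- adj[[v]][r, 2L]
      if (used[e]) next
      path <- v; u <- adj[[v]][r, 1L]; used[e] <- TRUE; path <- c(path, u)
      while (!breakpoint[u]) {
        nxt <- adj[[u]][!used[adj[[u]][, 2L]], , drop = FALSE]
        if (!nrow(nxt)) break                 # closed back into the chain
        used[nxt[1L, 2L]] <- TRUE
        u <- nxt[1L, 1L]
        path <- c(path, u)
      }
      paths[[length(paths) + 1L]] <- path
      is_cycle <- c(is_cycle, FALSE)
    }
  }
  # remaining edges form pure cycles; cut each at its smallest node id
  while (any(!used)) {
    e0 <- which(!used)[1L]
    # collect the cycle's nodes
    comp <- unique(c(cx$edges$from[e0], cx$edges$to[e0]))
    repeat {
      grow <- unique(c(cx$edges$from[!used], cx$edges$to[!used]))
      touch <- (cx$edges$from %in% comp | cx$edges$to %in% comp) & !used
      newn <- unique(c(comp, cx$edges$from[touch], cx$edges$to[touch]))
      if (length(newn) == length(comp)) break
      comp <- newn
    }
    start <- min(comp)
    path <- start; u <- start
    repeat {
      nxt <- adj[[u]][!used[adj[[u]][, 2L]], , drop = FALSE]
      if (!nrow(nxt)) break
      used[nxt[1L, 2L]] <- TRUE
      u <- nxt[1L, 1L]
      path <- c(path, u)
    }
    paths[[length(paths) + 1L]] <- path       # closes as [start, ..., start]
    is_cycle <- c(is_cycle, TRUE)
  }
  # isolated nodes become single-node paths so all nodes are covered
  covered <- unique(unlist(paths))
  for (v in setdiff(seq_len(n), covered)) {
    paths[[length(paths) + 1L]] <- v
    is_cycle <- c(is_cycle, FALSE)
  }
  # deterministic ordering: total sample count desc, then smallest node id
  if (length(paths)) {
    sizes <- vapply(paths, function(p)
      length(unique(unlist(cx$members[unique(p)]))), 0L)
    minid <- vapply(paths, min, 0)
    o <- order(-sizes, minid)
    paths <- paths[o]; is_cycle <- is_cycle[o]
  }
  structure(list(nodes = cx$nodes, members = cx$members, edges = cx$edges,
                 branch_nodes = which(deg >= 3L), paths = paths,
                 is_cycle = is_cycle, degree = deg),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("<state_graph> %d nodes, %d edges, %d path(s), %d branch node(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$paths),
              length(x$branch_nodes)))
  invisible(x)
}

#' Order samples along the concatenated linear paths
#'
#' Walks the paths in their stored order and each path's nodes in order;
#' within a node, samples are sorted ascending by filter value (ties by
#' sample id). A sample appearing in several nodes is emitted at its first
#' occurrence only, so every sample appears exactly once.
#'
#' @param sg a `state_graph`.
#' @param f a `filter_values` vector covering all samples.
#' @return Character vector of sample ids.
#' @export
order_samples <- function(sg, f) {
  seen <- character(); out <- character()
  for (p in sg$paths) {
    for (v in p) {
      ids <- sg$members[[v]]
      if (any(!ids %in% names(f))) stop("every sample needs a filter value")
      ids <- ids[order(f[ids], ids)]
      ids <- ids[!ids %in% seen]
      out <- c(out, ids)
      seen <- c(seen, ids)
    }
  }
  out
}

#' Display matrices permuted to the state-graph sample order
#'
#' Produces, with rows/columns permuted to `sample_order`: the expression
#' matrix, the Wasserstein distance matrix, the Euclidean distance matrix
#' of the diffusion embedding, and (when discrete covariates are supplied)
#' the per-gene point-biserial correlation with each covariate level.
#'
#' @param m normalized-scale [expr_matrix()].
#' @param sample_order character vector (from [order_samples()]).
#' @param D `sample_dist` Wasserstein matrix.
#' @param E `diffusion_map` embedding.
#' @param covariates optional factor or character vector named by sample.
#' @return List with elements `expression`, `wasserstein`,
#'   `embedding_dist`, and optionally `covariate_cor`.
#' @export
heatmap_matrices <- function(m, sample_order, D, E, covariates = NULL) {
  stopifnot(is_expr_matrix(m))
  samples <- colnames(m)
  if (!setequal(sample_order, samples) ||
      !setequal(rownames(D), samples) ||
      !setequal(rownames(E$coordinates), samples))
    stop("mismatched sample sets across inputs")
  ed <- as.matrix(stats::dist(E$coordinates))
  out <- list(
    expression = unclass(m)[, sample_order, drop = FALSE],
    wasserstein = unclass(D)[sample_order, sample_order],
    embedding_dist = ed[sample_order, sample_order])
  if (!is.null(covariates)) {
    cv <- factor(covariates[sample_order])
    cc <- sapply(levels(cv), function(lv)
      apply(out$expression, 1L, function(x) {
        ind <- as.numeric(cv == lv)
        if (stats::sd(x) == 0 || stats::sd(ind) == 0) 0
        else stats::cor(x, ind)
      }))
    out$covariate_cor <- cc
  }
  out
}

#' Group samples by maximal path of the state graph
#'
#' The default grouping for state calling: one group per linear path, with
#' a sample that occurs in several paths assigned to the first (largest)
#' one. Per-path filter extremes are attached as attribute `extremes`.
#'
#' @param sg a `state_graph`.
#' @param f optional `filter_values` for the extremes metadata.
#' @return Named list of sample-id vectors (`path1`, `path2`, ...).
#' @export
path_groups <- function(sg, f = NULL) {
  seen <- character(); groups <- list()
  for (k in seq_along(sg$paths)) {
    ids <- unique(unlist(sg$members[unique(sg$paths[[k]])]))
    ids <- setdiff(ids, seen)
    if (length(ids)) {
      groups[[paste0("path", length(groups) + 1L)]] <- ids
      seen <- c(seen, ids)
    }
  }
  if (!is.null(f)) {
    attr(groups, "extremes") <- lapply(groups, function(ids)
      c(low = ids[which.min(f[ids])], high = ids[which.max(f[ids])]))
  }
  groups
}

#' Call activated / inactivated / equivocal genes per state
#'
#' For each sample group and gene, computes the mean normalized expression
#' v and calls the gene activated if v >= 0.5 + delta, inactivated if
#' v <= 0.5 - delta, and equivocal otherwise — an approximate
#' dichotomization of the 0-1 expression scale. The default delta = 1/6
#' corresponds to half a raw standard deviation under the
#' (x - mu)/(3 sigma) + 0.5 normalization.
#'
#' @param m normalized-scale [expr_matrix()].
#' @param groups named list of non-empty sample-id vectors.
#' @param delta decision threshold in (0, 0.5).
#' @return A `coherent_states` data.frame: `state`, `gene`, `call`, `mean`.
#' @export
call_states <- function(m, groups, delta = 1 / 6) {
  stopifnot(is_expr_matrix(m))
  if (expr_scale(m) != "normalized")
    stop("call_states expects a normalized-scale matrix")
  if (delta <= 0 || delta >= 0.5) stop("delta must lie in (0, 0.5)")
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a non-empty named list")
  res <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (!length(ids)) stop("empty group: ", g)
    if (any(!ids %in% colnames(m))) stop("unknown sample in group ", g)
    v <- rowMeans(unclass(m)[, ids, drop = FALSE])
    call <- ifelse(v >= 0.5 + delta, "activated",
                   ifelse(v <= 0.5 - delta, "inactivated", "equivocal"))
    res[[g]] <- data.frame(state = g, gene = rownames(m), call = call,
                           mean = unname(v), row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("coherent_states", "data.frame"))
}

#' Serialize a state graph
#'
#' JSON carries nodes (with sample lists), edges, branch nodes and the path
#' decomposition; GraphML carries the 1-skeleton for viewers.
#'
#' @param sg a `state_graph`.
#' @param path output path.
#' @export
write_stategraph_json <- function(sg, path) {
  obj <- list(
    nodes = lapply(seq_len(nrow(sg$nodes)), function(i) list(
      id = sg$nodes$id[i], bin = sg$nodes$bin[i], size = sg$nodes$size[i],
      mean_filter = sg$nodes$mean_filter[i], degree = sg$degree[i],
      samples = sg$members[[i]])),
    edges = sg$edges,
    branch_nodes = sg$branch_nodes,
    paths = sg$paths,
    is_cycle = sg$is_cycle)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stategraph_json
#' @export
write_stategraph_graphml <- function(sg, path) {
  write_mapper_graphml(sg, path)
}
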