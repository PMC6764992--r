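# build a minimal mapper_complex by hand
mk_complex <- function(members, bins, edges) {
  nodes <- data.frame(id = seq_along(members), bin = bins,
                      size = lengths(members),
                      mean_filter = NA_real_)
  structure(list(nodes = nodes, members = members,
                 edges = if (nrow(edges)) cbind(edges, overlap = 1L)
                         else data.frame(from = integer(), to = integer(),
                                         overlap = integer())),
            class = "mapper_complex")
}

edge_df <- function(...) {
  v <- c(...)
  if (!length(v)) return(data.frame(from = integer(), to = integer()))
  m <- matrix(as.integer(v), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2])
}

test_that("a path graph decomposes into a single path", {
  cx <- mk_complex(list("a", "b", "c"), 0:2, edge_df(1, 2, 2, 3))
  sg <- decompose_paths(cx)
  expect_length(sg$paths, 1L)
  expect_true(identical(sg$paths[[1]], c(1L, 2L, 3L)) ||
              identical(sg$paths[[1]], c(3L, 2L, 1L)))
  expect_length(sg$branch_nodes, 0L)
})

test_that("a Y-graph splits at the degree-3 node", {
  cx <- mk_complex(list(c("a", "x"), "b", c("c", "y"), "d", "e"),
                   c(0, 1, 2, 3, 3),
                   edge_df(1, 2, 2, 3, 3, 4, 3, 5))
  sg <- decompose_paths(cx)
  expect_equal(sg$branch_nodes, 3L)
  expect_length(sg$paths, 3L)
  sizes <- lapply(sg$paths, sort)
  expect_true(any(vapply(sizes, identical, TRUE, c(1L, 2L, 3L))))
  expect_true(any(vapply(sizes, identical, TRUE, c(3L, 4L))))
  expect_true(any(vapply(sizes, identical, TRUE, c(3L, 5L))))
  # largest path (most samples) comes first
  expect_equal(sort(sg$paths[[1]]), c(1L, 2L, 3L))
  # every edge used exactly once
  expect_equal(sum(lengths(sg$paths) - 1L), nrow(cx$edges))
})

test_that("a pure cycle is cut at its smallest node id and flagged", {
  cx <- mk_complex(list("a", "b", "c"), 0:2, edge_df(1, 2, 2, 3, 1, 3))
  sg <- decompose_paths(cx)
  expect_length(sg$paths, 1L)
  p <- sg$paths[[1]]
  expect_equal(p[1], 1L)
  expect_equal(p[length(p)], 1L)
  expect_true(sg$is_cycle[1])
  expect_equal(sum(lengths(sg$paths) - 1L), nrow(cx$edges))
})

test_that("isolated nodes appear as single-node paths", {
  cx <- mk_complex(list("a", "b", "c"), c(0, 1, 2), edge_df(1, 2))
  sg <- decompose_paths(cx)
  expect_true(any(vapply(sg$paths, identical, TRUE, 3L)))
  covered <- sort(unique(unlist(sg$paths)))
  expect_equal(covered, 1:3)
})

test_that("order_samples sorts within nodes by filter and deduplicates", {
  cx <- mk_complex(list(c("a", "b", "c")), 0, edge_df())
  sg <- decompose_paths(cx)
  f <- user_filter(c(a = 0.3, b = 0.1, c = 0.2))
  expect_equal(order_samples(sg, f), c("b", "c", "a"))
  # shared sample emitted at first occurrence
  cx2 <- mk_complex(list(c("x", "a"), c("x", "b")), c(0, 1), edge_df(1, 2))
  sg2 <- decompose_paths(cx2)
  f2 <- user_filter(c(x = 0, a = 1, b = 2))
  ord <- order_samples(sg2, f2)
  expect_equal(sum(ord == "x"), 1L)
  expect_equal(length(ord), 3L)
  # ties in filter break by sample id
  f3 <- user_filter(c(a = 1, b = 1, c = 1))
  expect_equal(order_samples(sg, f3), c("a", "b", "c"))
})

test_that("heatmap matrices are consistent permutations of their inputs", {
  ds <- generate(planted_design(n_genes = 6L, k = 2L, samples_per_state = 4L,
                                seed = 3L))
  m <- normalize_zscore(ds$expression)
  D <- distance_matrix(ds$expression, ds$network)
  E <- diffusion_map(D, n_components = 2L)
  ord <- rev(colnames(m))
  hm <- heatmap_matrices(m, ord, D, E)
  expect_identical(colnames(hm$expression), ord)
  expect_equal(hm$wasserstein, unclass(D)[ord, ord])
  # embedding distance of a 2-sample system equals |coordinate difference|
  D2 <- structure(unclass(D)[1:2, 1:2], class = class(D))
  E2 <- diffusion_map(D2, n_components = 1L)
  hm2 <- heatmap_matrices(
    expr_matrix(unclass(m)[, 1:2], "normalized"), colnames(m)[1:2], D2, E2)
  expect_equal(hm2$embedding_dist[1, 2],
               abs(E2$coordinates[1, 1] - E2$coordinates[2, 1]))
  # identity permutation leaves matrices unchanged
  hm3 <- heatmap_matrices(m, colnames(m), D, E)
  expect_equal(hm3$expression, vals(m), ignore_attr = "scale")
  # covariate correlations are bounded and keyed by level
  cov <- setNames(rep(c("u", "v"), each = 4), colnames(m))
  hm4 <- heatmap_matrices(m, ord, D, E, covariates = cov)
  expect_identical(colnames(hm4$covariate_cor), c("u", "v"))
  expect_true(all(abs(hm4$covariate_cor) <= 1 + 1e-12))
  expect_error(heatmap_matrices(m, ord[-1], D, E), "mismatched")
})

test_that("call_states applies the closed dichotomization boundary", {
  v <- matrix(c(0.9, 0.5, 0.5 + 1 / 6, 0.9, 0.5, 0.5 + 1 / 6), 3, 2,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  m <- expr_matrix(v, "normalized")
  calls <- call_states(m, list(grp = c("s1", "s2")), delta = 1 / 6)
  expect_equal(calls$call, c("activated", "equivocal", "activated"))
  expect_equal(calls$mean, c(0.9, 0.5, 0.5 + 1 / 6))
  expect_error(call_states(m, list(grp = character())), "empty group")
  expect_error(call_states(normalize_zscore(
    expr_matrix(v * 10, "raw")), list(grp = "s1"), delta = 0.6), "delta")
})

test_that("raising delta moves genes only toward equivocal", {
  set.seed(51)
  v <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  m <- expr_matrix(v, "normalized")
  groups <- list(all = paste0("s", 1:5))
  prev <- call_states(m, groups, delta = 0.05)$call
  for (delta in c(0.1, 0.2, 0.3, 0.4)) {
    cur <- call_states(m, groups, delta = delta)$call
    moved <- prev != cur
    expect_true(all(cur[moved] == "equivocal"))
    prev <- cur
  }
})

test_that("path_groups partitions samples along the maximal paths", {
  cx2 <- mk_complex(list(c("x", "a"), c("x", "b"), "z"), c(0, 1, 2),
                    edge_df(1, 2))
  sg <- decompose_paths(cx2)
  g <- path_groups(sg, f = user_filter(c(x = 0, a = 1, b = 2, z = 3)))
  expect_equal(sort(unlist(g, use.names = FALSE)), c("a", "b", "x", "z"))
  expect_equal(anyDuplicated(unlist(g)), 0L)
  ex <- attr(g, "extremes")
  expect_equal(unname(ex[[1]]["low"]), "x")
})
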