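#' Design a synthetic expression dataset with planted coherent states
#'
#' Describes a small gene network plus k named activation patterns.
#' Expression is drawn per gene and sample as state_mean(gene) *
#' exp(sigma_noise * z) with z standard normal — multiplicative log-normal
#' noise, mimicking the positivity and right skew of FPKM/TPM values.
#' Level means: `high`, `low` as given; `mid` is their geometric mean, so
#' its z-scored value sits near the middle of the 0-1 scale.
#'
#' @param topology `"path"`, `"star"`, `"two_community"` or `"random_tree"`.
#' @param n_genes number of genes (network nodes).
#' @param states named list: per state, a character vector of levels
#'   (`"high"`/`"low"`/`"mid"`), one per gene. `NULL` gives k contiguous
#'   equal blocks of `high` activity on an otherwise `low` background —
#'   states that differ only in the network location of their activity.
#' @param k number of states when `states` is `NULL`.
#' @param samples_per_state samples drawn per state.
#' @param sigma_noise log-normal noise scale.
#' @param high,low raw means of the high and low levels.
#' @param seed RNG seed; generation is deterministic given the design.
#' @return A `planted_design` list.
#' @export
planted_design <- function(topology = c("path", "star", "two_community",
                                        "random_tree"),
                           n_genes = 12L, states = NULL, k = 3L,
                           samples_per_state = 30L, sigma_noise = 0.2,
                           high = 10, low = 1, seed = 7L) {
  topology <- match.arg(topology)
  if (high <= 0 || low <= 0) stop("level means must be positive")
  if (n_genes < 2L) stop("need at least 2 genes")
  genes <- sprintf("g%02d", seq_len(n_genes))
  if (is.null(states)) {
    if (k < 1L || k > n_genes) stop("k must lie in [1, n_genes]")
    cut <- floor(seq(0L, n_genes, length.out = k + 1L))
    states <- lapply(seq_len(k), function(s) {
      lv <- rep("low", n_genes)
      lv[(cut[s] + 1L):cut[s + 1L]] <- "high"
      lv
    })
    names(states) <- paste0("state", seq_len(k))
  }
  for (nm in names(states)) {
    if (length(states[[nm]]) != n_genes)
      stop("state ", nm, " must assign a level to every gene")
    if (!all(states[[nm]] %in% c("high", "low", "mid")))
      stop("levels must be high, low or mid")
  }
  structure(list(topology = topology, genes = genes, states = states,
                 samples_per_state = as.integer(samples_per_state),
                 sigma_noise = sigma_noise, high = high, low = low,
                 seed = as.integer(seed)),
            class = "planted_design")
}

level_means <- function(design) {
  c(high = design$high, low = design$low,
    mid = sqrt(design$high * design$low))
}

state_mean_matrix <- function(design) {
  lm <- level_means(design)
  vapply(design$states, function(lv) unname(lm[lv]),
         numeric(length(design$genes)))
}

design_network <- function(design) {
  g <- design$genes
  n <- length(g)
  edges <- switch(design$topology,
    path = data.frame(from = g[-n], to = g[-1L]),
    star = data.frame(from = g[1L], to = g[-1L]),
    two_community = {
      half <- ceiling(n / 2)
      a <- utils::combn(g[seq_len(half)], 2L)
      b <- utils::combn(g[seq(half + 1L, n)], 2L)
      data.frame(from = c(a[1L, ], b[1L, ], g[half]),
                 to = c(a[2L, ], b[2L, ], g[half + 1L]))
    },
    random_tree = {
      # seeded random tree: attach each node to a uniformly chosen earlier one
      parent <- 1L + floor(stats::runif(n - 1L) * seq_len(n - 1L))
      data.frame(from = g[parent], to = g[-1L])
    })
  gene_network(edges, nodes = g)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a planted-state dataset
#'
#' Draws `samples_per_state` samples per state with multiplicative
#' log-normal noise; deterministic given the design's seed. The returned
#' labels are for evaluation only — the pipeline never sees them.
#'
#' @param design a [planted_design()].
#' @return List with `expression` (raw [expr_matrix()]), `network`
#'   ([gene_network()]) and `labels` (named character vector of true
#'   states, names = sample ids).
#' @export
generate <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  with_seed(design$seed, {
    net <- design_network(design)
    mu <- state_mean_matrix(design)
    k <- ncol(mu)
    nps <- design$samples_per_state
    vals <- matrix(0, length(design$genes), k * nps)
    labels <- character(k * nps)
    ids <- character(k * nps)
    col <- 0L
    for (s in seq_len(k)) {
      for (r in seq_len(nps)) {
        col <- col + 1L
        z <- stats::rnorm(length(design$genes))
        vals[, col] <- mu[, s] * exp(design$sigma_noise * z)
        labels[col] <- colnames(mu)[s]
        ids[col] <- sprintf("s%03d", col)
      }
    }
    rownames(vals) <- design$genes
    colnames(vals) <- ids
    names(labels) <- ids
    list(expression = expr_matrix(vals, "raw"), network = net,
         labels = labels)
  })
}

#' Generate a Y-shaped dataset with bridge samples
#'
#' Adds `n_bridge` samples along convex combinations (in raw mean space)
#' between the mean vectors of states 1-2 and of states 1-3, producing a
#' Y-shaped point cloud whose correct state graph has exactly one branch
#' node.
#'
#' @param design a [planted_design()] with at least 2 states (3 for the
#'   full Y).
#' @param n_bridge bridge samples per state pair.
#' @return Same structure as [generate()]; bridge samples are labelled
#'   `bridge_1_2` / `bridge_1_3`.
#' @export
interpolated_branch <- function(design, n_bridge = 8L) {
  stopifnot(inherits(design, "planted_design"))
  k <- length(design$states)
  if (k < 2L) stop("interpolated_branch needs at least 2 states")
  base <- generate(design)
  if (n_bridge == 0L) return(base)
  mu <- state_mean_matrix(design)
  pairs <- list(c(1L, 2L))
  if (k >= 3L) pairs <- c(pairs, list(c(1L, 3L)))
  with_seed(design$seed + 1L, {
    newv <- list(); newl <- character()
    for (pr in pairs) {
      w <- seq_len(n_bridge) / (n_bridge + 1)
      for (wi in w) {
        mix <- (1 - wi) * mu[, pr[1L]] + wi * mu[, pr[2L]]
        z <- stats::rnorm(length(design$genes))
        newv[[length(newv) + 1L]] <- mix * exp(design$sigma_noise * z)
        newl <- c(newl, paste0("bridge_", pr[1L], "_", pr[2L]))
      }
    }
    add <- do.call(cbind, newv)
    ids <- sprintf("b%03d", seq_len(ncol(add)))
    colnames(add) <- ids
    rownames(add) <- design$genes
    vals <- cbind(unclass(base$expression), add)
    labels <- c(base$labels, stats::setNames(newl, ids))
    list(expression = expr_matrix(vals, "raw"), network = base$network,
         labels = labels)
  })
}

#' Three samples separated only by network location of activity
#'
#' On a path of `n_nodes` unit-strength edges, three samples carry the same
#' two-gene activity block at the start, middle and end of the path. All
#' pairwise Euclidean distances between the raw vectors are equal, yet the
#' network Wasserstein distance between the near pair is strictly smaller
#' than between the far pair — the property that motivates replacing the
#' Euclidean metric with a network-aware one.
#'
#' @param n_nodes path length (>= 6, even).
#' @param amplitude raw value of the active genes.
#' @return List with `expression` (3 samples), `network`, and the index
#'   pairs `near` and `far`.
#' @export
location_contrast_demo <- function(n_nodes = 6L, amplitude = 1) {
  if (n_nodes < 6L || n_nodes %% 2L != 0L) stop("n_nodes must be even, >= 6")
  genes <- sprintf("g%02d", seq_len(n_nodes))
  net <- gene_network(data.frame(from = genes[-n_nodes], to = genes[-1L]),
                      nodes = genes)
  mid <- n_nodes / 2L
  vals <- matrix(0, n_nodes, 3L,
                 dimnames = list(genes, c("near_a", "near_b", "far")))
  vals[c(1L, 2L), "near_a"] <- amplitude
  vals[c(mid, mid + 1L), "near_b"] <- amplitude
  vals[c(n_nodes - 1L, n_nodes), "far"] <- amplitude
  list(expression = expr_matrix(vals, "raw"), network = net,
       near = c("near_a", "near_b"), far = c("near_a", "far"))
}

#' Write a generated dataset to disk
#'
#' Expression TSV, edge list, and a two-column labels TSV.
#'
#' @param dataset output of [generate()] or [interpolated_branch()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  el <- igraph::as_data_frame(dataset$network$graph)
  utils::write.table(el[, c("from", "to", "strength")],
                     file.path(dir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sample = names(dataset$labels), label = dataset$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
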