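#' Read a key = value pipeline configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are kept as strings and coerced where used.
#'
#' @param path config file path.
#' @return Named list of strings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  stats::setNames(lapply(kv, function(x) trimws(x[3L])),
                  vapply(kv, function(x) trimws(x[2L]), ""))
}

default_config <- function() {
  list(expression = NULL, network = NULL, control = NULL, covariates = NULL,
       user_filter = NULL, delimiter = "\t",
       mode = "density", pseudocount = 0,
       epsilon_rule = "median", epsilon_value = NULL,
       n_components = 2L, selected_indices = NULL, include_trivial = FALSE,
       filter = "centrality", k = "auto",
       n_f = 6L, g = 0.5, t = NULL, min_overlap = 1L,
       delta = 1 / 6, seed = 1L, outdir = "netstates_out")
}

num_or <- function(x, default = NULL) {
  if (is.null(x) || (is.character(x) && !nzchar(x))) return(default)
  as.numeric(x)
}

#' Run the full state-discovery pipeline
#'
#' Executes every stage in order — normalization, network restriction,
#' Wasserstein distance matrix, diffusion embedding, filter, Mapper, state
#' graph, sample ordering, state calling, display matrices — writing each
#' intermediate artifact plus a run manifest (parameters, seed, package
#' version, per-stage wall times) into the output directory. A rerun with
#' the same config and inputs reproduces all outputs bit-identically.
#'
#' @param config named list (see [default_config fields in read_config()])
#'   or path to a key = value config file. `expression`/`network` may be
#'   paths or in-memory objects. When `t` is `NULL`, the single-linkage
#'   threshold defaults to half the median pairwise embedding distance.
#' @return Invisibly, a list with all in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config[!vapply(config, is.null, TRUE)])
  for (field in c("expression", "network")) {
    if (is.null(cfg[[field]]))
      stop("config field missing: ", field)
  }
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  m <- stage("read_expression", {
    if (is_expr_matrix(cfg$expression)) cfg$expression
    else read_expression(cfg$expression, cfg$delimiter)
  })
  net <- stage("read_network", {
    if (is_gene_network(cfg$network)) cfg$network
    else read_edge_list(cfg$network)
  })
  restricted <- stage("restrict", restrict_to_network(m, net, quiet = TRUE))
  normalized <- stage("normalize", normalize_zscore(restricted))
  write_expression(restricted, file.path(outdir, "restricted.tsv"))
  write_expression(normalized, file.path(outdir, "normalized.tsv"))

  D <- stage("distance", distance_matrix(restricted, net, mode = cfg$mode,
                                         pseudocount = num_or(cfg$pseudocount, 0)))
  write_distance_matrix(D, file.path(outdir, "distance.tsv"))

  E <- stage("diffuse", {
    eps <- if (identical(cfg$epsilon_rule, "value"))
      choose_epsilon(D, "value", num_or(cfg$epsilon_value))
    else choose_epsilon(D, "median")
    sel <- cfg$selected_indices
    if (is.character(sel)) sel <- as.integer(strsplit(sel, ",")[[1L]])
    diffusion_map(D, epsilon = eps, n_components = as.integer(cfg$n_components),
                  selected_indices = sel,
                  include_trivial = isTRUE(as.logical(cfg$include_trivial)))
  })
  write_embedding(E, file.path(outdir, "embedding.tsv"),
                  file.path(outdir, "eigenvalues.tsv"))

  f <- stage("filter", switch(cfg$filter,
    centrality = {
      k <- if (identical(cfg$k, "auto")) connected_knn_k(E$coordinates)
           else as.integer(cfg$k)
      centrality_filter(E$coordinates, k = k)
    },
    mahalanobis = {
      ctrl <- readLines(cfg$control, warn = FALSE)
      ctrl <- trimws(ctrl[nzchar(trimws(ctrl))])
      mahalanobis_filter(E$coordinates,
                         E$coordinates[ctrl, , drop = FALSE])
    },
    user = {
      df <- utils::read.table(cfg$user_filter, sep = "\t", header = FALSE)
      user_filter(stats::setNames(df[[2L]], df[[1L]]))
    },
    stop("unknown filter: ", cfg$filter)))

  cx <- stage("mapper", {
    t_link <- num_or(cfg$t)
    if (is.null(t_link)) {
      ed <- stats::dist(E$coordinates)
      t_link <- stats::median(ed) / 2
    }
    mapper(E$coordinates, f, n_f = as.integer(cfg$n_f),
           g = num_or(cfg$g, 0.5), t = t_link,
           min_overlap = as.integer(cfg$min_overlap))
  })
  write_mapper_json(cx, file.path(outdir, "mapper.json"))

  sg <- stage("stategraph", decompose_paths(cx))
  write_stategraph_json(sg, file.path(outdir, "stategraph.json"))

  ord <- stage("order", order_samples(sg, f))
  writeLines(ord, file.path(outdir, "sample_order.txt"))

  groups <- path_groups(sg, f)
  calls <- stage("states", call_states(normalized, groups,
                                       delta = num_or(cfg$delta, 1 / 6)))
  utils::write.table(calls, file.path(outdir, "state_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  covar <- NULL
  if (!is.null(cfg$covariates)) {
    df <- utils::read.table(cfg$covariates, sep = "\t", header = FALSE)
    covar <- stats::setNames(as.character(df[[2L]]), df[[1L]])
  }
  hm <- stage("heatmaps", heatmap_matrices(normalized, ord, D, E,
                                           covariates = covar))
  for (nm in names(hm)) {
    utils::write.table(
      data.frame(id = rownames(hm[[nm]]), hm[[nm]], check.names = FALSE),
      file.path(outdir, paste0("display_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "netstates",
    version = as.character(utils::packageVersion("netstates")),
    parameters = cfg[!vapply(cfg, function(x)
      is.null(x) || is_expr_matrix(x) || is_gene_network(x), TRUE)],
    epsilon = E$epsilon,
    stage_seconds = as.list(timings))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(expression = m, network = net, restricted = restricted,
                 normalized = normalized, distance = D, embedding = E,
                 filter = f, complex = cx, stategraph = sg,
                 sample_order = ord, groups = groups, calls = calls,
                 heatmaps = hm, outdir = outdir))
}

#' Pick a scan row from the stable middle regime
#'
#' From a [scan_parameters()] table, keeps the rows that are neither
#' degenerate extreme (all singletons, or one merged cluster) and whose
#' nerve is connected, orders them by (n_f, t), and returns the middle
#' row — a deterministic reading of the guidance to choose parameters
#' intermediate between the regime that shatters the sample set and the
#' regime that merges it.
#'
#' @param tab data.frame from [scan_parameters()].
#' @return One-row data.frame (the chosen `n_f`, `t` and its statistics).
#' @export
pick_stable_parameters <- function(tab) {
  cand <- tab[!tab$all_singletons & !tab$single_cluster &
                tab$components == 1L, , drop = FALSE]
  if (!nrow(cand))
    stop("no connected non-degenerate grid point; widen the grids")
  cand <- cand[order(cand$n_f, cand$t), , drop = FALSE]
  cand[ceiling(nrow(cand) / 2), , drop = FALSE]
}

#' Tabulate Mapper complexity over a parameter grid
#'
#' Runs Mapper at every combination of bin count and linkage threshold and
#' reports node/edge/component counts and the largest cluster, flagging the
#' two degenerate regimes (every sample its own cluster; one single
#' cluster). Sensible working parameters sit between the flagged extremes,
#' where the summary is stable over a range of values.
#'
#' @param points samples x M coordinate matrix.
#' @param f a `filter_values` vector.
#' @param n_f_grid integer vector of bin counts.
#' @param t_grid numeric vector of linkage thresholds.
#' @param g overlap fraction.
#' @param min_overlap minimum shared samples for an edge.
#' @return data.frame: `n_f`, `t`, `nodes`, `edges`, `components`,
#'   `max_cluster`, `all_singletons`, `single_cluster`.
#' @export
scan_parameters <- function(points, f, n_f_grid, t_grid, g = 0.5,
                            min_overlap = 1L) {
  if (!length(n_f_grid) || !length(t_grid)) stop("grids must be non-empty")
  n <- nrow(as.matrix(points))
  rows <- list()
  for (nf in n_f_grid) {
    for (tt in t_grid) {
      cx <- mapper(points, f, n_f = nf, g = g, t = tt,
                   min_overlap = min_overlap)
      gr <- mapper_igraph(cx)
      comps <- igraph::components(gr)$no
      mx <- if (nrow(cx$nodes)) max(cx$nodes$size) else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        n_f = nf, t = tt, nodes = nrow(cx$nodes), edges = nrow(cx$edges),
        components = comps, max_cluster = mx,
        all_singletons = mx <= 1L,
        single_cluster = nrow(cx$nodes) == 1L && mx == n)
    }
  }
  do.call(rbind, rows)
}
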