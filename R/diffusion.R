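#' Gaussian kernel matrix from pairwise distances
#'
#' W_ij = exp(-D_ij^2 / epsilon). The kernel scale epsilon sets the local
#' connectivity neighborhood: pairs within sqrt(epsilon) are strongly
#' connected, farther pairs negligibly.
#'
#' @param D symmetric non-negative distance matrix (e.g. a `sample_dist`).
#' @param epsilon positive kernel scale, on the scale of squared distances.
#' @return Symmetric matrix with unit diagonal.
#' @export
kernel_matrix <- function(D, epsilon) {
  D <- as.matrix(D)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar")
  exp(-(D^2) / epsilon)
}

#' Choose the diffusion kernel scale
#'
#' Any value between the minimum and maximum off-diagonal squared distance
#' is admissible; the default rule takes their median, a robust midpoint.
#' A user-supplied value outside that range is accepted with a warning.
#'
#' @param D symmetric distance matrix with at least 2 samples.
#' @param rule `"median"` or `"value"`.
#' @param value the user scale when `rule = "value"`.
#' @return Positive scalar epsilon.
#' @export
choose_epsilon <- function(D, rule = c("median", "value"), value = NULL) {
  rule <- match.arg(rule)
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("need at least 2 samples")
  d2 <- D[upper.tri(D)]^2
  if (all(d2 == 0)) stop("degenerate metric: all pairwise distances are zero")
  if (rule == "median") return(stats::median(d2))
  if (is.null(value) || value <= 0) stop("rule 'value' needs a positive value")
  if (value < min(d2) || value > max(d2))
    warning(sprintf("epsilon %g outside the pairwise squared-distance range [%g, %g]",
                    value, min(d2), max(d2)))
  value
}

#' Anisotropic (alpha = 1) Markov normalization of a kernel
#'
#' Two-step normalization: first the density-removing conjugation
#' Wt = D^-1 W D^-1 with D_ii = sum_j W_ij, then the row-stochastic
#' normalization P = Dt^-1 Wt with Dt_ii = sum_j Wt_ij. The alpha = 1 step
#' makes the spectral limit independent of how densely the underlying
#' manifold was sampled.
#'
#' @param W symmetric kernel matrix with positive diagonal.
#' @return Row-stochastic matrix P of the same dimension.
#' @export
adapted_markov <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-8) stop("W must be symmetric")
  d <- rowSums(W)
  if (any(d == 0)) stop("zero row sum in kernel")
  Wt <- W / outer(d, d)
  dt <- rowSums(Wt)
  if (any(dt == 0)) stop("zero row sum in adapted kernel")
  P <- Wt / dt
  dimnames(P) <- dimnames(W)
  P
}

#' Diffusion-map embedding from a Markov matrix
#'
#' Eigendecomposes the row-stochastic diffusion operator P through its
#' symmetric conjugate S = Dt^(1/2) P Dt^(-1/2) (guaranteeing a real
#' spectrum), orders eigenvalues by |lambda| descending (lambda_1 = 1 with
#' the constant eigenvector), and uses selected nontrivial eigenvectors as
#' per-sample coordinates. Eigenvector signs are fixed by making each
#' vector's largest-magnitude entry positive.
#'
#' @param P row-stochastic matrix from [adapted_markov()].
#' @param n_components number of nontrivial eigenvectors to use (default 2).
#' @param selected_indices optional 1-based indices over the nontrivial
#'   eigenvectors (e.g. `c(1, 2, 4)`), overriding `n_components`.
#' @param include_trivial if `TRUE`, indexing starts at the trivial constant
#'   eigenvector instead of dropping it.
#' @param diffusion_time optional power t; coordinates are scaled by
#'   lambda^t (default 0, i.e. bare eigenvectors).
#' @return A `diffusion_map`: list with `eigenvalues`, `eigenvectors`
#'   (columns, all of them), `coordinates` (samples x M matrix),
#'   `selected_indices`, and `epsilon` if supplied via attribute.
#' @export
embed <- function(P, n_components = 2L, selected_indices = NULL,
                  include_trivial = FALSE, diffusion_time = 0) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (max(abs(rowSums(P) - 1)) > 1e-8) stop("P must be row-stochastic")
  if (is.null(selected_indices)) {
    if (n_components >= n) stop("n_components must be smaller than the sample count")
    selected_indices <- seq_len(n_components)
  }
  # P = Dt^-1 Wt with Wt symmetric; recover dt from the stationary structure:
  # P is similar to S = diag(sqrt(dt)) P diag(1/sqrt(dt)), symmetric.
  # rowSums of the symmetrizing weights: dt is any positive vector with
  # diag(dt) P symmetric; dt = stationary distribution up to scale.
  dt <- stationary_row_weights(P)
  sq <- sqrt(dt)
  S <- sweep(sweep(P, 1L, sq, `*`), 2L, sq, `/`)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- order(abs(es$values), decreasing = TRUE)
  lam <- es$values[ord]
  vec <- es$vectors[, ord, drop = FALSE] / sq   # back-transform rows
  # unit norm + sign convention (largest-magnitude entry positive), for
  # reproducibility across eigensolvers
  for (k in seq_len(ncol(vec))) {
    vec[, k] <- vec[, k] / sqrt(sum(vec[, k]^2))
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  rownames(vec) <- rownames(P)
  pool <- if (include_trivial) seq_len(n) else seq_len(n)[-1L]
  if (any(selected_indices < 1L) || any(selected_indices > length(pool)))
    stop("selected eigenvector index out of range")
  idx <- pool[selected_indices]
  coords <- vec[, idx, drop = FALSE]
  if (diffusion_time != 0)
    coords <- sweep(coords, 2L, lam[idx]^diffusion_time, `*`)
  colnames(coords) <- paste0("phi", idx - 1L)   # trivial vector is phi0
  structure(list(eigenvalues = lam, eigenvectors = vec, coordinates = coords,
                 selected_indices = selected_indices,
                 include_trivial = include_trivial),
            class = "diffusion_map")
}

# positive vector dt (up to scale) making diag(dt) %*% P symmetric; for
# P = Dt^-1 Wt this is the vector of adapted-kernel row sums
stationary_row_weights <- function(P) {
  n <- nrow(P)
  # dt_i P_ij = dt_j P_ji  =>  dt_j / dt_i = P_ij / P_ji; anchor at node 1
  dt <- P[1L, ] / P[, 1L]
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    # fall back to the left Perron eigenvector
    e <- eigen(t(P))
    k <- which.min(abs(e$values - 1))
    dt <- abs(Re(e$vectors[, k]))
  }
  dt / sum(dt)
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat(sprintf("<diffusion_map> %d samples, %d coordinate(s); |lambda| = %s ...\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.4f", utils::head(abs(x$eigenvalues), 4L)),
                    collapse = ", ")))
  invisible(x)
}

#' Full diffusion map from a distance matrix
#'
#' Convenience wrapper: kernel, anisotropic normalization, embedding.
#'
#' @inheritParams kernel_matrix
#' @inheritParams embed
#' @param epsilon kernel scale, or `NULL` for the median rule.
#' @return A `diffusion_map` with `epsilon` recorded.
#' @export
diffusion_map <- function(D, epsilon = NULL, n_components = 2L,
                          selected_indices = NULL, include_trivial = FALSE,
                          diffusion_time = 0) {
  if (is.null(epsilon)) epsilon <- choose_epsilon(D)
  W <- kernel_matrix(D, epsilon)
  P <- adapted_markov(W)
  out <- embed(P, n_components = n_components,
               selected_indices = selected_indices,
               include_trivial = include_trivial,
               diffusion_time = diffusion_time)
  out$epsilon <- epsilon
  out
}

#' Write a diffusion embedding as TSV
#'
#' Coordinates as `sample` plus one column per eigenvector; eigenvalues to a
#' side-car two-column file when `eigenvalue_path` is given.
#'
#' @param E a `diffusion_map`.
#' @param path coordinates output path.
#' @param eigenvalue_path optional eigenvalue output path.
#' @export
write_embedding <- function(E, path, eigenvalue_path = NULL) {
  out <- data.frame(sample = rownames(E$coordinates),
                    E$coordinates, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(eigenvalue_path)) {
    utils::write.table(
      data.frame(index = seq_along(E$eigenvalues), lambda = E$eigenvalues),
      eigenvalue_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
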