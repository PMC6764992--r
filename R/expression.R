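#' Construct an expression matrix
#'
#' Light container for a genes x samples quantification matrix (FPKM/TPM-like
#' non-negative values on the `"raw"` scale, values in \[0, 1\] on the
#' `"normalized"` scale).
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene symbols and colnames sample identifiers.
#' @param scale `"raw"` or `"normalized"`.
#' @return An `expr_matrix`: the matrix with a `scale` attribute.
#' @export
expr_matrix <- function(values, scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || any(!nzchar(genes)))
    stop("all genes must have non-empty symbols (rownames)")
  if (is.null(samples) || any(!nzchar(samples)))
    stop("all samples must have non-empty identifiers (colnames)")
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative")
  if (scale == "normalized" && (any(values < 0) || any(values > 1)))
    stop("normalized-scale expression values must lie in [0, 1]")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x object to test.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

expr_scale <- function(m) attr(m, "scale")

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample identifiers, gene symbols in the first
#' column (its header is ignored), and finite non-negative numbers elsewhere.
#'
#' @param path file path.
#' @param delimiter field delimiter, `"\t"` (default) or `","`.
#' @return A raw-scale [expr_matrix()] with the file's row and column order.
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expected a gene column plus at least one sample column")
  genes <- df[[1L]]
  header <- colnames(df)[-1L]          # before subsetting, which mangles dups
  vals <- as.matrix(df[, -1L, drop = FALSE])
  colnames(vals) <- header
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite value '%s' at gene row %d, sample column %d",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value %s at gene row %d, sample column %d",
                 vals[neg[1L, 1L], neg[1L, 2L]], neg[1L, 1L], neg[1L, 2L]))
  }
  rownames(num) <- genes
  colnames(num) <- header
  expr_matrix(num, "raw")
}

#' Write an expression matrix as delimited text
#'
#' Mirrors [read_expression()]: numbers are serialized with full precision
#' (17 significant digits) so a write/read round trip is value-exact.
#'
#' @param m an [expr_matrix()].
#' @param path output path.
#' @param delimiter field delimiter.
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  stopifnot(is_expr_matrix(m))
  txt <- format(unclass(m), digits = 17, trim = TRUE, scientific = FALSE)
  out <- cbind(gene = rownames(m), txt)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Truncated translated z-score normalization
#'
#' Per gene, maps raw values x to (x - mu) / (3 sigma) + 0.5 and clamps to
#' \[0, 1\], so a gene's mean lands at 0.5 and +/- 3 standard deviations span
#' the displayable range. sigma is the population standard deviation
#' (divisor n); genes with sigma = 0 carry no contrast and map to the
#' constant 0.5.
#'
#' @param m a raw-scale [expr_matrix()].
#' @return A normalized-scale [expr_matrix()] of the same shape.
#' @export
normalize_zscore <- function(m) {
  stopifnot(is_expr_matrix(m))
  if (expr_scale(m) != "raw") stop("normalize_zscore expects a raw-scale matrix")
  v <- unclass(m)
  mu <- rowMeans(v)
  sigma <- sqrt(rowMeans((v - mu)^2))
  z <- (v - mu) / (3 * sigma) + 0.5
  z[sigma == 0, ] <- 0.5
  z <- pmin(pmax(z, 0), 1)
  expr_matrix(z, "normalized")
}

#' Restrict an expression matrix to the genes of a network
#'
#' Keeps exactly the genes present in both the matrix and the network, in
#' the network's node order, and reports how many genes were dropped from
#' the matrix and how many network genes had no measurements.
#'
#' @param m an [expr_matrix()].
#' @param g a [gene_network()].
#' @param quiet suppress the dropped/missing message.
#' @return An [expr_matrix()] over the shared genes.
#' @export
restrict_to_network <- function(m, g, quiet = FALSE) {
  stopifnot(is_expr_matrix(m), is_gene_network(g))
  shared <- intersect(network_nodes(g), rownames(m))
  if (!length(shared)) stop("no genes shared between matrix and network")
  dropped <- setdiff(rownames(m), shared)
  missing <- setdiff(network_nodes(g), shared)
  if (!quiet)
    message(sprintf("restrict_to_network: kept %d genes; dropped %d matrix-only; %d network genes unmeasured",
                    length(shared), length(dropped), length(missing)))
  expr_matrix(unclass(m)[shared, , drop = FALSE], expr_scale(m))
}
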