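# Delimited-text input/output. Matrix files are comma-delimited full square
# matrices with an optional single header row of node labels; time-series
# files are T x N with the same optional header. '.' is always the decimal
# mark (no locale dependence).

.has_header <- function(path, sep) {
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  any(is.na(suppressWarnings(as.numeric(first))))
}

#' Read a square matrix from delimited text
#'
#' @param path file path; comma-delimited, optional header row of node labels.
#' @param sep field separator.
#' @param sym_tol maximum tolerated asymmetry; a larger mismatch is an error
#'   naming the worst entry.
#' @param validate if `TRUE` (default) run the full correlation-matrix
#'   validation (unit diagonal, range, PSD warning); set `FALSE` for general
#'   symmetric matrices such as covariances.
#' @return numeric matrix with node labels as dimnames.
#' @export
read_square_matrix <- function(path, sep = ",", sym_tol = 1e-8, validate = TRUE) {
  hdr <- .has_header(path, sep)
  m <- as.matrix(utils::read.table(path, sep = sep, header = hdr,
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("'%s' is not square: %d x %d", path, nrow(m), ncol(m)),
         call. = FALSE)
  }
  asym <- abs(m - t(m))
  if (max(asym) > sym_tol) {
    idx <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop(sprintf(
      "'%s' is asymmetric: largest violation %.3g at entry (%d, %d)",
      path, max(asym), idx[1], idx[2]
    ), call. = FALSE)
  }
  if (validate) m <- validate_correlation_matrix(m, sym_tol = sym_tol)
  m
}

#' Write a square matrix as delimited text
#'
#' Full precision (17 significant digits), so write/read round-trips are exact
#' to within one double-precision ULP.
#'
#' @param m matrix to write.
#' @param path destination file.
#' @param sep field separator.
#' @param header write the column labels as a header row.
#' @export
write_square_matrix <- function(m, path, sep = ",", header = !is.null(colnames(m))) {
  df <- as.data.frame(format(m, digits = 17, scientific = TRUE, trim = TRUE))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a multivariate time series from delimited text
#'
#' Rows are time points, columns are nodes; an optional header row supplies
#' node labels.
#'
#' @inheritParams read_square_matrix
#' @return numeric `T x N` matrix.
#' @export
read_time_series <- function(path, sep = ",") {
  hdr <- .has_header(path, sep)
  m <- as.matrix(utils::read.table(path, sep = sep, header = hdr,
                                   check.names = FALSE))
  if (!is.numeric(m)) stop(sprintf("'%s' contains non-numeric data", path),
                           call. = FALSE)
  m
}

#' Write a weighted network as an edge list
#'
#' One row per unordered node pair with positive weight:
#' `node_i, node_j, weight`.
#'
#' @param net a `weighted_network`.
#' @param path destination file.
#' @param sep field separator.
#' @export
write_edge_list <- function(net, path, sep = ",") {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(node_i = net$nodes[idx[, 1]], node_j = net$nodes[idx[, 2]],
                   weight = w[idx])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
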