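#' Validate and normalize a correlation matrix
#'
#' Checks that `m` is a square symmetric numeric matrix with unit diagonal and
#' entries in \[-1, 1\], then returns a cleaned copy: exactly symmetrized
#' (average of `m` and its transpose) with an exact unit diagonal. Positive
#' semi-definiteness is checked within numerical tolerance and produces a
#' warning, not an error, because delimited-text round-tripping routinely
#' introduces eigenvalue violations at the 1e-12 scale.
#'
#' @param m numeric matrix to validate.
#' @param sym_tol maximum tolerated absolute asymmetry `|m[i,j] - m[j,i]|`.
#' @param diag_tol maximum tolerated deviation of diagonal entries from 1.
#' @param range_tol tolerated overshoot beyond \[-1, 1\] (values inside the
#'   tolerance are clamped).
#' @param check_psd if `TRUE`, warn when the smallest eigenvalue is below
#'   `-1e-8 * nrow(m)`.
#' @return the validated matrix, symmetrized, diagonal set to exactly 1.
#' @export
validate_correlation_matrix <- function(m, sym_tol = 1e-8, diag_tol = 1e-8,
                                        range_tol = 1e-8, check_psd = TRUE) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != ncol(m)) {
    stop("correlation matrix must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(m)) stop("correlation matrix contains missing values", call. = FALSE)
  asym <- abs(m - t(m))
  if (max(asym) > sym_tol) {
    idx <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop(sprintf(
      "matrix is not symmetric: largest violation %.3g at entry (%d, %d)",
      max(asym), idx[1], idx[2]
    ), call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > diag_tol) {
    i <- which.max(abs(diag(m) - 1))
    stop(sprintf("diagonal entry %d is %.6g, expected 1", i, diag(m)[i]),
         call. = FALSE)
  }
  if (max(abs(m)) > 1 + range_tol) {
    idx <- which(abs(m) == max(abs(m)), arr.ind = TRUE)[1, ]
    stop(sprintf("entry (%d, %d) = %.6g lies outside [-1, 1]",
                 idx[1], idx[2], m[idx[1], idx[2]]), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  m[m < -1] <- -1
  diag(m) <- 1
  if (check_psd) {
    ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8 * nrow(m)) {
      warning(sprintf(
        "correlation matrix is not positive semi-definite (smallest eigenvalue %.3g)",
        ev_min
      ), call. = FALSE)
    }
  }
  m
}

# Shared node-label helper: existing dimnames or V1..Vn.
.node_labels <- function(m) {
  lbl <- rownames(m)
  if (is.null(lbl)) lbl <- colnames(m)
  if (is.null(lbl)) lbl <- paste0("V", seq_len(nrow(m)))
  lbl
}
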