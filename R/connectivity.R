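#' Connectivity summaries of a correlation matrix
#'
#' Scalar and nodal summaries of average functional connectivity:
#' \describe{
#'   \item{`s`}{mean correlation over all node pairs (diagonal excluded).}
#'   \item{`s_plus`}{the same mean restricted to pairs with non-negative
#'     correlation (`rho >= 0`); flagged undefined if no such pair exists.}
#'   \item{`strength`}{node strength `s_i = sum_{j != i} rho(i, j)` (weighted
#'     degree over the full signed matrix).}
#'   \item{`strength_pos`}{positive node strength, summing only strictly
#'     positive correlations (`rho > 0`).}
#'   \item{`strength_norm`}{`s_i / (N - 1)`, normalized into \[-1, 1\].}
#' }
#' Note the deliberate asymmetry of conventions: the scalar `s_plus` includes
#' zero correlations (non-negative) while the nodal `strength_pos` excludes
#' them (strictly positive). Both follow their respective standard
#' definitions; zero entries are measure-zero in practice.
#'
#' @param corr correlation matrix, `N >= 2`.
#' @return object of class `connectivity_summary`.
#' @export
connectivity_summary <- function(corr) {
  rho <- validate_correlation_matrix(corr, check_psd = FALSE)
  n <- nrow(rho)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  up <- rho[upper.tri(rho)]
  s <- mean(up)
  nonneg <- up[up >= 0]
  s_plus_defined <- length(nonneg) > 0
  s_plus <- if (s_plus_defined) mean(nonneg) else NA_real_
  off <- rho
  diag(off) <- 0
  strength <- rowSums(off)
  strength_pos <- rowSums(off * (off > 0))
  structure(
    list(s = s, s_plus = s_plus, s_plus_defined = s_plus_defined,
         strength = strength, strength_pos = strength_pos,
         strength_norm = strength / (n - 1),
         nodes = .node_labels(corr), n_nodes = n),
    class = "connectivity_summary"
  )
}

#' @export
print.connectivity_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Average connectivity over %d nodes\n", x$n_nodes))
  cat(sprintf("  s  (all pairs)          : %.*f\n", digits, x$s))
  if (x$s_plus_defined) {
    cat(sprintf("  s+ (non-negative pairs) : %.*f\n", digits, x$s_plus))
  } else {
    cat("  s+ (non-negative pairs) : undefined (no pair with rho >= 0)\n")
  }
  cat(sprintf("  node strength range     : [%.*f, %.*f]\n",
              digits, min(x$strength), digits, max(x$strength)))
  invisible(x)
}
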