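# Clustering coefficients tailored to correlation matrices.
#
# Both coefficients compare, for each focal node i and each pair (j, l) of
# other nodes, the observed association between j and l with the
# pseudo-correlation rho(i,j) * rho(i,l) expected from the indirect path
# through i. Pairs are weighted by |rho(i,j) * rho(i,l)|: strong triangles
# should involve nodes strongly attached to the focal node. No thresholding
# and no discarding of negative correlations is involved.

.sign_mask <- function(r, R, sign_filter) {
  switch(sign_filter,
    all = matrix(TRUE, length(r), length(r)),
    positive = outer(r > 0, r > 0, `&`) & (R > 0),
    negative = outer(r < 0, r < 0, `&`) & (R < 0),
    stop(sprintf("unknown sign filter '%s'", sign_filter), call. = FALSE)
  )
}

.match_filter <- function(sign_filter) {
  match.arg(sign_filter, c("all", "positive", "negative"))
}

# Shared per-node accumulation for both correlation-matrix coefficients.
# FUN(P_quantity) maps the per-pair association (|partial| or partial MI).
.clustering_corr <- function(rho, sign_filter, eps, kind) {
  n <- nrow(rho)
  if (n < 3) stop("clustering needs at least 3 nodes", call. = FALSE)
  values <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  over_unit <- FALSE
  for (i in seq_len(n)) {
    r <- rho[i, -i]
    R <- rho[-i, -i, drop = FALSE]
    W <- abs(outer(r, r))
    use <- upper.tri(R) & .sign_mask(r, R, sign_filter)
    den <- sum(W[use])
    if (den <= 0) next
    contrib <- use & (W > 0)
    d <- 1 - r^2
    if (any(outer(d, d, pmin)[contrib] < eps)) {
      j <- which(d < eps)[1]
      others <- seq_len(nrow(rho))[-i]
      stop(sprintf(
        "degenerate triple at focal node %d: |rho(%d, %d)| is 1 within tolerance",
        i, i, others[j]
      ), call. = FALSE)
    }
    if (kind == "A") {
      P <- (R - outer(r, r)) / sqrt(outer(d, d))
      num <- sum(W[contrib] * abs(P[contrib]))
      values[i] <- num / den
    } else {
      r2 <- matrix(r^2, length(r), length(r))
      det3 <- 1 - r2 - t(r2) - R^2 + 2 * outer(r, r) * R
      if (any(det3[contrib] < eps)) {
        stop(sprintf(
          "degenerate triple at focal node %d: a 3x3 correlation submatrix is singular",
          i
        ), call. = FALSE)
      }
      det3[!contrib] <- 1  # unused entries; keeps log() off the j == l diagonal
      ld <- matrix(log(d), length(r), length(r))
      mi <- 0.5 * (ld + t(ld) - log(det3))
      num <- sum(W[contrib] * mi[contrib])
      values[i] <- num / (den * (1 + log(2 * pi)) / 2)
      if (values[i] > 1) over_unit <- TRUE
    }
    defined[i] <- TRUE
  }
  if (over_unit) {
    warning(paste(
      "a local mutual-information clustering value exceeds 1: the",
      "(1 + ln 2*pi)/2 normalizer does not bound the Gaussian partial mutual",
      "information on near-singular matrices; values are reported as computed"
    ), call. = FALSE)
  }
  list(values = values, defined = defined)
}

#' Partial-correlation clustering coefficient (absolute-value variant)
#'
#' For each node i, the weighted average over pairs `j < l` (both distinct
#' from i) of the absolute three-way partial correlation
#' `|rho_partial(j, l | i)|`, with weights `|rho(i,j) * rho(i,l)|`:
#' \deqn{C_i = \frac{\sum_{j<l} |\rho_{ij}\rho_{il}\,\rho^{partial}(j,l|i)|}
#'                  {\sum_{j<l} |\rho_{ij}\rho_{il}|}.}
#' Values lie in \[0, 1\]. A node with weight-sum zero (e.g. uncorrelated with
#' everything, or no admissible triangle under a sign filter) is undefined.
#'
#' @param corr correlation matrix.
#' @param sign_filter `"all"` uses every pair; `"positive"` restricts both
#'   sums to triples with `rho(i,j), rho(i,l), rho(j,l) > 0` (strict);
#'   `"negative"` to triples with all three `< 0`.
#' @param eps degeneracy guard for conditioning on a node perfectly correlated
#'   with a neighbor.
#' @return a `local_coefficients` object; average it with
#'   [global_clustering()].
#' @seealso [clustering_corr_M()] for the mutual-information variant.
#' @export
clustering_corr_A <- function(corr, sign_filter = "all", eps = 1e-12) {
  sign_filter <- .match_filter(sign_filter)
  rho <- validate_correlation_matrix(corr, check_psd = FALSE)
  res <- .clustering_corr(rho, sign_filter, eps, kind = "A")
  name <- paste0("cor_A", c(all = "", positive = "_pos", negative = "_neg")[sign_filter])
  local_coefficients(res$values, res$defined, name, .node_labels(corr))
}

#' Partial-mutual-information clustering coefficient
#'
#' Same weighted average as [clustering_corr_A()] but with the Gaussian
#' partial mutual information `I(X_j, X_l | X_i)` in place of the absolute
#' partial correlation, normalized by `(1 + ln 2*pi)/2` (the differential
#' entropy of a standard normal) so typical values fall in \[0, 1\]:
#' \deqn{C_i = \frac{\sum_{j<l} |\rho_{ij}\rho_{il}|\, I(X_j, X_l | X_i)}
#'                  {\frac{1+\ln 2\pi}{2}\sum_{j<l} |\rho_{ij}\rho_{il}|}.}
#' The normalizer does not bound the mutual information when a partial
#' correlation approaches 1 (|rho_partial| above about 0.97), so on
#' near-singular matrices a local value can exceed 1; it is then reported as
#' computed with a warning, never clipped.
#'
#' @inheritParams clustering_corr_A
#' @return a `local_coefficients` object.
#' @export
clustering_corr_M <- function(corr, sign_filter = "all", eps = 1e-12) {
  sign_filter <- .match_filter(sign_filter)
  rho <- validate_correlation_matrix(corr, check_psd = FALSE)
  res <- .clustering_corr(rho, sign_filter, eps, kind = "M")
  name <- paste0("cor_M", c(all = "", positive = "_pos", negative = "_neg")[sign_filter])
  local_coefficients(res$values, res$defined, name, .node_labels(corr))
}
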