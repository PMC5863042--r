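# Conventional clustering coefficients used as comparators: the unweighted
# coefficient on a thresholded network and the Barrat, Onnela and
# Zhang-Horvath weighted coefficients on the positive-weight network. All can
# be applied to either a Pearson or a full partial correlation matrix.

unweighted_network <- function(adjacency, nodes = NULL) {
  a <- as.matrix(adjacency)
  storage.mode(a) <- "double"
  stopifnot(nrow(a) == ncol(a), all(a %in% c(0, 1)),
            isTRUE(all.equal(a, t(a))), all(diag(a) == 0))
  if (is.null(nodes)) nodes <- .node_labels(adjacency)
  structure(list(adjacency = a, degree = rowSums(a), nodes = nodes),
            class = "unweighted_network")
}

weighted_network <- function(weights, nodes = NULL) {
  w <- as.matrix(weights)
  stopifnot(nrow(w) == ncol(w), all(w >= 0), all(diag(w) == 0))
  if (max(abs(w - t(w))) > 1e-12) stop("weights must be symmetric", call. = FALSE)
  w <- (w + t(w)) / 2
  if (is.null(nodes)) nodes <- .node_labels(weights)
  structure(list(weights = w, strength = rowSums(w), nodes = nodes),
            class = "weighted_network")
}

#' @export
print.unweighted_network <- function(x, ...) {
  cat(sprintf("Unweighted network: %d nodes, %d edges\n",
              nrow(x$adjacency), sum(x$adjacency) / 2))
  invisible(x)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("Weighted network: %d nodes, %d positive edges\n",
              nrow(x$weights), sum(x$weights > 0) / 2))
  invisible(x)
}

#' Threshold a correlation matrix into an unweighted network
#'
#' Two mutually exclusive rules. With `theta`, an edge is laid between i and j
#' iff `rho(i, j) >= theta`. With `edge_density` d in (0, 1), exactly
#' `floor(d * N * (N - 1) / 2)` edges are kept, taking the largest
#' off-diagonal correlations; ties at the cutoff are broken deterministically
#' in lexicographic `(i, j)` order of the upper-triangular entries.
#'
#' @param corr correlation matrix.
#' @param theta correlation threshold.
#' @param edge_density target fraction of the `N(N-1)/2` possible edges.
#' @return an `unweighted_network`: adjacency matrix plus degree vector.
#' @export
threshold_network <- function(corr, theta = NULL, edge_density = NULL) {
  rho <- validate_correlation_matrix(corr, check_psd = FALSE)
  if (is.null(theta) == is.null(edge_density)) {
    stop("supply exactly one of 'theta' and 'edge_density'", call. = FALSE)
  }
  n <- nrow(rho)
  a <- matrix(0, n, n)
  if (!is.null(theta)) {
    a[rho >= theta] <- 1
    diag(a) <- 0
  } else {
    if (edge_density <= 0 || edge_density >= 1) {
      stop("edge_density must lie strictly between 0 and 1", call. = FALSE)
    }
    ut <- which(upper.tri(rho), arr.ind = TRUE)
    vals <- rho[ut]
    keep <- order(-vals, ut[, 1], ut[, 2])[seq_len(floor(edge_density * n * (n - 1) / 2))]
    a[ut[keep, , drop = FALSE]] <- 1
    a <- a + t(a)
  }
  unweighted_network(a, .node_labels(corr))
}

#' Positive-weight network from a correlation matrix
#'
#' The common construction for weighted network analysis of correlation data:
#' edge weight `w_ij = rho(i, j)` where positive and 0 otherwise (negative
#' correlations are discarded); zero diagonal.
#'
#' @param corr correlation matrix.
#' @return a `weighted_network`: weights plus node strengths.
#' @export
positive_weight_network <- function(corr) {
  rho <- validate_correlation_matrix(corr, check_psd = FALSE)
  w <- pmax(rho, 0)
  diag(w) <- 0
  weighted_network(w, .node_labels(corr))
}

#' Unweighted local clustering coefficient
#'
#' Number of connected triangles through node i divided by the maximum
#' possible `k_i (k_i - 1) / 2`; undefined where the degree is 0 or 1.
#'
#' @param net an `unweighted_network`.
#' @return a `local_coefficients` object.
#' @export
clustering_unweighted <- function(net) {
  stopifnot(inherits(net, "unweighted_network"))
  a <- net$adjacency
  k <- net$degree
  tri <- diag(a %*% a %*% a) / 2
  defined <- k >= 2
  values <- ifelse(defined, 2 * tri / (k * (k - 1)), NA_real_)
  local_coefficients(values, defined, "unw", net$nodes)
}

#' Barrat weighted local clustering coefficient
#'
#' Average, over pairs of neighbors of i closing a triangle, of the mean of
#' the two focal edge weights, normalized by strength:
#' `C_i = sum_{j,l} ((w_ij + w_il)/2) a_ij a_il a_jl / (s_i (k_i - 1))`,
#' where the adjacency indicator is weight positivity. Reduces to the
#' unweighted coefficient on binary weights; undefined for degree <= 1.
#'
#' @param net a `weighted_network`.
#' @return a `local_coefficients` object.
#' @export
clustering_barrat <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  a <- (w > 0) + 0
  k <- rowSums(a)
  s <- net$strength
  aa <- a %*% a
  num <- rowSums(w * a * aa)  # sum over ordered (j, l): w_ij a_ij a_il a_jl
  defined <- k >= 2 & s > 0
  values <- ifelse(defined, num / (s * (k - 1)), NA_real_)
  local_coefficients(values, defined, "barrat", net$nodes)
}

#' Onnela weighted local clustering coefficient
#'
#' Geometric-mean triangle intensity normalized by the largest weight in the
#' network: `C_i = sum_{j,l} (w'_ij w'_il w'_jl)^{1/3} / (k_i (k_i - 1))` with
#' `w' = w / max(w)`. The max-normalizer (recomputed per matrix) makes the
#' coefficient invariant under uniform rescaling of all weights and bounds it
#' in \[0, 1\]. Undefined for degree <= 1; on an all-zero network every node
#' is undefined.
#'
#' @param net a `weighted_network`.
#' @return a `local_coefficients` object.
#' @export
clustering_onnela <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  wmax <- max(w)
  n <- nrow(w)
  if (wmax == 0) {
    return(local_coefficients(rep(NA_real_, n), rep(FALSE, n), "onnela", net$nodes))
  }
  wh <- (w / wmax)^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(wh %*% wh %*% wh)
  defined <- k >= 2
  values <- ifelse(defined, num / (k * (k - 1)), NA_real_)
  local_coefficients(values, defined, "onnela", net$nodes)
}

#' Zhang-Horvath weighted local clustering coefficient
#'
#' Ratio of the weighted triangle count to the weighted count of open triples:
#' `C_i = sum_{j,l} w'_ij w'_il w'_jl / sum_{j != l} w'_ij w'_il` with
#' `w' = w / max(w)`; scale-invariant, in \[0, 1\], and reduces to the
#' unweighted coefficient on binary weights. Undefined where the denominator
#' vanishes (fewer than two positively weighted neighbors).
#'
#' @param net a `weighted_network`.
#' @return a `local_coefficients` object.
#' @export
clustering_zhang <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  wmax <- max(w)
  n <- nrow(w)
  if (wmax == 0) {
    return(local_coefficients(rep(NA_real_, n), rep(FALSE, n), "zhang", net$nodes))
  }
  wh <- w / wmax
  num <- diag(wh %*% wh %*% wh)
  den <- rowSums(wh)^2 - rowSums(wh^2)  # sum over ordered j != l of w'_ij w'_il
  defined <- den > 0
  values <- ifelse(defined, num / den, NA_real_)
  local_coefficients(values, defined, "zhang", net$nodes)
}
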