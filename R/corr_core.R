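#' Pearson correlation matrix of a multivariate time series
#'
#' Computes the sample Pearson correlation between every pair of columns of a
#' time-series matrix (rows = time points, columns = nodes/ROIs). The result is
#' exactly symmetric with an exact unit diagonal and entries clamped to
#' \[-1, 1\] against floating-point overshoot.
#'
#' @param ts numeric matrix, `T x N`, with `T >= 4` rows (three-way partial
#'   correlation downstream needs at least 4 samples) and no constant column.
#' @return `N x N` correlation matrix carrying the column labels of `ts`.
#' @examples
#' x <- matrix(rnorm(200 * 5), 200, 5)
#' rho <- pearson_correlation(x)
#' @export
pearson_correlation <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric", call. = FALSE)
  if (nrow(ts) < 4) {
    stop("time series must have at least 4 time points", call. = FALSE)
  }
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    lbl <- colnames(ts)[bad]
    stop(sprintf("column %s has zero variance; correlation undefined",
                 if (is.null(lbl)) bad else sprintf("%d ('%s')", bad, lbl)),
         call. = FALSE)
  }
  rho <- stats::cor(ts)
  rho <- (rho + t(rho)) / 2
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

#' Sample covariance matrix with denominator T
#'
#' Covariance of the columns of a time-series matrix using the denominator-`T`
#' (population moment) normalization, the convention the H-Q-S null-model
#' moments consume. The choice cancels entirely in correlations and shifts the
#' H-Q-S moment targets only at order 1/T.
#'
#' @param ts numeric `T x N` matrix.
#' @return `N x N` covariance matrix.
#' @export
sample_covariance <- function(ts) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  if (n < 2) stop("need at least 2 time points", call. = FALSE)
  xc <- sweep(ts, 2, colMeans(ts))
  crossprod(xc) / n
}

#' Full partial correlation matrix
#'
#' Partial correlation between every node pair controlling for all remaining
#' `N - 2` nodes, computed from the inverse of the supplied correlation (or
#' covariance) matrix: `-Omega[i,j] / sqrt(Omega[i,i] * Omega[j,j])` where
#' `Omega` is the matrix inverse. The square root in the denominator is what
#' keeps the result in \[-1, 1\].
#'
#' @param corr square symmetric positive-definite correlation or covariance
#'   matrix.
#' @param max_condition largest accepted 2-norm condition number; beyond it the
#'   inversion is refused.
#' @return symmetric matrix of partial correlations with unit diagonal (by
#'   convention).
#' @export
full_partial_correlation <- function(corr, max_condition = 1e10) {
  m <- as.matrix(corr)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("input must be a square symmetric matrix", call. = FALSE)
  }
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
    stop(paste(
      "matrix is singular or ill-conditioned; full partial correlation is",
      "unreliable here and regularized estimation is out of scope"
    ), call. = FALSE)
  }
  omega <- solve((m + t(m)) / 2)
  p <- -omega / sqrt(outer(diag(omega), diag(omega)))
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- dimnames(m)
  p
}

#' Three-way partial correlation coefficient
#'
#' Correlation between nodes j and l after removing the linear effect of a
#' single conditioning node i:
#' `(rho_jl - rho_ij * rho_il) / sqrt((1 - rho_ij^2) * (1 - rho_il^2))`.
#' The numerator measures how far the observed `rho_jl` is from the
#' pseudo-correlation `rho_ij * rho_il` expected from the indirect path
#' j - i - l alone.
#'
#' Vectorized over its arguments (recycled to a common length).
#'
#' @param rho_jl correlation between j and l.
#' @param rho_ij correlation between i and j.
#' @param rho_il correlation between i and l.
#' @param eps degeneracy guard: an error is raised when `1 - rho_ij^2` or
#'   `1 - rho_il^2` falls below `eps` (node i is then a perfect copy of a
#'   neighbor and conditioning on it is undefined).
#' @return partial correlation(s), in \[-1, 1\] for any valid correlation
#'   triple.
#' @examples
#' partial_correlation3(0.5, 0.6, 0.4)  # (0.5 - 0.24) / sqrt(0.64 * 0.84)
#' @export
partial_correlation3 <- function(rho_jl, rho_ij, rho_il, eps = 1e-12) {
  d1 <- 1 - rho_ij^2
  d2 <- 1 - rho_il^2
  if (any(d1 < eps | d2 < eps)) {
    stop(paste(
      "degenerate triple: |rho(i,j)| or |rho(i,l)| is 1 within tolerance;",
      "the conditioning node is a perfect copy of a neighbor"
    ), call. = FALSE)
  }
  (rho_jl - rho_ij * rho_il) / sqrt(d1 * d2)
}

#' Gaussian partial mutual information of a correlation triple
#'
#' Mutual information between nodes j and l conditioned on node i, under the
#' assumption that the three signals are jointly Gaussian. In that case the
#' conditional mutual information has the closed form (natural log, nats)
#' \deqn{I = (1/2)[\ln(1-\rho_{ij}^2) + \ln(1-\rho_{il}^2) - \ln \det R_3]}
#' where `det R3 = 1 - rho_ij^2 - rho_il^2 - rho_jl^2 +
#' 2 rho_ij rho_il rho_jl` is the determinant of the 3x3 correlation matrix of
#' the triple. Equivalently `I = -ln(1 - rho_partial^2) / 2` with
#' `rho_partial` the three-way partial correlation, so `I >= 0` with equality
#' iff the partial correlation vanishes.
#'
#' @inheritParams partial_correlation3
#' @param eps guard: error when the determinant argument of the log is below
#'   `eps` (the triple is not a valid non-singular correlation matrix).
#' @return conditional mutual information in nats (vectorized).
#' @export
gaussian_partial_mi <- function(rho_jl, rho_ij, rho_il, eps = 1e-12) {
  d1 <- 1 - rho_ij^2
  d2 <- 1 - rho_il^2
  det3 <- 1 - rho_ij^2 - rho_il^2 - rho_jl^2 + 2 * rho_ij * rho_il * rho_jl
  if (any(d1 < eps | d2 < eps | det3 < eps)) {
    stop(paste(
      "degenerate triple: the 3x3 correlation matrix is singular within",
      "tolerance; partial mutual information diverges"
    ), call. = FALSE)
  }
  0.5 * (log(d1) + log(d2) - log(det3))
}

#' Mean absolute three-way partial correlation of a matrix
#'
#' Averages `|rho_partial(j, l | i)|` over every ordered choice of focal node i
#' and unordered pair `j < l` of the remaining nodes. For correlation matrices
#' estimated from independent white noise of length T this is approximately
#' `sqrt(2 / (pi * (T - 3)))`, the mean absolute value of a null sample
#' correlation with T - 1 effective observations -- the mechanism that sets
#' the white-noise baseline of the correlation clustering coefficients.
#'
#' @param corr correlation matrix (validated).
#' @param eps degeneracy guard passed through to the partial correlation.
#' @return scalar mean absolute partial correlation.
#' @export
mean_abs_partial3 <- function(corr, eps = 1e-12) {
  rho <- validate_correlation_matrix(corr, check_psd = FALSE)
  n <- nrow(rho)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  total <- 0
  count <- 0L
  for (i in seq_len(n)) {
    r <- rho[i, -i]
    d <- 1 - r^2
    if (any(d < eps)) {
      stop(sprintf("degenerate triple at focal node %d", i), call. = FALSE)
    }
    p <- (rho[-i, -i] - outer(r, r)) / sqrt(outer(d, d))
    up <- upper.tri(p)
    total <- total + sum(abs(p[up]))
    count <- count + sum(up)
  }
  total / count
}
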