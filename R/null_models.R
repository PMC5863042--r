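# Null models for correlation matrices: the Hirschberger-Qu-Steuer (H-Q-S)
# random covariance generator, which preserves the diagonal mean and the
# off-diagonal mean and variance of a reference covariance matrix, and
# correlation matrices of independent white-noise time series.

#' Moments of a covariance matrix for the H-Q-S generator
#'
#' Extracts the three moments the H-Q-S algorithm preserves: the mean of the
#' diagonal elements (`mu_on`), the mean of the strictly off-diagonal
#' elements (`mu_off`) and the population variance of the off-diagonal
#' elements (`sigma2_off`). The algorithm requires `mu_off > 0`; reference
#' matrices whose average off-diagonal covariance is negative (or zero)
#' cannot be randomized and raise an error, as do matrices with zero
#' off-diagonal variance.
#'
#' @param cov square symmetric covariance (or correlation) matrix.
#' @return object of class `hqs_moments` with fields `mu_on`, `mu_off`,
#'   `sigma2_off`, `n_nodes`.
#' @seealso [hqs_moment_set()] to build the object from known moment values,
#'   [hqs_generate()] to draw matrices.
#' @export
hqs_moments <- function(cov) {
  m <- as.matrix(cov)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("covariance matrix must be square and symmetric", call. = FALSE)
  }
  off <- m[row(m) != col(m)]
  hqs_moment_set(mean(diag(m)), mean(off),
                 mean((off - mean(off))^2), nrow(m))
}

#' Construct an H-Q-S moment specification directly
#'
#' @param mu_on mean diagonal covariance element; must be positive.
#' @param mu_off mean off-diagonal element; must be strictly positive (the
#'   algorithm's precondition).
#' @param sigma2_off variance of off-diagonal elements; must be strictly
#'   positive.
#' @param n_nodes matrix size to generate.
#' @return object of class `hqs_moments`.
#' @export
hqs_moment_set <- function(mu_on, mu_off, sigma2_off, n_nodes) {
  if (!is.finite(mu_off) || mu_off <= 0) {
    stop(paste(
      "H-Q-S precondition violated: the mean off-diagonal covariance must be",
      sprintf("positive (got %.6g)", mu_off)
    ), call. = FALSE)
  }
  if (!is.finite(sigma2_off) || sigma2_off <= 0) {
    stop(sprintf(
      "off-diagonal variance must be positive (got %.6g); the generator is degenerate",
      sigma2_off
    ), call. = FALSE)
  }
  if (!is.finite(mu_on) || mu_on <= 0) {
    stop(sprintf("mean diagonal element must be positive (got %.6g)", mu_on),
         call. = FALSE)
  }
  structure(list(mu_on = mu_on, mu_off = mu_off, sigma2_off = sigma2_off,
                 n_nodes = as.integer(n_nodes)),
            class = "hqs_moments")
}

#' @export
print.hqs_moments <- function(x, ...) {
  cat(sprintf(
    "H-Q-S moments (%d nodes): mu_on = %.4g, mu_off = %.4g, sigma2_off = %.4g, t_bar_max = %d\n",
    x$n_nodes, x$mu_on, x$mu_off, x$sigma2_off, hqs_t_bar_max(x)
  ))
  invisible(x)
}

#' Number of latent samples used by the H-Q-S generator
#'
#' `t_bar_max = max(2, floor((mu_on^2 - mu_off^2) / sigma2_off))`.
#'
#' @param moments an `hqs_moments` object.
#' @return integer number of latent white-noise samples per node.
#' @export
hqs_t_bar_max <- function(moments) {
  stopifnot(inherits(moments, "hqs_moments"))
  ratio <- (moments$mu_on^2 - moments$mu_off^2) / moments$sigma2_off
  # guard the floor against round-off when the ratio is an exact integer
  # (e.g. 0.91 / 0.01 evaluates just below 91 in binary floating point)
  max(2, floor(ratio + 1e-9))
}

#' Generate a random covariance/correlation matrix (H-Q-S algorithm)
#'
#' Draws `n_nodes * t_bar_max` independent normal variates `x[i, t]` and forms
#' the Gram matrix `cov[i, j] = sum_t x[i, t] * x[j, t]` -- i.e. each node is
#' modelled as a short white-noise series with a positive bias, independent
#' across nodes and samples. The output is positive semi-definite by
#' construction and, under the default parameterization, recovers the three
#' reference moments in expectation:
#' `E[cov_ij] = mu_off`, `Var[cov_ij] = sigma2_off` (i != j) and
#' `E[cov_ii] = sqrt(mu_off^2 + t_bar_max * sigma2_off)`, which equals `mu_on`
#' when `t_bar_max` is the untruncated ratio `(mu_on^2 - mu_off^2)/sigma2_off`.
#'
#' The default `"sqrt"` parameterization sets
#' `x_mean = sqrt(mu_off / t_bar_max)` and
#' `x_var = -mu_off / t_bar_max + sqrt(mu_off^2 / t_bar_max^2 +
#' sigma2_off / t_bar_max)`. A `"literal"` variant without the radicals is
#' available for auditability; it preserves none of the moments and is off by
#' default.
#'
#' @param moments an `hqs_moments` object (from a reference matrix via
#'   [hqs_moments()] or directly via [hqs_moment_set()]).
#' @param seed optional integer; when supplied, seeds the RNG so that one seed
#'   deterministically governs one matrix.
#' @param output `"correlation"` (the Gram matrix normalized to unit
#'   diagonal) or `"covariance"` (the raw Gram matrix).
#' @param parameterization `"sqrt"` (moment-preserving, default) or
#'   `"literal"`.
#' @return a matrix of the requested kind.
#' @export
hqs_generate <- function(moments, seed = NULL,
                         output = c("correlation", "covariance"),
                         parameterization = c("sqrt", "literal")) {
  stopifnot(inherits(moments, "hqs_moments"))
  output <- match.arg(output)
  parameterization <- match.arg(parameterization)
  t_bar <- hqs_t_bar_max(moments)
  mu_off <- moments$mu_off
  s2 <- moments$sigma2_off
  if (parameterization == "sqrt") {
    x_mean <- sqrt(mu_off / t_bar)
    x_var <- -mu_off / t_bar + sqrt(mu_off^2 / t_bar^2 + s2 / t_bar)
  } else {
    x_mean <- mu_off / t_bar
    x_var <- -mu_off / t_bar + mu_off^2 / t_bar^2 + s2 / t_bar
    if (x_var <= 0) {
      stop("literal parameterization yields a non-positive variance here",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(moments$n_nodes * t_bar, x_mean, sqrt(x_var)),
              moments$n_nodes, t_bar)
  cv <- tcrossprod(x)
  if (output == "covariance") return(cv)
  rho <- stats::cov2cor(cv)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho
}

#' Correlation matrix of independent white-noise series
#'
#' Draws `n_nodes` independent standard-normal time series of length `n_time`
#' and returns their sample Pearson correlation matrix. This is the
#' white-noise null: any off-diagonal structure is pure sampling fluctuation,
#' with standard deviation about `1 / sqrt(n_time - 1)` per entry.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param n_time series length (>= 4); 200 is a typical choice matching a
#'   resting-state recording after preprocessing.
#' @param seed optional integer RNG seed; one seed governs one matrix.
#' @return `n_nodes x n_nodes` correlation matrix.
#' @export
white_noise_correlation <- function(n_nodes = 30, n_time = 200, seed = NULL) {
  if (n_nodes < 3) stop("need at least 3 nodes", call. = FALSE)
  if (n_time < 4) stop("need at least 4 time points", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pearson_correlation(matrix(stats::rnorm(n_time * n_nodes), n_time, n_nodes))
}
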