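#' Clustering-coefficient profile of a correlation network
#'
#' Front door of the package: takes either a multivariate time series (rows =
#' time points, columns = nodes) or a precomputed correlation matrix, and
#' computes the selected local and global clustering coefficients together
#' with connectivity summaries. The correlation-matrix coefficients
#' (`"cor_A"`, `"cor_M"`) operate on the signed correlations directly; the
#' weighted comparators (`"barrat"`, `"onnela"`, `"zhang"`) use the
#' positive-weight network; the unweighted comparator (`"unw"`) requires a
#' thresholding rule (`theta` or `edge_density`).
#'
#' @param x numeric matrix: `T x N` time series or `N x N` correlation matrix.
#' @param kind `"auto"` (square symmetric unit-diagonal input is treated as a
#'   correlation matrix), `"timeseries"` or `"correlation"`.
#' @param coefficients character subset of
#'   `c("cor_A", "cor_M", "unw", "barrat", "onnela", "zhang")`. Default: all
#'   except `"unw"`, which is added automatically when a threshold rule is
#'   supplied.
#' @param sign_filter triangle sign restriction for the correlation-matrix
#'   coefficients: `"all"`, `"positive"` or `"negative"`.
#' @param theta,edge_density thresholding rule for the unweighted coefficient
#'   (mutually exclusive; see [threshold_network()]).
#' @return object of class `corrclust` with components `correlation` (the
#'   matrix used), `local` (named list of [local_coefficients] objects),
#'   `global` (named vector; `NA` where undefined at every node),
#'   `connectivity` (a [connectivity_summary()]), `n_nodes`, `options`, and
#'   `call`.
#' @examples
#' rho <- white_noise_correlation(10, 200, seed = 1)
#' fit <- corrclust(rho)
#' coef(fit)
#' summary(fit)
#' @export
corrclust <- function(x, kind = c("auto", "timeseries", "correlation"),
                      coefficients = NULL, sign_filter = "all",
                      theta = NULL, edge_density = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (kind == "auto") {
    looks_corr <- nrow(x) == ncol(x) &&
      max(abs(x - t(x))) <= 1e-8 && max(abs(diag(x) - 1)) <= 1e-8
    kind <- if (looks_corr) "correlation" else "timeseries"
  }
  rho <- if (kind == "timeseries") pearson_correlation(x) else
    validate_correlation_matrix(x)
  has_rule <- !is.null(theta) || !is.null(edge_density)
  all_coefs <- c("cor_A", "cor_M", "unw", "barrat", "onnela", "zhang")
  if (is.null(coefficients)) {
    coefficients <- if (has_rule) all_coefs else setdiff(all_coefs, "unw")
  }
  coefficients <- match.arg(coefficients, all_coefs, several.ok = TRUE)
  if ("unw" %in% coefficients && !has_rule) {
    stop("the unweighted coefficient needs 'theta' or 'edge_density'",
         call. = FALSE)
  }
  wnet <- if (any(c("barrat", "onnela", "zhang") %in% coefficients)) {
    positive_weight_network(rho)
  }
  unet <- if ("unw" %in% coefficients) {
    threshold_network(rho, theta = theta, edge_density = edge_density)
  }
  local <- lapply(stats::setNames(coefficients, coefficients), function(cf) {
    switch(cf,
      cor_A = clustering_corr_A(rho, sign_filter),
      cor_M = clustering_corr_M(rho, sign_filter),
      unw = clustering_unweighted(unet),
      barrat = clustering_barrat(wnet),
      onnela = clustering_onnela(wnet),
      zhang = clustering_zhang(wnet)
    )
  })
  global <- vapply(local, function(lc) {
    if (any(lc$defined)) mean(lc$values[lc$defined]) else NA_real_
  }, numeric(1))
  structure(
    list(correlation = rho, local = local, global = global,
         connectivity = connectivity_summary(rho),
         n_nodes = nrow(rho),
         options = list(kind = kind, sign_filter = sign_filter,
                        theta = theta, edge_density = edge_density),
         call = match.call()),
    class = "corrclust"
  )
}

#' @export
print.corrclust <- function(x, digits = 4, ...) {
  cat(sprintf("Correlation-network clustering profile: %d nodes\n", x$n_nodes))
  cat("Global coefficients (mean over defined nodes):\n")
  print(round(x$global, digits))
  invisible(x)
}

#' @describeIn corrclust global coefficients (`type = "global"`, a named
#'   vector) or the node-by-coefficient matrix of local values
#'   (`type = "local"`, `NA` where undefined).
#' @param object,... method arguments.
#' @param type see description.
#' @export
coef.corrclust <- function(object, type = c("global", "local"), ...) {
  type <- match.arg(type)
  if (type == "global") return(object$global)
  vapply(object$local, function(lc) lc$values, numeric(object$n_nodes))
}

#' @export
summary.corrclust <- function(object, ...) {
  tab <- data.frame(
    coefficient = names(object$local),
    global = unname(object$global),
    n_defined = vapply(object$local, function(lc) sum(lc$defined), integer(1)),
    n_undefined = vapply(object$local, function(lc) sum(!lc$defined), integer(1)),
    row.names = NULL
  )
  structure(list(coefficients = tab, connectivity = object$connectivity,
                 n_nodes = object$n_nodes),
            class = "summary.corrclust")
}

#' @export
print.summary.corrclust <- function(x, digits = 4, ...) {
  cat(sprintf("Correlation-network clustering profile: %d nodes\n\n", x$n_nodes))
  tab <- x$coefficients
  tab$global <- round(tab$global, digits)
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$connectivity, digits = digits)
  invisible(x)
}

#' @export
plot.corrclust <- function(x, ...) {
  locals <- x$local
  sn <- x$connectivity$strength_norm
  nc <- length(locals)
  old <- graphics::par(mfrow = grDevices::n2mfrow(nc))
  on.exit(graphics::par(old))
  for (nm in names(locals)) {
    lc <- locals[[nm]]
    graphics::plot(sn[lc$defined], lc$values[lc$defined],
                   xlab = "normalized node strength", ylab = nm,
                   main = sprintf("%s vs. strength", nm), ...)
  }
  invisible(x)
}
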