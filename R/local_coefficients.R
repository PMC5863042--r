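# Container for per-node coefficient values with defined/undefined flags.
# A node can legitimately have no admissible triangle (e.g. degree <= 1, or no
# pair of neighbors passing a sign filter); its value is then undefined and is
# excluded from -- not zero-filled into -- the global average.

local_coefficients <- function(values, defined, coefficient, nodes = NULL) {
  if (is.null(nodes)) nodes <- paste0("V", seq_along(values))
  values[!defined] <- NA_real_
  structure(
    list(values = as.numeric(values), defined = as.logical(defined),
         coefficient = coefficient, nodes = nodes),
    class = "local_coefficients"
  )
}

#' @export
print.local_coefficients <- function(x, ...) {
  cat(sprintf("Local clustering coefficient '%s' (%d nodes, %d defined)\n",
              x$coefficient, length(x$values), sum(x$defined)))
  v <- stats::setNames(round(x$values, 4), x$nodes)
  print(v)
  invisible(x)
}

#' @export
as.data.frame.local_coefficients <- function(x, ...) {
  data.frame(node = x$nodes, coefficient = x$coefficient,
             value = x$values, defined = x$defined,
             stringsAsFactors = FALSE)
}

#' Global clustering coefficient from local values
#'
#' Arithmetic mean of a local coefficient over the nodes where it is defined.
#' Nodes without an admissible triangle are excluded from the average rather
#' than contributing zero, mirroring the convention of dropping degree <= 1
#' nodes from the unweighted global coefficient.
#'
#' @param local a `local_coefficients` object.
#' @return scalar global coefficient.
#' @export
global_clustering <- function(local) {
  stopifnot(inherits(local, "local_coefficients"))
  if (!any(local$defined)) {
    stop(sprintf(
      "global '%s' is undefined: the local coefficient is undefined at every node",
      local$coefficient
    ), call. = FALSE)
  }
  mean(local$values[local$defined])
}
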