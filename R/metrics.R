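#' Global graph measures of a structural connectome
#'
#' Four standard measures summarise a weighted structural network:
#' `node_degree()` counts, for each region, the number of regions it is
#' connected to; `network_density()` is the fraction of possible
#' undirected connections that are present; `total_network_strength()` is
#' the sum of all connection weights (each undirected edge counted once);
#' and `global_efficiency()` is the average inverse shortest-path length
#' over all ordered region pairs, the canonical index of network
#' integration.
#'
#' For `global_efficiency()` with `weighted = TRUE` (the default) each
#' edge is traversed at a length of `1/weight`, the usual connectome
#' convention mapping strong connections to short paths; with
#' `weighted = FALSE` every edge has unit length (hop counts).
#' Disconnected pairs contribute an inverse distance of 0, so an empty
#' network has efficiency 0.
#'
#' @param matrix A `connectivity_matrix`.
#' @return `node_degree()`: named integer vector; `network_density()`,
#'   `total_network_strength()`, `global_efficiency()`: scalars.
#' @examples
#' p <- parcellation(c("A", "B", "C"))
#' m <- build_connectivity_matrix(streamline_set(
#'   data.frame(region_a = c("A", "B"), region_b = c("B", "C"),
#'              length = c(1, 1))), p, threshold = 0)
#' global_efficiency(m)  # (1 + 1 + 1/2) / 3 = 0.8333...
#' @name global_measures
NULL

#' @rdname global_measures
#' @export
node_degree <- function(matrix) {
  validate_connectivity_matrix(matrix)
  deg <- as.integer(rowSums(matrix$weights > 0))
  names(deg) <- matrix$parcellation$labels
  deg
}

#' @rdname global_measures
#' @export
network_density <- function(matrix) {
  validate_connectivity_matrix(matrix)
  n <- nrow(matrix$weights)
  if (n < 2L) stop("density needs at least 2 regions")
  sum(matrix$weights[upper.tri(matrix$weights)] > 0) / (n * (n - 1) / 2)
}

#' @rdname global_measures
#' @export
total_network_strength <- function(matrix) {
  validate_connectivity_matrix(matrix)
  sum(matrix$weights[upper.tri(matrix$weights)])
}

#' @rdname global_measures
#' @param weighted Logical; if `TRUE` shortest paths use per-edge lengths
#'   `1/weight`, otherwise unit lengths.
#' @export
global_efficiency <- function(matrix, weighted = TRUE) {
  validate_connectivity_matrix(matrix)
  w <- matrix$weights
  n <- nrow(w)
  if (n < 2L) stop("global efficiency needs at least 2 regions")
  if (all(w == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- if (weighted) 1 / igraph::E(g)$weight else NA
  d <- igraph::distances(g, weights = ew, algorithm = "dijkstra")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}
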