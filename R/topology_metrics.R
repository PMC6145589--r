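#' Mean degree
#'
#' The average number of edges incident to a node, `2M/N`. For biological
#' flow networks built from branching and fusion of vessels or cords this is
#' tightly constrained, typically falling between 2 and 3.
#'
#' @param net a [spatial_network]
#' @return a single number
#' @export
mean_degree <- function(net) 2 * n_edges(net) / n_nodes(net)

#' Average clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient (triangles through
#' a node divided by pairs of its neighbours). Nodes of degree < 2 contribute
#' zero to the average.
#'
#' @param net a [spatial_network]
#' @return a number in `[0, 1]`
#' @export
clustering_coefficient <- function(net) {
  igraph::transitivity(as_igraph(net), type = "localaverage",
                       isolates = "zero")
}

#' Alpha index (meshedness) of a connected planar network
#'
#' The density of independent cycles relative to the maximum possible in a
#' planar graph on the same nodes: `alpha = (M - N + 1) / (2N - 5)`. It is 0
#' for a tree and 1 for a maximal planar (triangulated) network.
#'
#' @param net a [spatial_network] (connected, planar, N >= 3)
#' @return a number, normally in `[0, 1]`
#' @export
alpha_index <- function(net) {
  N <- n_nodes(net)
  if (N < 3) stop("alpha index requires at least 3 nodes")
  (n_edges(net) - N + 1) / (2 * N - 5)
}

#' Hop-count shortest path lengths between all node pairs
#'
#' @param net a [spatial_network]
#' @return symmetric N x N matrix of topological (unweighted) shortest path
#'   lengths; unreachable pairs are `Inf`.
#' @export
topological_path_lengths <- function(net) {
  igraph::distances(as_igraph(net), weights = NA)
}

#' Topological efficiency
#'
#' The average over ordered node pairs of the inverse hop-count shortest
#' path length, `E_t = (1 / (N (N - 1))) * sum_{i != j} 1 / l_ij`;
#' unreachable pairs contribute zero. Already normalised to `[0, 1]` (equal
#' to 1 for a complete graph).
#'
#' @param net a [spatial_network]
#' @return a number in `[0, 1]`
#' @export
topological_efficiency <- function(net) {
  N <- n_nodes(net)
  if (N < 2) stop("efficiency requires at least 2 nodes")
  l <- topological_path_lengths(net)
  inv <- 1 / l
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

#' Topological edge betweenness centrality
#'
#' For each edge, the number of hop-count shortest paths between unordered
#' node pairs that traverse it, with ties split fractionally among the
#' multiple shortest paths of a pair.
#'
#' @param net a [spatial_network]
#' @return numeric vector, one value per edge (edge-table order), named
#'   `"source|target"`
#' @export
topological_edge_betweenness <- function(net) {
  b <- igraph::edge_betweenness(as_igraph(net), directed = FALSE, weights = NA)
  names(b) <- paste(net$edges$source, net$edges$target, sep = "|")
  b
}
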