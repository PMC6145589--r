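#' Total wiring length
#'
#' The sum of the Euclidean lengths of all edges, `W = sum_{i>j} A_ij D_ij`,
#' a proxy for the material cost of building the network. Edges are assumed
#' straight (tortuosity is neglected).
#'
#' @param net a [spatial_network]
#' @return a single non-negative number, in the units of the coordinates
#' @export
wiring_length <- function(net) sum(edge_lengths(net))

#' Physical (Euclidean-weighted) shortest path lengths
#'
#' Shortest paths where the length of a path is the sum of the Euclidean
#' lengths of the edges traversed.
#'
#' @param net a [spatial_network]
#' @return symmetric N x N matrix; unreachable pairs are `Inf`
#' @export
physical_path_lengths <- function(net) {
  igraph::distances(as_igraph(net), weights = edge_lengths(net))
}

#' Global physical efficiency
#'
#' The raw average physical efficiency is
#' `E_avg = (1 / (N (N - 1))) * sum_{i != j} 1 / l_ij` with `l_ij` the
#' physical (summed Euclidean edge length) shortest path length; unreachable
#' pairs contribute zero. Dividing by the same quantity for the fully
#' connected network on the same node positions (all pairs joined by straight
#' lines) gives the normalised global physical efficiency `E_p` in `[0, 1]`.
#'
#' @param net a [spatial_network]
#' @param D optional precomputed [distance_matrix()] (for the normalisation)
#' @return list with `E_p_avg` (raw), `E_p` (normalised), and `E_p_full`
#'   (the complete-graph reference value)
#' @export
physical_efficiency <- function(net, D = NULL) {
  N <- n_nodes(net)
  if (N < 2) stop("efficiency requires at least 2 nodes")
  if (is.null(D)) D <- suppressWarnings(distance_matrix(net))
  off <- upper.tri(D)
  if (any(D[off] == 0))
    stop("coincident nodes: complete-graph normalisation undefined")
  l <- physical_path_lengths(net)
  inv <- 1 / l
  diag(inv) <- 0
  e_avg <- sum(inv) / (N * (N - 1))
  e_full <- 2 * sum(1 / D[off]) / (N * (N - 1))
  list(E_p_avg = e_avg, E_p = e_avg / e_full, E_p_full = e_full)
}

#' Physical edge betweenness centrality
#'
#' For each edge, the sum over unordered node pairs of the fraction of
#' minimal-physical-length paths between the pair that traverse the edge.
#' Geometric ties (several paths of identical summed length) are split
#' fractionally.
#'
#' @param net a [spatial_network]
#' @return numeric vector, one value per edge (edge-table order), named
#'   `"source|target"`
#' @export
physical_edge_betweenness <- function(net) {
  b <- igraph::edge_betweenness(as_igraph(net), directed = FALSE,
                                weights = edge_lengths(net))
  names(b) <- paste(net$edges$source, net$edges$target, sep = "|")
  b
}

#' Spearman rank correlation between two edge betweenness maps
#'
#' Used to quantify how much the topological and physical notions of edge
#' centrality overlap in a spatially embedded network.
#'
#' @param be_t,be_p numeric vectors of per-edge betweenness values on the
#'   identical edge set (at least 3 edges)
#' @return Spearman's rho in `[-1, 1]`, with average ranks for ties; `NA`
#'   (with a warning) when either map has zero variance
#' @export
betweenness_rank_correlation <- function(be_t, be_p) {
  if (length(be_t) != length(be_p))
    stop("betweenness maps must cover the same edge set")
  if (length(be_t) < 3) stop("need at least 3 edges")
  if (!is.null(names(be_t)) && !is.null(names(be_p)) &&
      !identical(names(be_t), names(be_p)))
    stop("betweenness maps must cover the same edge set")
  if (sd(be_t) == 0 || sd(be_p) == 0) {
    warning("zero variance in a betweenness map; rank correlation undefined")
    return(NA_real_)
  }
  cor(be_t, be_p, method = "spearman")
}
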