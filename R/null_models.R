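#' Euclidean minimum spanning tree on the node positions of a network
#'
#' The spanning tree of minimal total Euclidean edge length, computed with
#' Prim's algorithm on the implicit complete graph of pairwise distances.
#' Node ids, coordinates and types are carried over; only the edge set
#' changes. The MST is the low-cost, low-redundancy extreme among connected
#' planar networks on a fixed node set and anchors the relative measures at
#' zero.
#'
#' @param net a [spatial_network] with at least 2 nodes and distinct
#'   coordinates
#' @return a [spatial_network] with `N - 1` edges
#' @export
euclidean_mst <- function(net) {
  n <- n_nodes(net)
  if (n < 2) stop("MST needs at least 2 nodes")
  x <- net$nodes$x
  y <- net$nodes$y
  if (anyDuplicated(cbind(x, y))) stop("coincident points: MST undefined")
  intree <- logical(n)
  intree[1] <- TRUE
  d2 <- (x - x[1])^2 + (y - y[1])^2
  parent <- rep(1L, n)
  ea <- integer(n - 1)
  eb <- integer(n - 1)
  for (k in seq_len(n - 1)) {
    d2m <- d2
    d2m[intree] <- Inf
    j <- which.min(d2m)  # ties resolved to the smallest index
    intree[j] <- TRUE
    ea[k] <- parent[j]
    eb[k] <- j
    d2new <- (x - x[j])^2 + (y - y[j])^2
    upd <- !intree & d2new < d2
    d2[upd] <- d2new[upd]
    parent[upd] <- j
  }
  spatial_network(net$nodes, cbind(ea, eb), name = paste0(net$name, "-mst"))
}

#' Greedy triangulation on the node positions of a network
#'
#' Connects node pairs in ascending order of Euclidean distance, skipping
#' any pair whose straight segment would cross an already accepted edge
#' (shared endpoints do not count as crossings; collinear overlap does).
#' Ties are broken deterministically by (distance, smaller id, larger id).
#' The result is a maximal planar straight-line graph -- the expensive,
#' highly redundant extreme that anchors the relative measures at one. In
#' general position it has exactly `3N - 3 - h` edges, `h` the number of
#' convex hull points.
#'
#' @param net a [spatial_network] with at least 3 nodes, distinct
#'   coordinates; an all-collinear node set degenerates to the chain (with a
#'   warning)
#' @return a [spatial_network]
#' @export
greedy_triangulation <- function(net) {
  n <- n_nodes(net)
  if (n < 3) stop("greedy triangulation needs at least 3 nodes")
  x <- net$nodes$x
  y <- net$nodes$y
  if (anyDuplicated(cbind(x, y)))
    stop("coincident points: triangulation undefined")
  cr <- (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
  if (all(cr == 0)) {
    warning("all nodes collinear; returning the chain")
    ord <- order((x - x[1]) * (x[2] - x[1]) + (y - y[1]) * (y[2] - y[1]))
    e <- cbind(ord[-n], ord[-1])
    return(spatial_network(net$nodes, e, name = paste0(net$name, "-gt")))
  }
  h <- length(chull(x, y))
  e <- cpp_gt_edges(x, y, 3L * n - 3L - h)
  spatial_network(net$nodes, e, name = paste0(net$name, "-gt"))
}

#' Connected degree-preserving rewired ensemble
#'
#' Generates an ensemble of randomized benchmarks for a network by repeated
#' double-edge swaps that preserve the degree sequence exactly, reject
#' self-loops and duplicate edges, and keep the graph connected. Each member
#' targets `swaps_per_edge * M` accepted swaps (attempts are capped at
#' `100 * M`). Node ids, coordinates and types are retained, so the members
#' can be used for spatially resolved comparisons (e.g. Rentian scaling);
#' only the connectivity is randomized.
#'
#' @param net a connected [spatial_network] with at least 2 edges
#' @param n_members ensemble size (default 10)
#' @param swaps_per_edge accepted swaps per edge to aim for (default 15)
#' @param seed master seed; per-member sub-seeds are derived from it
#' @return a `null_ensemble` list: `kind`, `members` (list of
#'   [spatial_network]), `source_name`, `seeds`, and an `info` data frame
#'   with accepted/attempted swap counts and a `flagged` column marking
#'   members on which no swap was accepted (degree sequences with no valid
#'   swap leave the member equal to the source).
#' @export
degree_preserving_rewire <- function(net, n_members = 10, swaps_per_edge = 15,
                                     seed = 1) {
  m <- n_edges(net)
  if (m < 2) stop("rewiring needs at least 2 edges")
  seeds <- spawn_seeds(seed, n_members)
  members <- vector("list", n_members)
  acc <- integer(n_members)
  att <- integer(n_members)
  for (k in seq_len(n_members)) {
    r <- cpp_rewire_connected(n_nodes(net), net$edge_idx,
                              as.integer(swaps_per_edge * m),
                              as.integer(100 * m), seeds[k])
    members[[k]] <- spatial_network(net$nodes, r$edges,
                                    name = sprintf("%s-rewire-%02d",
                                                   net$name, k))
    acc[k] <- r$accepted
    att[k] <- r$attempts
  }
  structure(list(kind = "rewired", members = members,
                 source_name = net$name, seeds = seeds,
                 info = data.frame(member = seq_len(n_members),
                                   accepted = acc, attempts = att,
                                   flagged = acc == 0)),
            class = "null_ensemble")
}

#' Apply a metric function to every member of a null ensemble
#' @param ensemble a `null_ensemble`
#' @param metric_fn function taking a [spatial_network] and returning a
#'   single number
#' @return numeric vector of member values
#' @export
ensemble_metric <- function(ensemble, metric_fn) {
  vapply(ensemble$members, metric_fn, numeric(1))
}

#' Normalise an empirical metric by its rewired-ensemble mean
#'
#' Returns `X / <X_rewire>` together with the ensemble mean and standard
#' deviation. A zero ensemble mean (common for the clustering coefficient of
#' rewired sparse networks, where triangles are rare) yields a missing value
#' with a warning rather than an infinity.
#'
#' @param x empirical metric value
#' @param ensemble_values the metric evaluated on each ensemble member (see
#'   [ensemble_metric()])
#' @return list with `value` (`x / mean`), `ensemble_mean`, `ensemble_sd`,
#'   `n`
#' @export
ensemble_normalize <- function(x, ensemble_values) {
  if (!length(ensemble_values)) stop("empty ensemble")
  mu <- mean(ensemble_values)
  s <- sd(ensemble_values)
  if (mu == 0) {
    warning("ensemble mean is zero; normalised value undefined")
    val <- NA_real_
  } else val <- x / mu
  list(value = val, ensemble_mean = mu, ensemble_sd = s,
       n = length(ensemble_values))
}
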