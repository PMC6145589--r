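#' Node type labels understood by the spatial network container
#'
#' `branch` and `endpoint` are ordinary junctions and tips, `inoculum` marks
#' the food source a mycelium was grown from, `penetrating_arteriole` marks a
#' degree-1 vasculature node where a surface vessel dives into the tissue,
#' and `unknown` is the default.
#'
#' @export
NODE_TYPES <- c("branch", "endpoint", "inoculum", "penetrating_arteriole",
                "unknown")

#' Construct a planar spatial network
#'
#' A `spatial_network` is a simple undirected graph whose nodes carry 2D
#' coordinates (arbitrary but consistent length units) and a type label.
#' Edges are stored as unordered pairs of node ids; duplicates and reversed
#' duplicates are collapsed.
#'
#' @param nodes data frame with columns `id`, `x`, `y` and optionally `type`
#'   (one of [NODE_TYPES], default `"unknown"`). Ids are treated as opaque
#'   strings; internal dense indexing follows row order.
#' @param edges data frame with columns `source`, `target` (node ids), or a
#'   two-column matrix of node ids / 1-based node indices.
#' @param name free-text network name.
#' @param allow_disconnected if `FALSE` (default) a disconnected graph is an
#'   error; set `TRUE` to analyse damaged or derived networks.
#' @return an object of class `spatial_network` with elements `nodes`,
#'   `edges` (id pairs), `edge_idx` (1-based index pairs), `name`.
#' @export
spatial_network <- function(nodes, edges, name = "network",
                            allow_disconnected = FALSE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y") %in% names(nodes)))
    stop("node table must have columns id, x, y")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!is.numeric(nodes$x) || !is.numeric(nodes$y))
    stop("non-numeric coordinates")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y)))
    stop("all node coordinates must be finite")
  if (is.null(nodes$type)) nodes$type <- "unknown"
  nodes$type <- as.character(nodes$type)
  nodes$type[is.na(nodes$type) | nodes$type == ""] <- "unknown"
  bad_type <- setdiff(unique(nodes$type), NODE_TYPES)
  if (length(bad_type))
    stop("unknown node type(s): ", paste(bad_type, collapse = ", "))
  nodes <- nodes[, c("id", "x", "y", "type")]
  rownames(nodes) <- NULL

  if (is.matrix(edges)) {
    edges <- data.frame(source = edges[, 1], target = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && !all(c("source", "target") %in% names(edges))) {
    if (ncol(edges) >= 2) names(edges)[1:2] <- c("source", "target")
    else stop("edge table must have columns source, target")
  }
  if (nrow(edges) == 0)
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  if (is.numeric(edges$source)) edges$source <- nodes$id[edges$source]
  if (is.numeric(edges$target)) edges$target <- nodes$id[edges$target]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)

  a <- match(edges$source, nodes$id)
  b <- match(edges$target, nodes$id)
  if (anyNA(a) || anyNA(b)) {
    missing_ids <- unique(c(edges$source[is.na(a)], edges$target[is.na(b)]))
    stop("edge table references unknown node id(s): ",
         paste(missing_ids, collapse = ", "))
  }
  if (any(a == b)) stop("self-loop edges are not allowed")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(lo * (nrow(nodes) + 1) + hi)
  lo <- lo[keep]
  hi <- hi[keep]
  ord <- order(lo, hi)
  lo <- lo[ord]
  hi <- hi[ord]
  edge_idx <- cbind(lo, hi)
  dimnames(edge_idx) <- NULL

  zero_len <- nodes$x[lo] == nodes$x[hi] & nodes$y[lo] == nodes$y[hi]
  if (any(zero_len)) stop("zero-length edge(s) between coincident nodes")
  if (anyDuplicated(nodes[, c("x", "y")]))
    warning("duplicate node coordinates present")

  net <- structure(
    list(nodes = nodes,
         edges = data.frame(source = nodes$id[lo], target = nodes$id[hi],
                            stringsAsFactors = FALSE),
         edge_idx = edge_idx,
         name = name),
    class = "spatial_network")

  if (!allow_disconnected && !is_connected(net))
    stop("network is disconnected (set allow_disconnected = TRUE to override)")
  net
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("<spatial_network> %s: %d nodes, %d edges\n",
              x$name, n_nodes(x), n_edges(x)))
  tt <- table(x$nodes$type)
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes / edges of a spatial network
#' @param net a [spatial_network]
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edge_idx)

#' Node degrees (in edge-count, by node order)
#' @param net a [spatial_network]
#' @export
node_degrees <- function(net) {
  tabulate(c(net$edge_idx[, 1], net$edge_idx[, 2]), nbins = n_nodes(net))
}

#' Convert a spatial network to an igraph graph
#'
#' Vertices keep `name` (the node id), `x`, `y` and `type` attributes; the
#' vertex order matches the node-table row order.
#'
#' @param net a [spatial_network]
#' @return an undirected [igraph::igraph] object
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes$id)
  g <- igraph::set_vertex_attr(g, "x", value = net$nodes$x)
  g <- igraph::set_vertex_attr(g, "y", value = net$nodes$y)
  g <- igraph::set_vertex_attr(g, "type", value = net$nodes$type)
  igraph::add_edges(g, t(net$edge_idx))
}

is_connected <- function(net) {
  if (n_nodes(net) <= 1) return(TRUE)
  igraph::is_connected(as_igraph(net))
}

#' Euclidean edge lengths, in node-table units
#' @param net a [spatial_network]
#' @return numeric vector, one entry per edge (edge-table order)
#' @export
edge_lengths <- function(net) {
  a <- net$edge_idx[, 1]
  b <- net$edge_idx[, 2]
  sqrt((net$nodes$x[a] - net$nodes$x[b])^2 +
       (net$nodes$y[a] - net$nodes$y[b])^2)
}

#' Pairwise Euclidean distance matrix of the node positions
#'
#' @param net a [spatial_network]
#' @return symmetric N x N matrix with zero diagonal; a warning is emitted
#'   when distinct nodes share coordinates (off-diagonal zeros).
#' @export
distance_matrix <- function(net) {
  D <- as.matrix(stats::dist(net$nodes[, c("x", "y")]))
  dimnames(D) <- list(net$nodes$id, net$nodes$id)
  if (n_nodes(net) > 1 && any(D[upper.tri(D)] == 0))
    warning("distinct nodes with identical coordinates (zero distances)")
  D
}

#' Validate a spatial network and summarise its basic structure
#'
#' @param net a [spatial_network]
#' @return a list with `connected`, `n_nodes`, `n_edges`,
#'   `duplicate_coordinate_pairs` and `messages`.
#' @export
validate_network <- function(net) {
  msgs <- character()
  conn <- is_connected(net)
  if (!conn) msgs <- c(msgs, "graph is disconnected")
  dup <- sum(duplicated(net$nodes[, c("x", "y")]))
  if (dup > 0) msgs <- c(msgs, sprintf("%d duplicated coordinate pair(s)", dup))
  if (conn && n_edges(net) < n_nodes(net) - 1)
    msgs <- c(msgs, "edge count below spanning-tree minimum")  # unreachable
  list(connected = conn, n_nodes = n_nodes(net), n_edges = n_edges(net),
       duplicate_coordinate_pairs = dup, messages = msgs)
}

#' Load a spatial network from node and edge tables
#'
#' @param nodes path to a CSV with header `id,x,y[,type]`, or an equivalent
#'   data frame.
#' @param edges path to a CSV with header `source,target`, or an equivalent
#'   data frame.
#' @param name network name; defaults to the node file basename.
#' @inheritParams spatial_network
#' @return a validated [spatial_network]
#' @export
load_network <- function(nodes, edges, name = NULL,
                         allow_disconnected = FALSE) {
  if (is.character(nodes)) {
    if (is.null(name))
      name <- sub("[-_.]?nodes\\.csv$", "", basename(nodes))
    nodes <- read.csv(nodes, stringsAsFactors = FALSE,
                      colClasses = c(id = "character"))
  }
  if (is.character(edges))
    edges <- read.csv(edges, stringsAsFactors = FALSE,
                      colClasses = c(source = "character",
                                     target = "character"))
  if (is.null(name)) name <- "network"
  spatial_network(nodes, edges, name = name,
                  allow_disconnected = allow_disconnected)
}

#' Write a spatial network as a CSV node/edge table pair
#'
#' Writes `<prefix>-nodes.csv` (`id,x,y,type`, coordinates with 10
#' significant digits) and `<prefix>-edges.csv` (`source,target`), UTF-8.
#' `load_network()` on the written pair reproduces the network exactly.
#'
#' @param net a [spatial_network]
#' @param prefix output path prefix (directories must exist)
#' @return invisibly, the two file paths written
#' @export
write_network <- function(net, prefix) {
  nf <- paste0(prefix, "-nodes.csv")
  ef <- paste0(prefix, "-edges.csv")
  nodes <- net$nodes
  nodes$x <- formatC(nodes$x, digits = 10, format = "g")
  nodes$y <- formatC(nodes$y, digits = 10, format = "g")
  write.csv(nodes, nf, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  write.csv(net$edges, ef, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(c(nodes = nf, edges = ef))
}

#' GraphML export / import with x, y and type node attributes
#'
#' @param net a [spatial_network]
#' @param path file path
#' @return `write_graphml` returns `path` invisibly; `read_graphml` returns a
#'   [spatial_network].
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @param name network name for the re-imported object
#' @param allow_disconnected passed to [spatial_network()]
#' @export
read_graphml <- function(path, name = NULL, allow_disconnected = FALSE) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                      x = igraph::vertex_attr(g, "x"),
                      y = igraph::vertex_attr(g, "y"),
                      type = igraph::vertex_attr(g, "type"),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (is.null(name)) name <- sub("\\.graphml$", "", basename(path))
  spatial_network(nodes, el, name = name,
                  allow_disconnected = allow_disconnected)
}

#' Remove isolated penetrating-arteriole stubs
#'
#' Deletes every degree-1 node labelled `penetrating_arteriole` together with
#' its single incident edge, producing the "reduced" representation of a
#' vasculature network in which only the looped surface backbone and its
#' junctions remain. The pass is applied once: branch nodes that become
#' degree-1 through the removal are not themselves removed.
#'
#' @param net a [spatial_network] with node type labels
#' @return a revalidated [spatial_network]
#' @export
reduce_stubs <- function(net) {
  deg <- node_degrees(net)
  drop <- which(deg == 1 & net$nodes$type == "penetrating_arteriole")
  if (!length(drop)) return(net)
  keep_edge <- !(net$edge_idx[, 1] %in% drop | net$edge_idx[, 2] %in% drop)
  nodes <- net$nodes[-drop, , drop = FALSE]
  edges <- net$edges[keep_edge, , drop = FALSE]
  out <- spatial_network(nodes, edges, name = paste0(net$name, "-reduced"))
  stopifnot(is_connected(out))  # degree-1 removals cannot disconnect
  out
}
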