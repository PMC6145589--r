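# Independent oracles and small builders used across the suite.

# spatial_network from bare coordinate vectors and an index edge matrix
snet <- function(x, y, edges, name = "test", allow_disconnected = FALSE) {
  spatial_network(data.frame(id = sprintf("n%d", seq_along(x)),
                             x = x, y = y),
                  edges, name = name, allow_disconnected = allow_disconnected)
}

# random scattered points
rpoints <- function(n, seed) {
  set.seed(seed)
  list(x = runif(n), y = runif(n))
}

# a small random connected planar network: pruned greedy triangulation
random_planar_net <- function(n, alpha = 0.1, seed = 1) {
  p <- rpoints(n, seed)
  net <- snet(p$x, p$y, cbind(seq_len(n - 1), seq_len(n - 1) + 1),
              allow_disconnected = TRUE)
  gt <- greedy_triangulation(net)
  cycles <- round(alpha * (2 * n - 5))
  m_target <- n - 1 + cycles
  len <- edge_lengths(gt)
  set.seed(seed + 1)
  keep <- gt$edge_idx
  # remove random non-bridge edges via igraph until the target count
  g <- as_igraph(gt)
  while (igraph::ecount(g) > m_target) {
    br <- igraph::bridges(g)
    cand <- setdiff(seq_len(igraph::ecount(g)), br)
    if (!length(cand)) break
    g <- igraph::delete_edges(g, sample(cand, 1))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  snet(p$x, p$y, el)
}

# decode a Pruefer sequence (length n - 2, entries in 1..n) into tree edges
prufer_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  ptr <- 0L
  for (i in seq_along(pr)) {
    leaf <- which(degree == 1L)[1]
    edges[i, ] <- c(leaf, pr[i])
    degree[leaf] <- 0L
    degree[pr[i]] <- degree[pr[i]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# minimum spanning tree length by exhaustive enumeration of all labelled
# trees (Cayley: n^(n-2)); practical for n <= 6
brute_mst_length <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, n <= 6)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_edges(seqs[r, ], n)
    w <- sum(sqrt((x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2))
    if (w < best) best <- w
  }
  best
}

# all spanning-tree wiring lengths (same enumeration), for dominance checks
all_spanning_tree_lengths <- function(x, y) {
  n <- length(x)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  apply(seqs, 1, function(s) {
    e <- prufer_edges(s, n)
    sum(sqrt((x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2))
  })
}

# brute-force edge betweenness by exhaustive simple-path enumeration;
# weighted (Euclidean) or hop-count. Practical for n <= 10.
brute_edge_betweenness <- function(net, weighted = TRUE, tol = 1e-9) {
  n <- n_nodes(net)
  eidx <- net$edge_idx
  m <- nrow(eidx)
  w <- if (weighted) edge_lengths(net) else rep(1, m)
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    a <- eidx[k, 1]; b <- eidx[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  be <- numeric(m)
  for (q in seq_len(n - 1)) for (r in seq(q + 1, n)) {
    best <- Inf
    paths <- list()
    dfs <- function(v, visited, elist, len) {
      if (len > best + tol) return(invisible())
      if (v == r) {
        if (len < best - tol) {
          best <<- len
          paths <<- list(elist)
        } else paths[[length(paths) + 1]] <<- elist
        return(invisible())
      }
      A <- adj[[v]]
      for (row in seq_len(nrow(A))) {
        nxt <- A[row, 1]
        eid <- A[row, 2]
        if (!visited[nxt]) {
          visited[nxt] <- TRUE
          dfs(nxt, visited, c(elist, eid), len + w[eid])
          visited[nxt] <- FALSE
        }
      }
    }
    vis <- logical(n)
    vis[q] <- TRUE
    dfs(q, vis, integer(0), 0)
    keep <- vapply(paths, function(el) sum(w[el]) <= best + tol, logical(1))
    paths <- paths[keep]
    for (el in paths) be[el] <- be[el] + 1 / length(paths)
  }
  be
}

# does the network embedding contain any crossing edge pair? (brute force)
is_planar_embedding <- function(net) {
  cpp <- get("cpp_count_crossings", envir = asNamespace("planarnet"))
  cpp(net$nodes$x, net$nodes$y, net$edge_idx) == 0
}
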