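#' Deterministic geometric fixtures
#'
#' Small, exactly-known networks used as oracles throughout the package:
#' `grid` (a `size` x `size` integer lattice), `path` (unit-spaced chain),
#' `cycle` (regular polygon), `star` (one hub with `size - 1` unit-radius
#' leaves), `complete` (regular polygon with all pairs connected) and
#' `square` (unit square corners with the 4 side edges).
#'
#' @param kind one of `"grid"`, `"path"`, `"cycle"`, `"star"`, `"complete"`,
#'   `"square"`
#' @param size fixture size parameter (nodes, or lattice side for `grid`;
#'   ignored for `square`)
#' @return a [spatial_network]
#' @export
make_fixture <- function(kind = c("grid", "path", "cycle", "star",
                                  "complete", "square"), size = 4) {
  kind <- match.arg(kind)
  if (size < 1) stop("size must be >= 1")
  if (kind == "complete" && size > 2000)
    stop("complete fixture capped at 2000 nodes (quadratic edge count)")
  if (kind == "grid") {
    ij <- expand.grid(i = seq_len(size), j = seq_len(size))
    nodes <- data.frame(id = sprintf("n%d", seq_len(nrow(ij))),
                        x = as.numeric(ij$i - 1), y = as.numeric(ij$j - 1))
    idx <- function(i, j) (j - 1) * size + i
    e <- NULL
    if (size > 1) {
      h <- cbind(idx(seq_len(size - 1), rep(seq_len(size), each = size - 1)),
                 idx(seq_len(size - 1) + 1, rep(seq_len(size), each = size - 1)))
      v <- cbind(idx(rep(seq_len(size), each = size - 1), seq_len(size - 1)),
                 idx(rep(seq_len(size), each = size - 1), seq_len(size - 1) + 1))
      e <- rbind(h, v)
    }
    return(spatial_network(nodes, if (is.null(e)) NULL else e,
                           name = sprintf("grid-%d", size)))
  }
  if (kind == "path") {
    nodes <- data.frame(id = sprintf("n%d", seq_len(size)),
                        x = as.numeric(seq_len(size) - 1), y = 0)
    e <- if (size > 1) cbind(seq_len(size - 1), seq_len(size - 1) + 1) else NULL
    return(spatial_network(nodes, e, name = sprintf("path-%d", size)))
  }
  if (kind == "cycle") {
    if (size < 3) stop("cycle needs size >= 3")
    th <- 2 * pi * (seq_len(size) - 1) / size
    nodes <- data.frame(id = sprintf("n%d", seq_len(size)),
                        x = cos(th), y = sin(th))
    e <- cbind(seq_len(size), c(seq_len(size)[-1], 1L))
    return(spatial_network(nodes, e, name = sprintf("cycle-%d", size)))
  }
  if (kind == "star") {
    if (size < 2) stop("star needs size >= 2")
    th <- 2 * pi * (seq_len(size - 1) - 1) / (size - 1)
    nodes <- data.frame(id = sprintf("n%d", seq_len(size)),
                        x = c(0, cos(th)), y = c(0, sin(th)))
    e <- cbind(1L, 1L + seq_len(size - 1))
    return(spatial_network(nodes, e, name = sprintf("star-%d", size)))
  }
  if (kind == "complete") {
    if (size < 2) stop("complete needs size >= 2")
    th <- 2 * pi * (seq_len(size) - 1) / size
    nodes <- data.frame(id = sprintf("n%d", seq_len(size)),
                        x = cos(th), y = sin(th))
    e <- t(utils::combn(size, 2))
    return(spatial_network(nodes, e, name = sprintf("complete-%d", size)))
  }
  # unit square, 4 side edges
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  spatial_network(nodes, cbind(c(1, 2, 3, 4), c(2, 3, 4, 1)), name = "square")
}

#' Configuration for the synthetic network generators
#'
#' @param n_nodes number of nodes (>= 10)
#' @param target_alpha target alpha index (meshedness) in `[0, 1]`; the
#'   generators hit the nearest achievable cycle count, so the achieved value
#'   is within half a cycle (`0.5 / (2N - 5)`) of the target
#' @param stub_fraction fraction of nodes that are degree-1 penetrating
#'   arteriole stubs (vasculature regime only, `< 0.6`)
#' @param region side length of the bounding square
#' @param seed integer seed; the seed fully determines the output
#' @param kind `"mycelium"`, `"vasculature"` or `"fixture"`
#' @return a `generator_config` list
#' @export
generator_config <- function(n_nodes, target_alpha = 0.14,
                             stub_fraction = 0.4, region = 1, seed = 1,
                             kind = c("mycelium", "vasculature", "fixture")) {
  kind <- match.arg(kind)
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  if (target_alpha < 0 || target_alpha > 1) stop("target_alpha must be in [0, 1]")
  if (stub_fraction < 0 || stub_fraction >= 0.6)
    stop("stub_fraction must be in [0, 0.6)")
  if (region <= 0) stop("region must be positive")
  structure(list(n_nodes = as.integer(n_nodes), target_alpha = target_alpha,
                 stub_fraction = stub_fraction, region = region,
                 seed = as.integer(seed), kind = kind),
            class = "generator_config")
}

# Greedy-triangulation scaffold on given points, pruned uniformly at random
# among non-bridge edges (never disconnecting) down to the edge count that
# realises `cycles` independent cycles. Returns a 2-column index matrix.
prune_scaffold <- function(x, y, cycles, seed) {
  n <- length(x)
  h <- length(chull(x, y))
  gt <- cpp_gt_edges(x, y, 3L * n - 3L - h)
  m_target <- n - 1L + cycles
  if (m_target > nrow(gt))
    stop("unreachable target_alpha: scaffold has only ", nrow(gt), " edges")
  len <- sqrt((x[gt[, 1]] - x[gt[, 2]])^2 + (y[gt[, 1]] - y[gt[, 2]])^2)
  out <- cpp_prune_keep_connected(n, gt, len, nrow(gt) - m_target, 0, seed)
  if (nrow(out) != m_target) stop("pruning failed to reach target edge count")
  out
}

# Minimum spanning tree of the points plus `cycles` additional edges picked
# uniformly from the remaining greedy-triangulation edges: a minimal-cost
# backbone carrying a few anastomotic loops. Returns a 2-column index matrix.
mst_plus_loops <- function(x, y, cycles, seed) {
  n <- length(x)
  h <- length(chull(x, y))
  gt <- cpp_gt_edges(x, y, 3L * n - 3L - h)
  carrier <- spatial_network(data.frame(id = sprintf("n%d", seq_len(n)),
                                        x = x, y = y), gt)
  mst <- euclidean_mst(carrier)$edge_idx
  key <- function(E) paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  pool <- which(!(key(gt) %in% key(mst)))
  # the GT need not contain every MST edge; drop loop candidates that would
  # cross one so the union stays planar
  ok <- vapply(pool, function(k)
    !cpp_segment_conflicts(x, y, mst, gt[k, 1], gt[k, 2]), logical(1))
  pool <- pool[ok]
  if (cycles > length(pool))
    stop("unreachable target_alpha: scaffold has only ", length(pool),
         " loop candidates")
  if (cycles > 0) {
    pick <- with_seed(seed, sample(pool, cycles))
    rbind(mst, gt[pick, , drop = FALSE])
  } else mst
}

#' Generate a mycelium-like planar network
#'
#' Emulates the loopy regime of mature mycelial cord networks: a connected
#' planar graph grown around a central inoculum, with node density decaying
#' radially away from the inoculum and an alpha index in the empirical range
#' (around 0.14). Points are sampled with a radially decaying density, a
#' greedy triangulation provides a maximal planar scaffold (a stand-in for
#' the densely anastomosed mat), and edges are thinned uniformly at random
#' among non-bridges until the target cycle count is reached -- leaving
#' loops of all length scales, the signature of cord fusion.
#'
#' @param cfg a [generator_config()] (kind `"mycelium"`)
#' @return a [spatial_network]; node 1 is the inoculum at the region centre,
#'   degree-1 nodes are labelled `endpoint`, all others `branch`
#' @export
generate_mycelium_like <- function(cfg) {
  n <- cfg$n_nodes
  seeds <- spawn_seeds(cfg$seed, 2)
  pts <- with_seed(seeds[1], {
    r <- (cfg$region / 2) * runif(n - 1)^0.7
    th <- runif(n - 1, 0, 2 * pi)
    list(x = c(0, r * cos(th)) + cfg$region / 2,
         y = c(0, r * sin(th)) + cfg$region / 2)
  })
  cycles <- round(cfg$target_alpha * (2 * n - 5))
  edges <- prune_scaffold(pts$x, pts$y, cycles, seeds[2])
  deg <- tabulate(edges, nbins = n)
  type <- ifelse(deg == 1, "endpoint", "branch")
  type[1] <- "inoculum"
  nodes <- data.frame(id = sprintf("n%d", seq_len(n)), x = pts$x, y = pts$y,
                      type = type, stringsAsFactors = FALSE)
  spatial_network(nodes, edges,
                  name = sprintf("mycelium-a%.3f-s%d", cfg$target_alpha,
                                 cfg$seed))
}

#' Generate a vasculature-like planar network
#'
#' Emulates pial (brain-surface) vasculature: a sparse looped backbone (low
#' alpha index, around 0.02) with a prescribed fraction of degree-1
#' penetrating-arteriole stub nodes hanging off it. The backbone is the
#' Euclidean minimum spanning tree of uniformly scattered junction points
#' plus a small number of anastomotic loop edges drawn from the greedy
#' triangulation -- a minimal-cost vessel tree with the sparse strategic
#' redundancy characteristic of the pial surface backbone. Each stub is
#' then attached by a short non-crossing edge to a random backbone node.
#' Stub edges do not change the cycle count, so the achieved alpha index of
#' the full network matches the target.
#'
#' @param cfg a [generator_config()] (kind `"vasculature"`); `target_alpha`
#'   defaults are sensible around 0.02
#' @return a [spatial_network] with `ceiling(stub_fraction * n_nodes)`
#'   penetrating-arteriole nodes
#' @export
generate_vasculature_like <- function(cfg) {
  n <- cfg$n_nodes
  n_stub <- as.integer(ceiling(cfg$stub_fraction * n))
  n_b <- n - n_stub
  if (n_b < 10) stop("too few backbone nodes; lower stub_fraction")
  seeds <- spawn_seeds(cfg$seed, 3)
  pts <- with_seed(seeds[1], list(x = runif(n_b, 0, cfg$region),
                                  y = runif(n_b, 0, cfg$region)))
  cycles <- round(cfg$target_alpha * (2 * n - 5))
  edges <- mst_plus_loops(pts$x, pts$y, cycles, seeds[2])

  x <- pts$x
  y <- pts$y
  if (n_stub > 0) {
    edges <- with_seed(seeds[3], {
      att <- sample.int(n_b, n_stub, replace = TRUE)
      for (s in seq_len(n_stub)) {
        v <- att[s]
        d_nn <- sqrt(min((x[-v] - x[v])^2 + (y[-v] - y[v])^2))
        len <- 0.3 * d_nn
        placed <- FALSE
        for (try in seq_len(60)) {
          ang <- runif(1, 0, 2 * pi)
          px <- x[v] + len * cos(ang)
          py <- y[v] + len * sin(ang)
          xs <- c(x, px)
          ys <- c(y, py)
          if (!cpp_segment_conflicts(xs, ys, edges, v, length(xs))) {
            x <- xs
            y <- ys
            edges <- rbind(edges, c(v, length(xs)))
            placed <- TRUE
            break
          }
          if (try %% 10 == 0) len <- len / 2
        }
        if (!placed) stop("could not place a non-crossing arteriole stub")
      }
      edges
    })
  }
  deg <- tabulate(edges, nbins = n_b + n_stub)
  type <- c(ifelse(deg[seq_len(n_b)] == 1, "endpoint", "branch"),
            rep("penetrating_arteriole", n_stub))
  nodes <- data.frame(id = sprintf("n%d", seq_len(n_b + n_stub)),
                      x = x, y = y, type = type, stringsAsFactors = FALSE)
  spatial_network(nodes, edges,
                  name = sprintf("vasculature-a%.3f-s%d", cfg$target_alpha,
                                 cfg$seed))
}
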