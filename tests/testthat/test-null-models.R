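test_that("euclidean MST is the minimal spanning tree", {
  sq <- make_fixture("square")
  mst <- euclidean_mst(sq)
  expect_equal(n_edges(mst), 3)
  expect_equal(wiring_length(mst), 3)

  # collinear points: the chain
  coll <- snet(c(0, 2, 1, 5), c(0, 0, 0, 0),
               cbind(1:3, 2:4), allow_disconnected = TRUE)
  expect_equal(wiring_length(euclidean_mst(coll)), 5)

  # brute-force over all labelled spanning trees of 6 random points
  for (s in 1:3) {
    p <- rpoints(6, s + 60)
    carrier <- snet(p$x, p$y, cbind(1:5, 2:6))
    w <- wiring_length(euclidean_mst(carrier))
    expect_equal(w, brute_mst_length(p$x, p$y), tolerance = 1e-12)
  }

  # independent implementation cross-check on a larger set
  p <- rpoints(60, 77)
  carrier <- snet(p$x, p$y, cbind(1:59, 2:60))
  D <- distance_matrix(carrier)
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  w_ref <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(wiring_length(euclidean_mst(carrier)), w_ref,
               tolerance = 1e-10)
})

test_that("greedy triangulation is planar, maximal, with 3N - 3 - h edges", {
  # 3 non-collinear points: the triangle
  tri <- greedy_triangulation(snet(c(0, 1, 0), c(0, 0, 1),
                                   rbind(c(1, 2), c(2, 3))))
  expect_equal(n_edges(tri), 3)

  # unit square: 4 sides plus exactly one diagonal, deterministic tie-break
  gt_sq <- greedy_triangulation(make_fixture("square"))
  expect_equal(n_edges(gt_sq), 5)
  diag_edges <- gt_sq$edges[edge_lengths(gt_sq) > 1.2, ]
  expect_equal(nrow(diag_edges), 1)

  crossings <- get("cpp_count_crossings", envir = asNamespace("planarnet"))
  conflicts <- get("cpp_segment_conflicts", envir = asNamespace("planarnet"))
  for (n in c(10, 25, 50)) {
    p <- rpoints(n, n)
    carrier <- snet(p$x, p$y, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
    gt <- greedy_triangulation(carrier)
    h <- length(chull(p$x, p$y))
    expect_equal(n_edges(gt), 3 * n - 3 - h)
    expect_equal(crossings(p$x, p$y, gt$edge_idx), 0)
    # maximality: every absent pair conflicts with an accepted edge
    pairs <- t(utils::combn(n, 2))
    present <- paste(gt$edge_idx[, 1], gt$edge_idx[, 2])
    absent <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% present), ,
                    drop = FALSE]
    ok <- vapply(seq_len(nrow(absent)), function(k)
      conflicts(p$x, p$y, gt$edge_idx, absent[k, 1], absent[k, 2]),
      logical(1))
    expect_true(all(ok))
  }

  expect_warning(chain <- greedy_triangulation(
    snet(c(0, 1, 2, 3), c(0, 0, 0, 0), cbind(1:3, 2:4))), "collinear")
  expect_equal(n_edges(chain), 3)
})

test_that("rewired ensembles preserve degrees and connectivity", {
  net <- generate_mycelium_like(
    generator_config(80, target_alpha = 0.12, seed = 5, kind = "mycelium"))
  ens <- degree_preserving_rewire(net, n_members = 5, seed = 2)
  for (member in ens$members) {
    expect_equal(sort(node_degrees(member)), sort(node_degrees(net)))
    expect_equal(node_degrees(member), node_degrees(net))  # per node
    expect_true(igraph::is_connected(as_igraph(member)))
    expect_equal(member$nodes, net$nodes)
  }
  expect_true(all(ens$info$accepted > 0))

  # cycle(4): every degree-preserving connected simple graph is a 4-cycle
  c4 <- make_fixture("cycle", 4)
  ens4 <- degree_preserving_rewire(c4, n_members = 4, seed = 1)
  for (member in ens4$members) {
    expect_equal(node_degrees(member), rep(2L, 4))
    expect_true(igraph::is_connected(as_igraph(member)))
  }

  # star: no valid swap exists; members equal source and are flagged
  st <- make_fixture("star", 6)
  ens_st <- degree_preserving_rewire(st, n_members = 3, seed = 1)
  expect_true(all(ens_st$info$flagged))
  expect_equal(ens_st$members[[1]]$edge_idx, st$edge_idx)
})

test_that("ensemble normalisation guards against zero means", {
  expect_equal(ensemble_normalize(3, c(3, 3, 3))$value, 1)
  expect_equal(ensemble_normalize(3, c(3, 3, 3))$ensemble_sd, 0)
  expect_warning(z <- ensemble_normalize(0.5, c(0, 0, 0)), "zero")
  expect_true(is.na(z$value))
})

test_that("wiring is sandwiched between MST and GT for generated networks", {
  for (s in 1:3) {
    net <- generate_mycelium_like(
      generator_config(70, target_alpha = 0.1, seed = s, kind = "mycelium"))
    w <- wiring_length(net)
    expect_lte(wiring_length(euclidean_mst(net)), w + 1e-12)
    expect_gte(wiring_length(greedy_triangulation(net)), w - 1e-12)
  }
})
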