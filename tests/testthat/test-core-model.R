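test_that("construction validates and canonicalises edges", {
  sq <- make_fixture("square")
  expect_equal(n_nodes(sq), 4)
  expect_equal(n_edges(sq), 4)

  # reversed duplicates collapse to a single undirected edge
  net <- snet(c(0, 1), c(0, 0), rbind(c(1, 2), c(2, 1)))
  expect_equal(n_edges(net), 1)

  nodes <- data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 0))
  expect_error(spatial_network(nodes, data.frame(source = "a", target = "z")),
               "unknown node id")
  expect_error(spatial_network(nodes, data.frame(source = "a", target = "a")),
               "self-loop")
  expect_error(spatial_network(data.frame(id = c("a", "b"),
                                          x = c("p", "q"), y = c(0, 0)),
                               data.frame(source = "a", target = "b")),
               "non-numeric")
  expect_error(snet(c(0, 1, 5), c(0, 0, 5), cbind(1, 2)), "disconnected")
  expect_silent(snet(c(0, 1, 5), c(0, 0, 5), cbind(1, 2),
                     allow_disconnected = TRUE))
  # zero-length edges are an error, merely duplicated coordinates a warning
  expect_error(snet(c(0, 0), c(1, 1), cbind(1, 2)), "zero-length")
  expect_warning(snet(c(0, 0, 1), c(1, 1, 0), rbind(c(1, 3), c(2, 3))),
                 "duplicate")
})

test_that("CSV and GraphML round trips reproduce the network exactly", {
  cfg <- generator_config(60, target_alpha = 0.1, seed = 4, kind = "mycelium")
  net <- generate_mycelium_like(cfg)
  tmp <- file.path(tempdir(), "rt")
  write_network(net, tmp)
  back <- load_network(paste0(tmp, "-nodes.csv"), paste0(tmp, "-edges.csv"))
  expect_equal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$type, net$nodes$type)
  expect_equal(back$nodes$x, net$nodes$x, tolerance = 1e-9)
  expect_equal(back$edges, net$edges)

  gml <- file.path(tempdir(), "rt.graphml")
  write_graphml(net, gml)
  back2 <- read_graphml(gml)
  expect_equal(back2$nodes$id, net$nodes$id)
  expect_equal(back2$nodes$type, net$nodes$type)
  expect_equal(back2$nodes$y, net$nodes$y, tolerance = 1e-12)
  expect_equal(back2$edge_idx, net$edge_idx)

  # single node, no edges
  one <- spatial_network(data.frame(id = "a", x = 0, y = 0), NULL)
  write_network(one, file.path(tempdir(), "one"))
  back3 <- load_network(file.path(tempdir(), "one-nodes.csv"),
                        file.path(tempdir(), "one-edges.csv"))
  expect_equal(n_nodes(back3), 1)
  expect_equal(n_edges(back3), 0)
})

test_that("distance matrix is Euclidean and rigid-motion invariant", {
  net <- snet(c(0, 3), c(0, 4), cbind(1, 2))
  expect_equal(distance_matrix(net)[1, 2], 5)

  sq <- make_fixture("square")
  D <- distance_matrix(sq)
  expect_equal(sort(D[upper.tri(D)]), c(1, 1, 1, 1, sqrt(2), sqrt(2)))
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)

  # translation + rotation leave D unchanged (relative tolerance 1e-9)
  p <- rpoints(40, 11)
  net1 <- snet(p$x, p$y, cbind(seq_len(39), seq_len(39) + 1))
  th <- 0.83
  net2 <- snet(cos(th) * p$x - sin(th) * p$y + 5,
               sin(th) * p$x + cos(th) * p$y - 2,
               cbind(seq_len(39), seq_len(39) + 1))
  expect_equal(distance_matrix(net2), distance_matrix(net1),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_warning(D0 <- distance_matrix(
    snet(c(0, 0, 1), c(1, 1, 0), rbind(c(1, 3), c(2, 3))) |>
      suppressWarnings()), "identical coordinates")
  expect_equal(D0[1, 2], 0, ignore_attr = TRUE)
})

test_that("reduce_stubs removes exactly the labelled degree-1 arterioles", {
  # triangle plus one arteriole stub
  nodes <- data.frame(id = c("a", "b", "c", "s"),
                      x = c(0, 1, 0.5, 0.1), y = c(0, 0, 1, -0.4),
                      type = c("branch", "branch", "branch",
                               "penetrating_arteriole"))
  net <- spatial_network(nodes, rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4)))
  red <- reduce_stubs(net)
  expect_equal(n_nodes(red), 3)
  expect_equal(n_edges(red), 3)

  # no labels: identity
  expect_identical(reduce_stubs(make_fixture("grid", 3))$edges,
                   make_fixture("grid", 3)$edges)

  # two stubs on the same backbone node: both removed, backbone intact
  nodes2 <- data.frame(id = c("a", "b", "c", "s1", "s2"),
                       x = c(0, 1, 0.5, -0.3, -0.31),
                       y = c(0, 0, 1, 0.1, -0.1),
                       type = c("branch", "branch", "branch",
                                "penetrating_arteriole",
                                "penetrating_arteriole"))
  net2 <- spatial_network(nodes2,
                          rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(1, 5)))
  red2 <- reduce_stubs(net2)
  expect_equal(red2$nodes$id, c("a", "b", "c"))
  # attachment degree drops by exactly the number of removed stubs
  expect_equal(node_degrees(net2)[1] - node_degrees(red2)[1], 2)
  expect_equal(node_degrees(net2)[2:3], node_degrees(red2)[2:3])

  # degree-1 arterioles only: a labelled degree-2 node survives
  v <- generate_vasculature_like(
    generator_config(80, target_alpha = 0.02, stub_fraction = 0.3, seed = 3,
                     kind = "vasculature"))
  red3 <- reduce_stubs(v)
  expect_equal(n_nodes(red3), 80 - ceiling(0.3 * 80))
  expect_false(any(red3$nodes$type == "penetrating_arteriole"))
})

test_that("validation report summarises structure", {
  rep <- validate_network(make_fixture("grid", 3))
  expect_true(rep$connected)
  expect_equal(rep$n_nodes, 9)
  expect_equal(rep$n_edges, 12)
  expect_equal(rep$duplicate_coordinate_pairs, 0)

  disc <- snet(c(0, 1, 5, 6), c(0, 0, 0, 0), rbind(c(1, 2), c(3, 4)),
               allow_disconnected = TRUE)
  rep2 <- validate_network(disc)
  expect_false(rep2$connected)
  expect_match(rep2$messages, "disconnected", all = FALSE)
})
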