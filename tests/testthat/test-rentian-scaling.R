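test_that("rent exponent fit recovers exact and noisy power laws", {
  exact <- data.frame(n = c(4, 16, 64), m = c(2, 4, 8))
  f <- suppressWarnings(fit_rent_exponent(exact))
  expect_equal(f$exponent, 0.5, tolerance = 1e-12)
  expect_equal(f$pearson_r, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  flat <- data.frame(n = c(4, 8, 16, 32, 64), m = rep(7, 5))
  expect_equal(suppressWarnings(fit_rent_exponent(flat))$exponent, 0,
               tolerance = 1e-12)

  # lognormal noise around a known exponent
  set.seed(42)
  n <- round(10^runif(500, 0.5, 2.5))
  m <- 10^(0.3 + 0.6 * log10(n) + rnorm(500, 0, 0.1))
  f2 <- fit_rent_exponent(data.frame(n = n, m = m))
  expect_lt(abs(f2$exponent - 0.6), 0.02)

  # zero / degenerate samples are excluded or rejected
  withzero <- rbind(exact, data.frame(n = c(0, 12), m = c(3, 0)))
  f3 <- suppressWarnings(fit_rent_exponent(withzero))
  expect_equal(f3$n_excluded, 2)
  expect_equal(f3$exponent, 0.5, tolerance = 1e-12)
  expect_error(fit_rent_exponent(data.frame(n = c(4, 4, 4), m = c(2, 2, 2))),
               "degenerate")
})

test_that("topological partitioning emits symmetric cuts and path-like slopes", {
  g <- make_fixture("grid", 6)
  s <- suppressWarnings(topological_partition_samples(g, runs = 2, seed = 1))
  # the two level-1 partitions share the same m (the bisection cut)
  lev1 <- s[s$level == 1 & s$run == 1, ]
  expect_equal(nrow(lev1), 2)
  expect_equal(lev1$m[1], lev1$m[2])
  expect_equal(sum(lev1$n), 36)

  # path: every optimal cut is a single edge, slope near zero
  p16 <- make_fixture("path", 16)
  sp <- suppressWarnings(topological_partition_samples(p16, runs = 2,
                                                       seed = 2))
  expect_true(all(sp$m <= 2))
  expect_lt(suppressWarnings(fit_rent_exponent(sp))$exponent, 0.15)
})

test_that("both Rent flavours recover the mesh exponent one-half", {
  g16 <- make_fixture("grid", 16)
  ts <- topological_partition_samples(g16, runs = 3, seed = 1)
  t_hat <- mean(vapply(split(ts, ts$run),
                       function(z) fit_rent_exponent(z)$exponent, numeric(1)))
  expect_lt(abs(t_hat - 0.5), 0.05)

  ps <- physical_partition_samples(g16, n_boxes = 2000, seed = 1)
  pf <- fit_rent_exponent(ps, "physical")
  expect_lt(abs(pf$exponent - 0.5), 0.05)
  expect_gt(pf$pearson_r, 0.9)
})

test_that("physical boxes respect the hull and exclude empty samples", {
  net <- generate_mycelium_like(
    generator_config(150, target_alpha = 0.12, seed = 6, kind = "mycelium"))
  s <- physical_partition_samples(net, n_boxes = 800, seed = 3)
  expect_equal(nrow(s), 800)
  # boxes were drawn inside the hull, so none can contain every node
  expect_true(all(s$n < n_nodes(net)))
  f <- fit_rent_exponent(s, "physical")
  expect_equal(f$n_samples + f$n_excluded, 800)
  expect_error(physical_partition_samples(
    snet(c(0, 1, 2), c(0, 0, 0), cbind(1:2, 2:3))), "collinear")
})

test_that("adding long-range shortcuts raises the physical exponent", {
  g <- make_fixture("grid", 12)
  base <- fit_rent_exponent(
    physical_partition_samples(g, n_boxes = 1500, seed = 4),
    "physical")$exponent
  wins <- 0
  for (s in 1:5) {
    set.seed(s + 90)
    extra <- t(replicate(30, sort(sample.int(144, 2))))
    aug <- snet(g$nodes$x, g$nodes$y, rbind(g$edge_idx, extra))
    p_aug <- fit_rent_exponent(
      physical_partition_samples(aug, n_boxes = 1500, seed = 4),
      "physical")$exponent
    if (p_aug > base) wins <- wins + 1
  }
  expect_gte(wins, 4)  # one-sided sign test over seeds
})

test_that("rent summary combines exponents, ratios and the p_min bound", {
  net <- generate_mycelium_like(
    generator_config(150, target_alpha = 0.14, seed = 2, kind = "mycelium"))
  ens <- degree_preserving_rewire(net, n_members = 4, seed = 5)
  rs <- rent_summary(net, ens, runs = 2, n_boxes = 1000, seed = 7)
  expect_equal(rs$p_min, max(0.5, rs$t))
  expect_true(rs$t >= 0 && rs$t <= 1)
  expect_true(rs$p >= 0 && rs$p <= 1)
  expect_equal(rs$ratio_p_min, rs$p_min / rs$p)
  expect_equal(length(rs$p_rewire), 4)

  # ensemble of copies of the source: ratios collapse to 1, delta to 0
  clone_ens <- structure(list(kind = "rewired",
                              members = list(net, net, net),
                              source_name = net$name, seeds = 1:3,
                              info = NULL), class = "null_ensemble")
  rs2 <- rent_summary(net, clone_ens, runs = 2, n_boxes = 800, seed = 9)
  expect_equal(rs2$p_tilde, 1, tolerance = 1e-12)
  expect_lt(abs(rs2$t_tilde - 1), 0.1)
  # sub-mesh exponents: p_min pinned at 1/2 on both sides, so delta vanishes
  expect_equal(rs2$delta, 0, tolerance = 1e-12)

  expect_error(rent_summary(net, structure(list(members = list(net, net)),
                                           class = "null_ensemble"),
                            runs = 1, n_boxes = 500, seed = 1), "3 usable")
})
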