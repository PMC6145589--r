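test_that("robustness R is exact on the 3-node path and deterministic", {
  p3 <- make_fixture("path", 3)
  r <- robustness_R(p3, trials = 8, seed = 1)
  # halving the LCC of a 2-edge path always requires removing both edges
  expect_true(all(r$values == 100))
  expect_equal(r$R_mean, 100)
  expect_equal(r$R_sd, 0)

  r2 <- robustness_R(p3, trials = 8, seed = 1)
  expect_identical(r2$values, r$values)
  expect_error(robustness_R(spatial_network(data.frame(id = "a", x = 0, y = 0),
                                            NULL)), "2 nodes")
})

test_that("denser graphs are more robust than trees on the same nodes", {
  k6 <- make_fixture("complete", 6)
  tree <- euclidean_mst(k6)
  r_k <- robustness_R(k6, trials = 20, seed = 3)$R_mean
  r_t <- robustness_R(tree, trials = 20, seed = 3)$R_mean
  expect_gt(r_k, r_t)

  # trees vs their greedy triangulation, across seeds
  for (s in 1:5) {
    p <- rpoints(40, s + 200)
    carrier <- snet(p$x, p$y, cbind(1:39, 2:40))
    mst <- euclidean_mst(carrier)
    gt <- greedy_triangulation(carrier)
    expect_lt(robustness_R(mst, trials = 10, seed = s)$R_mean,
              robustness_R(gt, trials = 10, seed = s)$R_mean)
  }
})

test_that("more trials shrink the standard error of R", {
  net <- random_planar_net(40, alpha = 0.08, seed = 12)
  r10 <- robustness_R(net, trials = 10, seed = 5)
  r40 <- robustness_R(net, trials = 40, seed = 5)
  expect_lt(r40$R_sd / sqrt(40), r10$R_sd / sqrt(10))
})

test_that("efficiency decline starts at one and drops on damaged trees", {
  net <- random_planar_net(30, alpha = 0.1, seed = 7)
  cur <- efficiency_decline(net, f_max = 0.1, trials = 5, seed = 2)
  expect_equal(cur$mean_ratio[1], 1)
  expect_equal(cur$sd_ratio[1], 0)
  expect_true(all(cur$mean_ratio <= 1 + 1e-12))

  # any removal disconnects a tree and strictly lowers efficiency
  tree <- euclidean_mst(net)
  f_one <- 1.01 / n_edges(tree)  # exactly one edge removed
  cur_t <- efficiency_decline(tree, f_max = f_one, df = f_one, trials = 5,
                              seed = 3)
  expect_lt(cur_t$mean_ratio[2], 1)

  # determinism
  cur2 <- efficiency_decline(net, f_max = 0.1, trials = 5, seed = 2)
  expect_identical(cur2$mean_ratio, cur$mean_ratio)
})

test_that("decline slope is the OLS slope over the initial window", {
  fake <- structure(list(f = seq(0, 0.2, by = 0.004),
                         mean_ratio = 1 - 2 * seq(0, 0.2, by = 0.004)),
                    class = "decline_curve")
  expect_equal(decline_slope(fake), -2, tolerance = 1e-12)
  flat <- structure(list(f = seq(0, 0.1, by = 0.004),
                         mean_ratio = rep(1, 26)), class = "decline_curve")
  expect_equal(decline_slope(flat), 0, tolerance = 1e-12)
  expect_error(decline_slope(structure(list(f = c(0, 0.2),
                                            mean_ratio = c(1, 0.5)),
                                       class = "decline_curve")), "3 grid")
})

test_that("sparse vasculature-like nets decline faster than loopy mycelium-like", {
  s_m <- s_v <- numeric(8)
  for (s in 1:8) {
    m <- generate_mycelium_like(
      generator_config(120, target_alpha = 0.144, seed = s,
                       kind = "mycelium"))
    v <- generate_vasculature_like(
      generator_config(120, target_alpha = 0.022, stub_fraction = 0.4,
                       seed = s, kind = "vasculature"))
    s_m[s] <- decline_slope(efficiency_decline(m, f_max = 0.1, trials = 10,
                                               seed = 70 + s))
    s_v[s] <- decline_slope(efficiency_decline(v, f_max = 0.1, trials = 10,
                                               seed = 170 + s))
  }
  expect_lt(mean(s_v), mean(s_m))  # more negative: faster decline
})

test_that("the GT decline curve dominates the MST curve on matched points", {
  p <- rpoints(80, 404)
  carrier <- snet(p$x, p$y, cbind(1:79, 2:80))
  mst <- euclidean_mst(carrier)
  gt <- greedy_triangulation(carrier)
  cm <- efficiency_decline(mst, f_max = 0.2, df = 0.02, trials = 8, seed = 5)
  cg <- efficiency_decline(gt, f_max = 0.2, df = 0.02, trials = 8, seed = 5)
  inner <- cm$f > 0
  expect_true(all(cg$mean_ratio[inner] > cm$mean_ratio[inner]))
})
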