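#' Structural robustness under random edge removal
#'
#' Edges are removed one at a time in uniformly random order; `R` is the
#' percentage of edges that had to be removed for the size of the largest
#' connected component (LCC) to first drop below half the node count. Random
#' removal order makes `R` stochastic, so it is averaged over `trials`
#' independent removal sequences. The halving threshold is strict
#' (`LCC < N/2`); if the LCC never drops below the threshold (only possible
#' for N = 2) the full removal, `R = 100`, is reported.
#'
#' @param net a connected [spatial_network] with at least 2 nodes
#' @param trials number of random removal sequences (default 20)
#' @param seed master seed; per-trial sub-seeds are derived from it
#' @return a `robustness_result` list: `R_mean`, `R_sd`, `values` (per
#'   trial), `trials`, `seed`
#' @export
robustness_R <- function(net, trials = 20, seed = 1) {
  N <- n_nodes(net)
  M <- n_edges(net)
  if (N < 2) stop("robustness requires at least 2 nodes")
  if (M < 1) stop("robustness requires at least 1 edge")
  seeds <- spawn_seeds(seed, trials)
  vals <- numeric(trials)
  for (tr in seq_len(trials)) {
    perm <- with_seed(seeds[tr], sample.int(M))
    prof <- cpp_lcc_profile(N, net$edge_idx, perm)  # prof[k+1]: after k removals
    below <- which(prof < N / 2)
    k <- if (length(below)) below[1] - 1L else M
    vals[tr] <- 100 * k / M
  }
  structure(list(R_mean = mean(vals), R_sd = sd(vals), values = vals,
                 trials = trials, seed = seed),
            class = "robustness_result")
}

#' Decline of physical efficiency under random edge removal
#'
#' For each removal fraction `f` on the grid `0, df, ..., f_max`, an
#' independent uniformly random subset of `floor(f * M)` edges is removed
#' and the global physical efficiency of the damaged (possibly
#' disconnected; unreachable pairs contribute zero) network is computed.
#' The reported curve is the mean over `trials` of `E_p(f) / E_p(0)`.
#' Removal subsets are independent across fractions and trials.
#'
#' @param net a connected [spatial_network]
#' @param f_max largest removal fraction (default 0.6)
#' @param df grid step (default 0.004)
#' @param trials removal subsets per fraction (default 20)
#' @param seed master seed
#' @return a `decline_curve` list: `f`, `mean_ratio`, `sd_ratio`, `trials`,
#'   `seed`
#' @export
efficiency_decline <- function(net, f_max = 0.6, df = 0.004, trials = 20,
                               seed = 1) {
  N <- n_nodes(net)
  M <- n_edges(net)
  g <- as_igraph(net)
  w <- edge_lengths(net)
  eff_avg <- function(graph, weights) {
    d <- igraph::distances(graph, weights = weights)
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv) / (N * (N - 1))
  }
  e0 <- eff_avg(g, w)
  if (e0 <= 0) stop("network has zero physical efficiency")
  f <- seq(0, f_max, by = df)
  seeds <- spawn_seeds(seed, length(f))
  mr <- numeric(length(f))
  sr <- numeric(length(f))
  for (i in seq_along(f)) {
    nrem <- floor(f[i] * M)
    if (nrem == 0) {
      mr[i] <- 1
      sr[i] <- 0
      next
    }
    ratios <- with_seed(seeds[i], {
      vapply(seq_len(trials), function(tr) {
        drop <- sample.int(M, nrem)
        eff_avg(igraph::delete_edges(g, drop), w[-drop]) / e0
      }, numeric(1))
    })
    mr[i] <- mean(ratios)
    sr[i] <- sd(ratios)
  }
  structure(list(f = f, mean_ratio = mr, sd_ratio = sr, trials = trials,
                 seed = seed),
            class = "decline_curve")
}

#' Initial slope of an efficiency-decline curve
#'
#' Ordinary least-squares slope of the mean efficiency ratio against the
#' removal fraction, over `f` in `[0, f_limit]` (default 0.1). More negative
#' slopes indicate networks whose transport efficiency degrades faster under
#' random damage.
#'
#' @param curve a `decline_curve` from [efficiency_decline()]
#' @param f_limit upper end of the fit window (default 0.1)
#' @return the slope (a single number, negative for any real network)
#' @export
decline_slope <- function(curve, f_limit = 0.1) {
  keep <- curve$f <= f_limit + 1e-12
  if (sum(keep) < 3) stop("need at least 3 grid points below f_limit")
  unname(coef(lm(curve$mean_ratio[keep] ~ curve$f[keep]))[2])
}
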