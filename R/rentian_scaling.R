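#' Topological Rentian partition samples
#'
#' Recursive min-cut bi-partitioning: the network is split into halves,
#' quarters, and so on, each split attempting to minimise the number of
#' edges crossing between the two sides (spectral Fiedler-vector split with
#' greedy boundary refinement, balance tolerance 10%). Each bisection
#' records, for both of the partitions it creates, the pair (`n` = nodes
#' inside the partition, `m` = edges crossing the partition boundary drawn
#' by that bisection, i.e. the cut between the two halves). Attributing the
#' cut -- rather than every edge leaving the partition in the full network
#' -- keeps the estimator free of the outer-surface saturation that
#' otherwise biases the exponent downward on finite networks; on an L x L
#' mesh it recovers the theoretical exponent 1/2. A partition is split
#' further while it still has at least `min_partition` nodes. Several
#' randomized runs (refinement tie-breaks differ) are pooled.
#'
#' @param net a connected [spatial_network] with `N >= 2 * min_partition`
#' @param runs number of independent partitioning runs (default 5)
#' @param min_partition stop splitting below this size (default 8)
#' @param seed master seed
#' @return data frame with columns `n`, `m`, `level`, `run`
#' @export
topological_partition_samples <- function(net, runs = 5, min_partition = 8,
                                          seed = 1) {
  N <- n_nodes(net)
  if (N < 2 * min_partition) stop("network too small to partition")
  eidx <- net$edge_idx
  adj <- lapply(seq_len(N), function(i) integer(0))
  for (k in seq_len(nrow(eidx))) {
    a <- eidx[k, 1]; b <- eidx[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seeds <- spawn_seeds(seed, runs)
  out <- vector("list", runs)
  for (r in seq_len(runs)) {
    samples <- list()
    with_seed(seeds[r], {
      recurse <- function(members, level) {
        halves <- bisect_partition(members, adj, N)
        if (length(halves) < 2) return(invisible())
        inA <- logical(N)
        inA[halves[[1]]] <- TRUE
        inB <- logical(N)
        inB[halves[[2]]] <- TRUE
        cut <- sum((inA[eidx[, 1]] & inB[eidx[, 2]]) |
                   (inB[eidx[, 1]] & inA[eidx[, 2]]))
        for (h in halves) {
          samples[[length(samples) + 1]] <<-
            c(n = length(h), m = cut, level = level)
          if (length(h) >= min_partition) recurse(h, level + 1)
        }
      }
      recurse(seq_len(N), 1L)
    })
    df <- as.data.frame(do.call(rbind, samples))
    df$run <- r
    out[[r]] <- df
  }
  do.call(rbind, out)
}

# Balanced two-way split of `members` minimising (greedily) the cut within
# the induced subgraph. Spectral Fiedler split + single-move refinement with
# a 10% balance tolerance. Falls back to grouping connected components when
# the induced subgraph is disconnected. Uses the current RNG stream for
# tie-breaks.
bisect_partition <- function(members, adj, N) {
  n <- length(members)
  if (n < 2) return(list(members))
  pos <- integer(N)
  pos[members] <- seq_len(n)
  # induced adjacency (local indices)
  ladj <- lapply(members, function(v) {
    nb <- adj[[v]]
    pos[nb[nb %in% members]]
  })
  # connected components of the induced subgraph
  comp <- integer(n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    stack <- s
    comp[s] <- nc
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- ladj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- nc
      stack <- c(stack, new)
    }
  }
  if (nc > 1L) {
    # greedy balance of whole components into two bins
    sizes <- tabulate(comp, nc)
    ord <- order(sizes, decreasing = TRUE)
    bin <- integer(nc)
    tot <- c(0L, 0L)
    for (cid in ord) {
      b <- which.min(tot)
      bin[cid] <- b
      tot[b] <- tot[b] + sizes[cid]
    }
    side <- bin[comp]
    if (all(side == side[1])) side[1] <- 3L - side[1]  # force two sides
    return(list(members[side == 1L], members[side == 2L]))
  }
  # Fiedler vector of the induced Laplacian (dense; partitions stay small)
  A <- matrix(0, n, n)
  for (v in seq_len(n)) A[v, ladj[[v]]] <- 1
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE)
  f <- ev$vectors[, n - 1L]
  f <- f + runif(n) * 1e-9  # randomized tie-break
  ord <- order(f)
  half <- n %/% 2L
  side <- integer(n)
  side[ord[seq_len(half)]] <- 1L
  side[ord[-seq_len(half)]] <- 2L
  # greedy refinement: move nodes with positive cut gain, keep balance >= 45%
  min_side <- max(1L, floor(0.45 * n))
  for (it in seq_len(50L)) {
    to2 <- vapply(seq_len(n), function(v) sum(side[ladj[[v]]] == 2L),
                  numeric(1))
    degs <- lengths(ladj)
    gain <- ifelse(side == 1L, to2 - (degs - to2), (degs - to2) - to2)
    sz <- tabulate(side, 2L)
    movable <- (side == 1L & sz[1] - 1L >= min_side) |
               (side == 2L & sz[2] - 1L >= min_side)
    gain[!movable] <- -Inf
    g <- max(gain)
    if (!is.finite(g) || g <= 0) break
    best <- which(gain == g)
    v <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
    side[v] <- 3L - side[v]
  }
  list(members[side == 1L], members[side == 2L])
}

# half-plane test: which points lie inside the convex hull polygon
points_in_hull <- function(px, py, hx, hy) {
  nh <- length(hx)
  inside <- rep(TRUE, length(px))
  for (k in seq_len(nh)) {
    a <- k
    b <- if (k == nh) 1L else k + 1L
    cr <- (hx[b] - hx[a]) * (py - hy[a]) - (hy[b] - hy[a]) * (px - hx[a])
    inside <- inside & cr <= 0  # chull vertices come in clockwise order
  }
  inside
}

#' Physical Rentian partition samples
#'
#' Samples `n_boxes` axis-aligned square partitions of the embedded network.
#' Box side lengths are drawn uniformly between `s_min` (the side whose
#' expected node content is 2, from the global node density over the convex
#' hull) and `s_max` (the largest side for which at least 1% of candidate
#' boxes fit inside the hull); centres are uniform, and a box is accepted
#' only if all four corners lie inside the convex hull of the nodes, which
#' avoids boundary effects. Per box, `n` counts the nodes inside the
#' half-open square and `m` the edges with exactly one endpoint inside.
#'
#' @param net a [spatial_network] with at least 3 non-collinear nodes
#' @param n_boxes number of accepted boxes to sample (default 5000)
#' @param seed master seed
#' @param s_range optional numeric `c(s_min, s_max)` overriding the automatic
#'   side-length range
#' @return data frame with columns `n`, `m`, `side`
#' @export
physical_partition_samples <- function(net, n_boxes = 5000, seed = 1,
                                       s_range = NULL) {
  x <- net$nodes$x
  y <- net$nodes$y
  hidx <- chull(x, y)
  if (length(hidx) < 3) stop("degenerate (collinear) convex hull")
  hx <- x[hidx]
  hy <- y[hidx]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  eidx <- net$edge_idx
  N <- length(x)

  with_seed(seed, {
    if (is.null(s_range)) {
      s_min <- sqrt(2 * area / N)
      # binary search for the largest side with >= 1% containment acceptance
      accept_rate <- function(s) {
        cx <- runif(1000, min(hx), max(hx))
        cy <- runif(1000, min(hy), max(hy))
        ok <- points_in_hull(cx - s / 2, cy - s / 2, hx, hy) &
              points_in_hull(cx + s / 2, cy - s / 2, hx, hy) &
              points_in_hull(cx + s / 2, cy + s / 2, hx, hy) &
              points_in_hull(cx - s / 2, cy + s / 2, hx, hy)
        mean(ok)
      }
      lo <- s_min
      hi <- max(max(hx) - min(hx), max(hy) - min(hy))
      for (it in seq_len(12)) {
        mid <- (lo + hi) / 2
        if (accept_rate(mid) >= 0.01) lo <- mid else hi <- mid
      }
      s_max <- max(lo, s_min * 1.5)
    } else {
      s_min <- s_range[1]
      s_max <- s_range[2]
    }

    got <- 0L
    res_n <- integer(n_boxes)
    res_m <- integer(n_boxes)
    res_s <- numeric(n_boxes)
    for (batch in seq_len(500)) {
      if (got >= n_boxes) break
      nb <- 4L * (n_boxes - got)
      s <- runif(nb, s_min, s_max)
      cx <- runif(nb, min(hx), max(hx))
      cy <- runif(nb, min(hy), max(hy))
      ok <- points_in_hull(cx - s / 2, cy - s / 2, hx, hy) &
            points_in_hull(cx + s / 2, cy - s / 2, hx, hy) &
            points_in_hull(cx + s / 2, cy + s / 2, hx, hy) &
            points_in_hull(cx - s / 2, cy + s / 2, hx, hy)
      s <- s[ok]; cx <- cx[ok]; cy <- cy[ok]
      if (!length(s)) next
      take <- seq_len(min(length(s), n_boxes - got))
      for (k in take) {
        x0 <- cx[k] - s[k] / 2
        y0 <- cy[k] - s[k] / 2
        inside <- x >= x0 & x < x0 + s[k] & y >= y0 & y < y0 + s[k]
        got <- got + 1L
        res_n[got] <- sum(inside)
        res_m[got] <- sum(xor(inside[eidx[, 1]], inside[eidx[, 2]]))
        res_s[got] <- s[k]
      }
    }
    if (got < n_boxes)
      warning(sprintf("only %d of %d boxes accepted", got, n_boxes))
    data.frame(n = res_n[seq_len(got)], m = res_m[seq_len(got)],
               side = res_s[seq_len(got)])
  })
}

#' Fit a Rent exponent from partition samples
#'
#' Ordinary least squares of `log10(m)` on `log10(n)`; the slope is the Rent
#' exponent. Samples with `n = 0` or `m = 0` are excluded (their logarithm is
#' undefined); the exclusion count is reported.
#'
#' @param samples data frame with columns `n` and `m` (from
#'   [topological_partition_samples()] or [physical_partition_samples()])
#' @param flavor `"topological"` or `"physical"`, recorded in the result
#' @return a `rent_fit` list: `exponent`, `pearson_r`, `r_squared`,
#'   `n_samples`, `n_excluded`, `n_range`, `flavor`
#' @export
fit_rent_exponent <- function(samples, flavor = "topological") {
  keep <- samples$n > 0 & samples$m > 0
  s <- samples[keep, , drop = FALSE]
  if (nrow(s) < 3) stop("too few usable partition samples")
  ln <- log10(s$n)
  lm_ <- log10(s$m)
  if (length(unique(ln)) < 2) stop("degenerate samples: all n identical")
  if (nrow(s) < 10 || diff(range(ln)) < 1)
    warning("fewer than 10 samples or less than one decade in n")
  fit <- lm(lm_ ~ ln)
  r <- if (sd(lm_) == 0) 0 else cor(ln, lm_)
  structure(list(exponent = unname(coef(fit)[2]), pearson_r = r,
                 r_squared = r^2, n_samples = nrow(s),
                 n_excluded = sum(!keep), n_range = range(s$n),
                 flavor = flavor),
            class = "rent_fit")
}

#' Rentian scaling summary with rewired-ensemble context
#'
#' Computes the topological Rent exponent `t` (mean of per-run fits), the
#' physical Rent exponent `p`, and their ratios to the mean exponents of a
#' connected degree-preserving rewired ensemble whose members keep the
#' source node positions. The theoretical minimum physical exponent is
#' `p_min = max(1 - 1/d_E, t)` with Euclidean embedding dimension `d_E = 2`,
#' so `p_min = max(0.5, t)`; exponents close to `p_min` indicate a
#' wiring-efficient spatial embedding. The reported `delta`
#' (`p_min/p - <p_min_rewire/p_rewire>`) is positive for networks embedded
#' more cost-efficiently than their rewired counterparts. The bound
#' `t >= 1 - 1/d_T` also yields an implied lower bound on the topological
#' dimension, `d_T >= 1/(1 - t)`.
#'
#' @param net a connected [spatial_network]
#' @param ensemble a rewired `null_ensemble` of `net` (see
#'   [degree_preserving_rewire()]); at least 3 usable members
#' @param runs partitioning runs per network for the topological exponent
#' @param n_boxes physical boxes per network
#' @param min_partition recursion stop size
#' @param seed master seed
#' @return a `rent_summary` list with `t`, `t_sd`, `p`, `p_min`, `t_tilde`,
#'   `p_tilde`, `ratio_p_min`, `delta`, `d_T_lower`, `d_E` and the
#'   underlying fits
#' @export
rent_summary <- function(net, ensemble, runs = 5, n_boxes = 5000,
                         min_partition = 8, seed = 1) {
  seeds <- spawn_seeds(seed, 2 + length(ensemble$members))
  topo <- topological_partition_samples(net, runs = runs,
                                        min_partition = min_partition,
                                        seed = seeds[1])
  t_runs <- vapply(split(topo, topo$run),
                   function(s) fit_rent_exponent(s, "topological")$exponent,
                   numeric(1))
  t_val <- mean(t_runs)
  phys_samples <- physical_partition_samples(net, n_boxes = n_boxes,
                                             seed = seeds[2])
  p_fit <- fit_rent_exponent(phys_samples, "physical")
  p_val <- p_fit$exponent

  t_rew <- numeric(0)
  p_rew <- numeric(0)
  for (k in seq_along(ensemble$members)) {
    member <- ensemble$members[[k]]
    ok <- TRUE
    tryCatch({
      tk <- topological_partition_samples(member, runs = runs,
                                          min_partition = min_partition,
                                          seed = seeds[2 + k])
      tkv <- mean(vapply(split(tk, tk$run),
                         function(s) fit_rent_exponent(s, "topological")$exponent,
                         numeric(1)))
      # identical coordinates and seed: identical boxes, member edges differ
      pk <- physical_partition_samples(member, n_boxes = n_boxes,
                                       seed = seeds[2])
      pkv <- fit_rent_exponent(pk, "physical")$exponent
      t_rew <- c(t_rew, tkv)
      p_rew <- c(p_rew, pkv)
    }, error = function(e) {
      warning(sprintf("ensemble member %d dropped: %s", k, conditionMessage(e)))
      ok <<- FALSE
    })
  }
  if (length(p_rew) < 3) stop("fewer than 3 usable ensemble members")

  p_min <- max(0.5, t_val)
  p_min_rew <- pmax(0.5, t_rew)
  structure(list(
    t = t_val, t_sd = sd(t_runs), t_runs = t_runs,
    p = p_val, p_fit = p_fit,
    t_tilde = t_val / mean(t_rew),
    p_tilde = p_val / mean(p_rew),
    p_min = p_min,
    ratio_p_min = p_min / p_val,
    delta = p_min / p_val - mean(p_min_rew / p_rew),
    d_E = 2,
    d_T_lower = if (t_val < 1) 1 / (1 - t_val) else Inf,
    t_rewire = t_rew, p_rewire = p_rew),
    class = "rent_summary")
}
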