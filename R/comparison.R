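#' Relative wiring, efficiency and robustness against the spatial null models
#'
#' Rescales the wiring length `W`, the global physical efficiency `E_p` and
#' the robustness `R` of a network between the values attained by its
#' Euclidean minimum spanning tree (0) and its greedy triangulation (1) on
#' the identical node positions:
#' `X_rel = (X - X_MST) / (X_GT - X_MST)`.
#' The wiring and efficiency anchors are exact; robustness is a trial
#' average, so its anchors hold only up to Monte-Carlo noise.
#'
#' @param net a connected [spatial_network]
#' @param mst,gt optional precomputed null models (must share `net`'s node
#'   positions); built on the fly when `NULL`
#' @param trials robustness trials per network (default 20)
#' @param seed master seed; independent sub-seeds are used for the empirical,
#'   MST and GT robustness runs
#' @return a `relative_measures` list: `W_rel`, `E_p_rel`, `R_rel`, and the
#'   raw triples `W`, `E_p`, `R` (each `c(net, mst, gt)`)
#' @export
relative_measures <- function(net, mst = NULL, gt = NULL, trials = 20,
                              seed = 1) {
  if (is.null(mst)) mst <- euclidean_mst(net)
  if (is.null(gt)) gt <- greedy_triangulation(net)
  D <- suppressWarnings(distance_matrix(net))
  W <- c(wiring_length(net), wiring_length(mst), wiring_length(gt))
  E <- c(physical_efficiency(net, D)$E_p, physical_efficiency(mst, D)$E_p,
         physical_efficiency(gt, D)$E_p)
  seeds <- spawn_seeds(seed, 3)
  R <- c(robustness_R(net, trials, seeds[1])$R_mean,
         robustness_R(mst, trials, seeds[2])$R_mean,
         robustness_R(gt, trials, seeds[3])$R_mean)
  if (W[3] == W[2] || E[3] == E[2] || R[3] == R[2])
    stop("degenerate null models: GT and MST coincide")
  structure(list(
    W_rel = (W[1] - W[2]) / (W[3] - W[2]),
    E_p_rel = (E[1] - E[2]) / (E[3] - E[2]),
    R_rel = (R[1] - R[2]) / (R[3] - R[2]),
    W = setNames(W, c("net", "mst", "gt")),
    E_p = setNames(E, c("net", "mst", "gt")),
    R = setNames(R, c("net", "mst", "gt"))),
    class = "relative_measures")
}

#' Two-group comparison of a network metric
#'
#' Group means, standard errors of the mean (`sd / sqrt(n)`), and a
#' two-sided two-sample t-test. The default is the pooled-variance
#' (Student's) test; set `var_equal = FALSE` for Welch's test.
#'
#' @param values numeric vector of per-network metric values
#' @param group factor (or character) with exactly two levels, parallel to
#'   `values`
#' @param metric metric name recorded in the output
#' @param var_equal use the pooled-variance test (default `TRUE`)
#' @param alpha significance threshold (default 0.05)
#' @return one-row data frame: metric, per-group n / mean / SEM, `t`, `df`,
#'   `p`, `significant`
#' @export
group_compare <- function(values, group, metric = "metric", var_equal = TRUE,
                          alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (length(values) != length(group)) stop("values and group lengths differ")
  v1 <- values[group == levels(group)[1]]
  v2 <- values[group == levels(group)[2]]
  if (length(v1) < 2 || length(v2) < 2)
    stop("each group needs at least 2 members")
  sem <- function(v) sd(v) / sqrt(length(v))
  if (sd(v1) == 0 && sd(v2) == 0) {
    warning("zero pooled variance; p undefined")
    tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  } else {
    tt <- t.test(v1, v2, var.equal = var_equal)
  }
  data.frame(metric = metric,
             group1 = levels(group)[1], group2 = levels(group)[2],
             n1 = length(v1), n2 = length(v2),
             mean1 = mean(v1), sem1 = sem(v1),
             mean2 = mean(v2), sem2 = sem(v2),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             significant = !is.na(tt$p.value) && tt$p.value < alpha,
             stringsAsFactors = FALSE)
}

#' Full comparative pipeline over a set of networks
#'
#' Computes, for every input network, the topological metrics (mean degree,
#' clustering, alpha index, topological efficiency), the Spearman
#' correlation between topological and physical edge betweenness, the
#' relative wiring/efficiency/robustness against the MST and GT null
#' models, and optionally rewired-ensemble-normalised clustering and
#' topological efficiency and a Rentian scaling summary. When two groups
#' with at least two members each are present, every metric column is
#' compared between the groups with a two-sample t-test.
#'
#' @param networks list of [spatial_network] objects (or of
#'   [generator_config()] objects, which are realised with their `kind`'s
#'   generator)
#' @param groups character vector of group labels, parallel to `networks`
#' @param seed master seed for all stochastic stages
#' @param robustness_trials trials for [robustness_R()] (default 20)
#' @param rewire_members rewired ensemble size for normalised metrics; 0
#'   disables the rewired normalisation (default 0)
#' @param include_rent compute [rent_summary()] per network (needs
#'   `rewire_members >= 3`; default `FALSE`)
#' @param rent_runs,rent_boxes Rentian sampling effort when enabled
#' @param var_equal t-test variant for the group table
#' @return a `pipeline_report` list: `records` (one row per network),
#'   `group_table` (one row per metric; `NULL` without two valid groups),
#'   `seed`
#' @export
run_pipeline <- function(networks, groups = NULL, seed = 1,
                         robustness_trials = 20, rewire_members = 0,
                         include_rent = FALSE, rent_runs = 3,
                         rent_boxes = 2000, var_equal = TRUE) {
  n <- length(networks)
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) stop("groups must parallel networks")
  if (include_rent && rewire_members < 3)
    stop("include_rent requires rewire_members >= 3")
  seeds <- spawn_seeds(seed, 3 * n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    net <- networks[[i]]
    if (inherits(net, "generator_config")) {
      net <- switch(net$kind,
                    mycelium = generate_mycelium_like(net),
                    vasculature = generate_vasculature_like(net),
                    stop("fixture configs cannot be realised automatically"))
    }
    rho <- betweenness_rank_correlation(topological_edge_betweenness(net),
                                        physical_edge_betweenness(net))
    rel <- relative_measures(net, trials = robustness_trials,
                             seed = seeds[3 * i - 2])
    row <- data.frame(
      name = net$name, group = groups[i],
      n_nodes = n_nodes(net), n_edges = n_edges(net),
      mean_degree = mean_degree(net),
      clustering = clustering_coefficient(net),
      alpha = alpha_index(net),
      E_t = topological_efficiency(net),
      rho_betweenness = rho,
      W = wiring_length(net),
      E_p = physical_efficiency(net)$E_p,
      R = robustness_R(net, robustness_trials, seeds[3 * i - 1])$R_mean,
      W_rel = rel$W_rel, E_p_rel = rel$E_p_rel, R_rel = rel$R_rel,
      stringsAsFactors = FALSE)
    if (rewire_members > 0) {
      ens <- degree_preserving_rewire(net, n_members = rewire_members,
                                      seed = seeds[3 * i])
      row$clustering_norm <- suppressWarnings(
        ensemble_normalize(row$clustering,
                           ensemble_metric(ens, clustering_coefficient))$value)
      row$E_t_norm <- ensemble_normalize(
        row$E_t, ensemble_metric(ens, topological_efficiency))$value
      if (include_rent) {
        rs <- rent_summary(net, ens, runs = rent_runs, n_boxes = rent_boxes,
                           seed = seeds[3 * i])
        row$rent_t <- rs$t
        row$rent_p <- rs$p
        row$t_tilde <- rs$t_tilde
        row$p_tilde <- rs$p_tilde
        row$ratio_p_min <- rs$ratio_p_min
        row$rent_delta <- rs$delta
      }
    }
    rows[[i]] <- row
  }
  records <- do.call(rbind, rows)

  group_table <- NULL
  tab <- table(groups)
  if (length(tab) == 2 && all(tab >= 2)) {
    metric_cols <- setdiff(names(records),
                           c("name", "group", "n_nodes", "n_edges"))
    gt_rows <- lapply(metric_cols, function(mc) {
      v <- records[[mc]]
      ok <- !is.na(v)
      if (any(table(factor(groups[ok], levels = names(tab))) < 2))
        return(NULL)
      tryCatch(suppressWarnings(
        group_compare(v[ok], groups[ok], metric = mc,
                      var_equal = var_equal)),
        error = function(e) NULL)
    })
    group_table <- do.call(rbind, gt_rows)
  }
  structure(list(records = records, group_table = group_table, seed = seed),
            class = "pipeline_report")
}

#' Write a pipeline report as a JSON bundle
#'
#' Serialises the per-network records, the group table, and the seed to a
#' single JSON file (full double precision), suitable for archiving a run
#' alongside its inputs.
#'
#' @param report a `pipeline_report` from [run_pipeline()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(list(records = report$records,
                            group_table = report$group_table,
                            seed = report$seed),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
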