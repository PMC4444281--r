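# Coexpression network construction by absolute-correlation thresholding,
# automatic threshold selection, and basic topology summaries.

#' Build a gene coexpression network at a given correlation threshold
#'
#' Adds an edge between every gene pair with `|r| >= tau` (undefined
#' correlations never form edges), then restricts the graph to its largest
#' connected component; when several components tie in size the one
#' containing the lexicographically smallest node identifier is kept. The
#' signed correlation is stored as edge attribute `r` and the threshold as
#' graph attribute `tau`.
#'
#' @param corr A [correlation_matrix()].
#' @param tau Link-strength threshold in `(0, 1]`.
#' @return A simple undirected connected [igraph::igraph].
#' @examples
#' sim <- generate_modular_expression(
#'   synthetic_spec(n_genes = 30, n_modules = 1, module_corr = 0.9, seed = 1))
#' net <- build_network(correlation_matrix(sim$expr, "E"), tau = 0.6)
#' igraph::vcount(net)
#' @export
build_network <- function(corr, tau) {
  assert_number(tau, "tau", lower = 0, upper = 1, open_lower = TRUE)
  r <- corr$r
  a <- abs(r)
  a[is.na(a)] <- -Inf
  idx <- which(a >= tau & upper.tri(a), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stopf("no edges at tau = %g (max |r| off-diagonal = %g)",
          tau, suppressWarnings(max(a[upper.tri(a)], na.rm = TRUE)),
          class = "gcntools_empty_network_error")
  }
  genes <- rownames(r)
  g <- igraph::graph_from_data_frame(
    data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
               r = r[idx], stringsAsFactors = FALSE),
    directed = FALSE)
  g <- giant_component(g)
  dropped <- length(genes) - igraph::vcount(g)
  if (dropped > 0) {
    message(sprintf("build_network: tau = %g, kept giant component with %d nodes (%d gene(s) dropped)",
                    tau, igraph::vcount(g), dropped))
  }
  g$tau <- tau
  g
}

# Largest connected component; size ties broken by the component containing
# the lexicographically smallest vertex name.
giant_component <- function(g) {
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(b) {
      min(igraph::V(g)$name[comp$membership == b])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Network connectivity (mean degree) k = 2L/N
#'
#' For an undirected network with `L` edges and `N` nodes the connectivity
#' is `k = 2L/N`, the arithmetic mean of the node degrees.
#'
#' @param net An [igraph::igraph].
#' @return The mean degree, a single number.
#' @examples
#' connectivity(igraph::make_full_graph(4))  # 3
#' @export
connectivity <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1) stopf("connectivity undefined for an empty graph")
  2 * igraph::ecount(net) / n
}

#' Degree distribution table
#'
#' Tabulates node degrees: one row per observed degree with its count and
#' normalized frequency (frequencies sum to 1; absent degrees are omitted).
#' Backing data for log-log degree-distribution plots.
#'
#' @param net An [igraph::igraph].
#' @return A data frame with columns `degree`, `count`, `freq`.
#' @export
degree_distribution_table <- function(net) {
  d <- igraph::degree(net)
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)),
             count = as.integer(tab),
             freq = as.integer(tab) / length(d))
}

#' Select the correlation threshold by component coverage and stability
#'
#' Scans an ascending grid of candidate thresholds and returns the largest
#' `tau` at which (a) the giant component still covers at least
#' `min_component_frac` of the nodes that have any edge at `tau`, and (b)
#' the community partition is stable under a small threshold perturbation:
#' the adjusted Rand index (ARI) between the partitions at `tau` and at
#' `tau +/- stability_delta` (computed on their common nodes) is at least
#' `stability_min`. This operationalizes the construction rule that nodes
#' should connect into the major component while slight threshold changes
#' leave the topology essentially unchanged.
#'
#' @param corr A [correlation_matrix()].
#' @param tau_grid Ascending vector of candidate thresholds in `(0, 1)`.
#'   Defaults mirror typical grids for DE-subset networks
#'   (`seq(0.930, 0.980, 0.005)`); whole-transcriptome networks typically
#'   need a higher grid such as `seq(0.990, 0.998, 0.001)`.
#' @param stability_delta Threshold perturbation used for the stability
#'   check. Defaults to one grid step; pass a smaller value to probe
#'   stability at a finer scale than the search grid (the perturbed
#'   networks are built ad hoc, they need not be grid points).
#' @param min_component_frac Minimum giant-component share of non-isolated
#'   nodes (default 0.8).
#' @param stability_min Minimum ARI under perturbation (default 0.8).
#' @param seed Seed for the community detection used in the stability check.
#' @param n_restarts Louvain restarts per partition (default 5).
#' @return A list with `tau` (selected threshold) and `report`, a data frame
#'   with one row per grid point: `tau`, `n_nodes`, `n_edges`,
#'   `giant_frac`, `ari_lo`, `ari_hi` (ARI against the partitions at
#'   `tau - stability_delta` and `tau + stability_delta`), `eligible`.
#' @export
select_threshold <- function(corr, tau_grid = seq(0.930, 0.980, by = 0.005),
                             stability_delta = NULL,
                             min_component_frac = 0.8, stability_min = 0.8,
                             seed = 1, n_restarts = 5) {
  if (length(tau_grid) < 2 || is.unsorted(tau_grid, strictly = TRUE)) {
    stopf("'tau_grid' must be strictly ascending with >= 2 values")
  }
  if (any(tau_grid <= 0 | tau_grid >= 1)) stopf("'tau_grid' values must lie in (0, 1)")
  if (is.null(stability_delta)) stability_delta <- min(diff(tau_grid))
  assert_number(stability_delta, "stability_delta", lower = 0, upper = 1,
                open_lower = TRUE, open_upper = TRUE)

  a <- abs(corr$r)
  a[is.na(a)] <- -Inf
  diag(a) <- -Inf
  row_max <- apply(a, 1, max)  # strongest link per gene, for isolation counts

  part_cache <- new.env(parent = emptyenv())
  partition_at <- function(tau) {
    key <- sprintf("%.12f", tau)
    if (!is.null(part_cache[[key]])) return(part_cache[[key]])
    net <- tryCatch(suppressMessages(build_network(corr, tau)),
                    gcntools_empty_network_error = function(e) NULL)
    res <- if (is.null(net)) list(net = NULL, part = NULL) else {
      list(net = net,
           part = detect_communities(net, seed = seed, n_restarts = n_restarts))
    }
    part_cache[[key]] <- res
    res
  }
  ari_between <- function(pa, pb) {
    if (is.null(pa) || is.null(pb)) return(NA_real_)
    common <- intersect(names(pa$membership), names(pb$membership))
    if (length(common) < 2) return(0)
    ma <- pa$membership[common]
    mb <- pb$membership[common]
    adjusted_rand_index(as.integer(factor(ma)), as.integer(factor(mb)))
  }

  k <- length(tau_grid)
  n_nodes <- n_edges <- giant_frac <- ari_lo <- ari_hi <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    tau <- tau_grid[i]
    at <- partition_at(tau)
    if (is.null(at$net)) next
    n_nodes[i] <- igraph::vcount(at$net)
    n_edges[i] <- igraph::ecount(at$net)
    giant_frac[i] <- n_nodes[i] / sum(row_max >= tau)
    lo <- tau - stability_delta
    hi <- tau + stability_delta
    if (lo > 0) ari_lo[i] <- ari_between(at$part, partition_at(lo)$part)
    if (hi < 1) ari_hi[i] <- ari_between(at$part, partition_at(hi)$part)
  }
  eligible <- !is.na(giant_frac) & giant_frac >= min_component_frac &
    (is.na(ari_lo) | ari_lo >= stability_min) &
    (is.na(ari_hi) | ari_hi >= stability_min) &
    !(is.na(ari_lo) & is.na(ari_hi))
  report <- data.frame(tau = tau_grid, n_nodes = n_nodes, n_edges = n_edges,
                       giant_frac = giant_frac, ari_lo = ari_lo,
                       ari_hi = ari_hi, eligible = eligible)
  if (!any(eligible)) {
    cond <- errorCondition(
      "no threshold in the grid satisfies the component-coverage and stability criteria",
      report = report,
      class = c("gcntools_no_threshold_error", "gcntools_error"))
    stop(cond)
  }
  list(tau = tau_grid[max(which(eligible))], report = report)
}
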