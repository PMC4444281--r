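# End-to-end orchestration: read -> filter -> DE screen -> per group x
# {DE, CO}: correlation -> threshold selection -> network -> connectivity ->
# scale-free fit -> hierarchy -> communities -> coarse-grained structure,
# with all artifacts written as TSV/GraphML/JSON.

#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults; any value can be
#' overridden via `...` (or by the YAML file passed to [run_pipeline()]).
#' The `DE` grid default spans high correlations typical for networks built
#' from a differentially expressed gene subset; the `CO` (whole-universe)
#' grid sits higher because the far larger number of gene pairs demands a
#' stricter threshold to keep chance edges rare.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    expression_path = NULL,
    group_map_path = NULL,
    keep_genes_path = NULL,
    de = list(alpha = 0.05, variant = "student", min_genes = 10L),
    network = list(tau_grid_de = seq(0.930, 0.980, by = 0.005),
                   tau_grid_co = seq(0.990, 0.998, by = 0.001),
                   min_component_frac = 0.8,
                   stability_min = 0.8,
                   stability_delta = NULL),
    hierarchy = list(hub_quantile = 0.9, vip_k0_quantile = 0.5),
    community = list(seed = 1L, n_restarts = 10L),
    powerlaw = list(bootstrap_reps = 0L),
    report = list(top_k_communities = 9L),
    out_dir = NULL,
    verbose = TRUE)
  merge_config(defaults, list(...))
}

# recursive modifyList so partial nested overrides keep sibling defaults
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  do.call(pipeline_config, config)
}

pipeline_stage <- function(stage, verbose, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      stage = stage, parent = e,
      class = c("gcntools_pipeline_error", "gcntools_error")))
  })
}

#' Run the full coexpression-network pipeline
#'
#' Executes every stage of the two-group analysis: reads and validates the
#' expression matrix, applies the optional gene-universe keep-list, runs the
#' differential-expression screen, and then builds four networks — for each
#' group, one from the DE gene subset ("DE") and one from the full gene
#' universe ("CO") — each with threshold selection, connectivity, a
#' power-law degree fit, node-hierarchy categorization, community detection
#' and coarse-grained community structure. All artifacts are written under
#' `out_dir` along with a machine-readable `report.json`. Reruns with the
#' same inputs and configuration produce byte-identical reports.
#'
#' @param config A configuration list from [pipeline_config()] (or a path to
#'   a YAML file of overrides). `expression_path`, `group_map_path` and
#'   `out_dir` are required.
#' @return The report bundle, invisibly a list: `de` (screen summary),
#'   `networks` (one entry per network with `N`, `L`, `tau`, `k`,
#'   `powerlaw`, `n_communities`, `q`, `hierarchy_counts`, `cgcs`),
#'   `comparisons` (DE-vs-DE and CO-vs-CO group contrasts).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  for (field in c("expression_path", "group_map_path", "out_dir")) {
    if (is.null(cfg[[field]])) stopf("config field '%s' is required", field)
  }
  verbose <- isTRUE(cfg$verbose)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  em <- pipeline_stage("read_expression", verbose, {
    read_expression_matrix(cfg$expression_path, cfg$group_map_path)
  })
  log_stage(verbose, "read_expression: %d genes, %d samples",
            nrow(em$values), ncol(em$values))

  if (!is.null(cfg$keep_genes_path)) {
    em <- pipeline_stage("filter_gene_universe", verbose, {
      keep <- utils::read.delim(cfg$keep_genes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
      filter_gene_universe(em, keep)
    })
    log_stage(verbose, "filter_gene_universe: %d genes retained", nrow(em$values))
  }

  de <- pipeline_stage("differential_expression", verbose, {
    res <- differential_expression(em, alpha = cfg$de$alpha,
                                   variant = cfg$de$variant)
    n_sig <- sum(res$significant)
    if (n_sig < cfg$de$min_genes) {
      stopf("only %d significant gene(s) at alpha = %g; too few to build DE networks (minimum %d)",
            n_sig, cfg$de$alpha, cfg$de$min_genes)
    }
    res
  })
  write_de_table(de, file.path(cfg$out_dir, "de_table.tsv"))
  de_genes <- de$gene[de$significant]
  log_stage(verbose, "differential_expression: %d significant of %d genes (%d up, %d down)",
            length(de_genes), nrow(de), sum(de$significant & de$direction == "up"),
            sum(de$significant & de$direction == "down"))

  groups <- group_levels(em)
  universes <- list(DE = de_genes, CO = genes_of(em))
  networks <- list()
  for (grp in groups) {
    for (cls in c("DE", "CO")) {
      id <- paste0(grp, "-", cls)
      networks[[id]] <- pipeline_stage(paste0("network:", id), verbose, {
        analyze_network(em, grp, cls, universes[[cls]], cfg, id, verbose)
      })
    }
  }

  comparisons <- list(
    DE = compare_networks(networks[[paste0(groups[1], "-DE")]],
                          networks[[paste0(groups[2], "-DE")]]),
    CO = compare_networks(networks[[paste0(groups[1], "-CO")]],
                          networks[[paste0(groups[2], "-CO")]]))

  report <- list(
    groups = groups,
    de = list(n_genes = nrow(de),
              n_significant = length(de_genes),
              n_up = sum(de$significant & de$direction == "up", na.rm = TRUE),
              n_down = sum(de$significant & de$direction == "down", na.rm = TRUE),
              alpha = cfg$de$alpha, variant = cfg$de$variant),
    networks = lapply(networks, function(x) x[setdiff(names(x), "objects")]),
    comparisons = comparisons)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  out <- c(report, list(objects = lapply(networks, `[[`, "objects")))
  invisible(out)
}

# One network's full analysis; returns the report entry plus live objects.
analyze_network <- function(em, grp, cls, universe, cfg, id, verbose) {
  sub <- suppressMessages(filter_gene_universe(em, universe))
  corr <- suppressMessages(correlation_matrix(sub, grp))
  grid <- if (cls == "DE") cfg$network$tau_grid_de else cfg$network$tau_grid_co
  sel <- select_threshold(corr, tau_grid = grid,
                          stability_delta = cfg$network$stability_delta,
                          min_component_frac = cfg$network$min_component_frac,
                          stability_min = cfg$network$stability_min,
                          seed = cfg$community$seed,
                          n_restarts = cfg$community$n_restarts)
  net <- suppressMessages(build_network(corr, sel$tau))
  k <- connectivity(net)
  fit <- tryCatch(
    suppressMessages(powerlaw_fit_ks(igraph::degree(net),
                                     bootstrap_reps = cfg$powerlaw$bootstrap_reps,
                                     seed = cfg$community$seed)),
    gcntools_degenerate_fit_error = function(e) NULL)
  hier <- hierarchy_table(net, cfg$hierarchy$hub_quantile,
                          cfg$hierarchy$vip_k0_quantile)
  part <- detect_communities(net, seed = cfg$community$seed,
                             n_restarts = cfg$community$n_restarts)
  coarse <- coarse_grain(net, part)
  top <- top_communities(coarse, min(cfg$report$top_k_communities,
                                     nrow(coarse$communities)))

  prefix <- file.path(cfg$out_dir, id)
  write_edge_list(net, paste0(prefix, "_edges.tsv"))
  write_graphml(net, paste0(prefix, ".graphml"))
  utils::write.table(degree_distribution_table(net),
                     paste0(prefix, "_degree_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hier, paste0(prefix, "_hierarchy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_partition(part, paste0(prefix, "_partition.tsv"))
  write_coarse_network(coarse, paste0(prefix, "_cgcs.tsv"))

  log_stage(verbose, "network:%s: tau = %g, N = %d, L = %d, k = %.2f, Q = %.3f, %d communities",
            id, sel$tau, igraph::vcount(net), igraph::ecount(net), k,
            part$q, part$n_communities)

  list(id = id, group = grp, class = cls,
       n_universe = nrow(sub$values),
       N = igraph::vcount(net), L = igraph::ecount(net),
       tau = sel$tau, k = k,
       powerlaw = if (is.null(fit)) NULL else unclass(fit),
       n_communities = part$n_communities, q = part$q,
       hierarchy_counts = as.list(table(hier$category)),
       cgcs_top = list(communities = top$communities, inter = top$inter),
       objects = list(network = net, partition = part, coarse = coarse,
                      hierarchy = hier, threshold_report = sel$report))
}

#' Side-by-side comparison of two network report entries
#'
#' Tabulates `N`, `L`, `k`, `Q` and community/hierarchy counts for two
#' networks with their differences (b minus a) and ratios (b over a); a
#' field missing from either entry yields an `NA` row rather than an error.
#'
#' @param a,b Network entries from a [run_pipeline()] report bundle.
#' @return A data frame with columns `metric`, `a`, `b`, `diff`, `ratio`.
#' @export
compare_networks <- function(a, b) {
  metric_of <- function(x, m) {
    v <- switch(m,
                N = x$N, L = x$L, k = x$k, Q = x$q,
                n_communities = x$n_communities,
                n_hubs = x$hierarchy_counts[["hub"]],
                n_vips = x$hierarchy_counts[["VIP"]],
                n_high_hubs = x$hierarchy_counts[["high-hub"]])
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  metrics <- c("N", "L", "k", "Q", "n_communities", "n_hubs", "n_vips",
               "n_high_hubs")
  va <- vapply(metrics, metric_of, numeric(1), x = a)
  vb <- vapply(metrics, metric_of, numeric(1), x = b)
  data.frame(metric = metrics, a = va, b = vb,
             diff = vb - va, ratio = vb / va,
             row.names = NULL, stringsAsFactors = FALSE)
}
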