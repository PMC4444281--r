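# Synthetic-data generators: modular expression matrices and benchmark graphs
# with known ground truth, so every downstream stage is testable without
# external data.

#' Specification for a synthetic two-group modular expression experiment
#'
#' Describes a simulated microarray-style study: two groups of
#' `n_samples_per_group` samples each (default 7, a typical small
#' patient-cohort design), `n_genes` genes organized into `n_modules`
#' coexpression modules, and a planted set of differentially expressed genes.
#'
#' Coexpression follows a single-latent-factor-per-module model: gene
#' expression is `baseline + noise_sd * (s * sqrt(module_corr) * factor +
#' sqrt(1 - module_corr) * eps)` with `s = +/-1`, so the expected Pearson
#' correlation between two genes of the same module is exactly
#' `module_corr` in magnitude and the marginal gene SD is exactly `noise_sd`.
#' Half the genes in each module load negatively, so within-module
#' correlations come in both signs and exercise absolute-value edge rules.
#'
#' @param n_genes Number of genes (rows).
#' @param n_modules Number of coexpression modules; genes are split into
#'   contiguous blocks of near-equal size.
#' @param n_samples_per_group Samples per group (default 7).
#' @param module_corr Target magnitude of the within-module Pearson
#'   correlation, in `[0, 1)`; 0 gives independent genes.
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   (rounded to a count), split evenly between up- and down-regulated.
#' @param effect_size Mean shift of DE genes in group A, in units of
#'   `noise_sd`.
#' @param noise_sd Marginal standard deviation of each gene (> 0).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   intensities, on a log2-intensity-like scale.
#' @param group_labels Two group labels; the first is "group A", the group
#'   that receives the DE shift.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return A validated list of class `synthetic_spec`.
#' @seealso [generate_modular_expression()]
#' @export
synthetic_spec <- function(n_genes, n_modules, n_samples_per_group = 7,
                           module_corr = 0.8, de_fraction = 0.05,
                           effect_size = 3, noise_sd = 1,
                           baseline_mean = 8, baseline_sd = 1,
                           group_labels = c("E", "L"), seed = 1) {
  assert_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  assert_number(n_modules, "n_modules", lower = 1, upper = n_genes, integer = TRUE)
  assert_number(n_samples_per_group, "n_samples_per_group", lower = 2, integer = TRUE)
  assert_number(module_corr, "module_corr", lower = 0, upper = 1, open_upper = TRUE)
  assert_number(de_fraction, "de_fraction", lower = 0, upper = 1)
  assert_number(effect_size, "effect_size", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  assert_number(baseline_sd, "baseline_sd", lower = 0)
  assert_number(seed, "seed", integer = TRUE)
  if (length(group_labels) != 2 || anyDuplicated(group_labels)) {
    stopf("invalid value for 'group_labels': need two distinct labels",
          class = "gcntools_validation_error")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 module_corr = module_corr, de_fraction = de_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 group_labels = as.character(group_labels),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a two-group expression matrix with planted modules and DE genes
#'
#' Draws one latent factor per module per sample, assigns each gene a signed
#' loading on its module's factor, and adds independent Gaussian noise; the
#' planted differential-expression shift (`effect_size * noise_sd`, up or
#' down) is applied in group A only. Per-gene and per-module random draws use
#' independent sub-streams of `spec$seed`, so enlarging the simulation does
#' not perturb earlier genes' values.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expr` (a two-group [expression_matrix()]), `group_a`
#'   and `group_b` (the per-group genes-by-samples numeric submatrices), and
#'   `truth`: a list with `module_of_gene` (named integer vector),
#'   `de_genes_up` and `de_genes_down` (disjoint character vectors).
#' @examples
#' sim <- generate_modular_expression(
#'   synthetic_spec(n_genes = 40, n_modules = 2, seed = 1))
#' sim$expr
#' length(sim$truth$de_genes_up)
#' @export
generate_modular_expression <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  n <- spec$n_genes
  nspg <- spec$n_samples_per_group
  ns <- 2L * nspg
  width <- max(4L, nchar(as.character(n)))
  genes <- sprintf("g%0*d", width, seq_len(n))
  samples <- c(paste0(spec$group_labels[1], seq_len(nspg)),
               paste0(spec$group_labels[2], seq_len(nspg)))
  module_of_gene <- sort(rep_len(seq_len(spec$n_modules), n))
  names(module_of_gene) <- genes

  # one latent factor per module, drawn on its own sub-stream
  factors <- matrix(0, spec$n_modules, ns)
  for (m in seq_len(spec$n_modules)) {
    factors[m, ] <- with_seed(substream_seed(spec$seed, paste0("factor-", m)),
                              rnorm(ns))
  }

  # signed loadings: alternate sign within each module -> half negative
  pos_in_module <- stats::ave(seq_len(n), module_of_gene, FUN = seq_along)
  sign_of_gene <- ifelse(pos_in_module %% 2 == 1, 1, -1)
  a <- sqrt(spec$module_corr)
  b <- sqrt(1 - spec$module_corr)

  vals <- matrix(0, n, ns, dimnames = list(genes, samples))
  for (i in seq_len(n)) {
    draws <- with_seed(substream_seed(spec$seed, paste0("gene-", genes[i])),
                       rnorm(ns + 1))
    baseline <- spec$baseline_mean + spec$baseline_sd * draws[1]
    eps <- draws[-1]
    vals[i, ] <- baseline + spec$noise_sd *
      (sign_of_gene[i] * a * factors[module_of_gene[i], ] + b * eps)
  }

  n_de <- round(spec$de_fraction * n)
  de_up <- de_down <- character(0)
  if (n_de > 0) {
    de_idx <- with_seed(substream_seed(spec$seed, "de-genes"), sample(n, n_de))
    n_up <- ceiling(n_de / 2)
    de_up <- genes[de_idx[seq_len(n_up)]]
    de_down <- genes[de_idx[setdiff(seq_len(n_de), seq_len(n_up))]]
    shift <- spec$effect_size * spec$noise_sd
    cols_a <- seq_len(nspg)
    vals[de_up, cols_a] <- vals[de_up, cols_a] + shift
    vals[de_down, cols_a] <- vals[de_down, cols_a] - shift
  }

  grp <- factor(rep(spec$group_labels, each = nspg), levels = spec$group_labels)
  names(grp) <- samples
  em <- expression_matrix(vals, grp)
  list(expr = em,
       group_a = group_values(em, spec$group_labels[1]),
       group_b = group_values(em, spec$group_labels[2]),
       truth = list(module_of_gene = module_of_gene,
                    de_genes_up = de_up,
                    de_genes_down = de_down))
}

#' Generate a planted-partition benchmark graph
#'
#' Simple undirected graph with `n_communities` blocks of near-equal size
#' (sizes differ by at most one); each within-block pair is joined
#' independently with probability `p_in`, each between-block pair with
#' `p_out`. Used as ground truth for community-detection benchmarks, so
#' `p_in > p_out` is required.
#'
#' @param n_nodes Number of nodes.
#' @param n_communities Number of planted blocks.
#' @param p_in,p_out Within- and between-block edge probabilities.
#' @param seed Integer seed.
#' @return A list with `graph` (an [igraph::igraph] with vertex names
#'   `v1..vN`) and `truth$community_of_node` (named integer vector).
#' @examples
#' bench <- generate_planted_partition_graph(60, 3, 0.5, 0.02, seed = 1)
#' igraph::vcount(bench$graph)
#' @export
generate_planted_partition_graph <- function(n_nodes, n_communities,
                                             p_in, p_out, seed = 1) {
  assert_number(n_nodes, "n_nodes", lower = 1, integer = TRUE)
  assert_number(n_communities, "n_communities", lower = 1, upper = n_nodes,
                integer = TRUE)
  assert_number(p_in, "p_in", lower = 0, upper = 1)
  assert_number(p_out, "p_out", lower = 0, upper = 1)
  assert_number(seed, "seed", integer = TRUE)
  if (p_in <= p_out) {
    stopf("invalid value for 'p_in'/'p_out': p_in (%g) must exceed p_out (%g) for a recoverable planted partition",
          p_in, p_out, class = "gcntools_validation_error")
  }
  sizes <- rep(n_nodes %/% n_communities, n_communities)
  extra <- n_nodes %% n_communities
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  pref <- matrix(p_out, n_communities, n_communities)
  diag(pref) <- p_in
  g <- with_seed(seed,
                 igraph::sample_sbm(n_nodes, pref.matrix = pref,
                                    block.sizes = sizes, directed = FALSE))
  igraph::V(g)$name <- paste0("v", seq_len(n_nodes))
  community_of_node <- rep(seq_len(n_communities), times = sizes)
  names(community_of_node) <- igraph::V(g)$name
  list(graph = g, truth = list(community_of_node = community_of_node))
}

#' Generate a scale-free graph by preferential attachment
#'
#' Barabasi-Albert growth: each new node attaches to `m_attach` existing
#' nodes with probability proportional to their degree. Positive control for
#' the power-law degree-distribution test: the resulting degree sequence is
#' asymptotically power-law with exponent near 3.
#'
#' @param n_nodes Number of nodes; `m_attach` must be smaller.
#' @param m_attach Edges added per new node.
#' @param seed Integer seed.
#' @return A connected simple undirected [igraph::igraph] with vertex names.
#' @export
generate_scale_free_graph <- function(n_nodes, m_attach, seed = 1) {
  assert_number(n_nodes, "n_nodes", lower = 2, integer = TRUE)
  assert_number(seed, "seed", integer = TRUE)
  if (!(is.numeric(m_attach) && length(m_attach) == 1 &&
        m_attach == round(m_attach) && m_attach >= 1 && m_attach < n_nodes)) {
    stopf("invalid value for 'm_attach': must be a whole number in [1, n_nodes)",
          class = "gcntools_validation_error")
  }
  g <- with_seed(seed,
                 igraph::sample_pa(n_nodes, m = m_attach, directed = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("v", seq_len(n_nodes))
  g
}

#' Generate an Erdos-Renyi random graph
#'
#' G(n, p) model; negative control for the power-law test (its degree law is
#' binomial/Poisson, not power-law).
#'
#' @param n_nodes Number of nodes.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return A simple undirected [igraph::igraph] with vertex names.
#' @export
generate_er_graph <- function(n_nodes, p, seed = 1) {
  assert_number(n_nodes, "n_nodes", lower = 1, integer = TRUE)
  assert_number(p, "p", lower = 0, upper = 1)
  assert_number(seed, "seed", integer = TRUE)
  g <- with_seed(seed, igraph::sample_gnp(n_nodes, p))
  igraph::V(g)$name <- paste0("v", seq_len(n_nodes))
  g
}

#' Write a simulated study to disk as plain-text pipeline inputs
#'
#' Convenience wrapper: generates a modular expression data set and writes
#' the expression TSV, the sample-to-group map TSV, and the ground truth as
#' JSON, ready for [run_pipeline()].
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the three file paths and the simulation.
#' @export
simulate_study <- function(spec, dir) {
  sim <- generate_modular_expression(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                group_map = file.path(dir, "groups.tsv"),
                truth = file.path(dir, "truth.json"))
  write_expression_matrix(sim$expr, paths$expression)
  write_group_map(sim$expr, paths$group_map)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = FALSE)
  invisible(c(paths, list(sim = sim)))
}
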