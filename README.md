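# gcntools

Gene coexpression network analysis for two-group expression studies:
differential-expression screening, correlation-threshold network inference,
scale-free diagnostics, hub/VIP node hierarchy, community detection and
coarse-grained community structure — with a synthetic-data module that makes
the whole pipeline testable against known ground truth.

## The problem

Given a genes × samples expression matrix split into two groups (e.g. early-
vs late-onset patients), one wants to compare the groups not gene by gene
but at the level of the transcriptional network: which genes co-vary, how
densely connected each group's network is, which genes occupy privileged
positions, and how the network decomposes into communities. `gcntools`
implements that workflow for researchers analyzing small-cohort expression
studies (microarray or otherwise), and for methodologists who need a fully
seeded, ground-truthed benchmark of each stage.

## The model

* **DE screen.** Per-gene unpaired two-sample t-test (Student pooled by
  default, Welch optional), two-sided, unadjusted *p* < α (default 0.05);
  optional Benjamini–Hochberg column.
* **Networks.** Within each group, Pearson correlation *r* over that group's
  samples; edge iff |*r*| ≥ τ; the analyzed network is the largest connected
  component. τ is selected automatically as the largest grid value at which
  the giant component covers ≥ 80% of non-isolated nodes and the community
  partition is stable (ARI ≥ 0.8) under a small τ perturbation. Networks are
  built from the DE gene subset ("DE") and from the full gene universe
  ("CO"). Connectivity is reported as k = 2L/N (mean degree, L edges, N
  nodes).
* **Scale-free check.** Discrete power-law fit P(k) ∝ k^(−α) for k ≥ x_min
  by exact maximum likelihood; x_min minimizes the Kolmogorov–Smirnov
  distance; semi-parametric bootstrap goodness-of-fit p-value.
* **Node hierarchy.** k0 = degree; k1 = edges leaving the node's immediate
  neighborhood (ring-1 → ring-2 edges). Categories from quantile thresholds
  on (k0, k1): hubs (high k0), VIPs (low k0 but high k1 — their few links
  lead to highly connected nodes), high-hubs (both high).
* **Communities.** Seeded multilevel (Louvain) modularity optimization,
  best of *n* restarts; Newman–Girvan Q; adjusted Rand index / NMI for
  partition comparison; coarse-grained community structure (CGCS) by
  contracting communities, with inter-community edge-count fractions.

## Worked example

```r
library(gcntools)

# a synthetic two-group study: 200 genes in 2 coexpression modules,
# 7 samples per group, 5% DE genes at 3 SD
spec <- synthetic_spec(n_genes = 200, n_modules = 2, module_corr = 0.9,
                       de_fraction = 0.05, effect_size = 3, seed = 1)
sim <- generate_modular_expression(spec)
sim$expr
#> expression_matrix: 200 genes x 14 samples (E: 7, L: 7)

de <- differential_expression(sim$expr)
sum(de$significant)
#> [1] 13

cm  <- correlation_matrix(sim$expr, "E")
sel <- select_threshold(cm, tau_grid = seq(0.5, 0.95, 0.05), seed = 1)
sel$tau
#> [1] 0.85

net <- build_network(cm, sel$tau)
connectivity(net)          # k = 2L/N
#> [1] 60.29

part <- detect_communities(net, seed = 1)
part
#> gcn_partition: 2 communities over 200 nodes, Q = 0.4623

truth <- sim$truth$module_of_gene[names(part$membership)]
compare_partitions(part$membership, truth)$ari   # planted modules recovered
#> [1] 1

head(hierarchy_table(net), 3)
coarse_grain(net, part)
#> coarse_network: 2 communities, 6029 edges (8 inter-community)
```

The numbers above are what the code prints for this seed: the two planted
modules are recovered exactly (ARI = 1), the selected threshold is 0.85, and
the E-group network has N = 200, L = 6029, hence k = 60.29.

The full four-network comparison (E-DE, L-DE, E-CO, L-CO) runs from one
configuration:

```r
paths <- simulate_study(spec, "study_dir")
cfg <- pipeline_config(
  expression_path = paths$expression,
  group_map_path  = paths$group_map,
  network = list(tau_grid_de = seq(0.70, 0.95, by = 0.05),
                 tau_grid_co = seq(0.90, 0.98, by = 0.01),
                 stability_delta = 0.01),
  out_dir = "study_dir/out")
report <- run_pipeline(cfg)
```

This writes, per network, the edge list (TSV + GraphML), degree
distribution, hierarchy table, partition, CGCS tables and a machine-readable
`report.json`; reruns are byte-identical.

## Testing

```r
devtools::test()          # or: testthat::test_dir("tests/testthat")
```

The suite checks every stage against independent oracles (BFS ring counts
for concentric degrees, exhaustive partition enumeration for modularity
optima, closed-form t and ARI values, brute-force power-law scans) plus
end-to-end recovery of planted structure.

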