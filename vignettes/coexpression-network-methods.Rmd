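---
title: "Methods: coexpression networks, node hierarchy and community structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression networks, node hierarchy and community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcntools)
```

# Overview

`gcntools` implements a two-group transcriptional-network analysis: starting
from a genes-by-samples expression matrix with two sample groups (for
example early- versus late-onset patients), it

1. screens for differentially expressed (DE) genes with a per-gene two-sample
   t-test;
2. builds, separately per group, gene coexpression networks (GCNs) from
   Pearson correlations — one network on the DE gene subset ("DE" networks)
   and one on the full gene universe ("CO" networks) — with an automatically
   selected link-strength threshold;
3. checks scale-free status of each network with a discrete power-law fit
   and a Kolmogorov–Smirnov (K-S) bootstrap;
4. categorizes nodes into hubs, VIPs and high-hubs from concentric node
   degrees $(k_0, k_1)$;
5. detects communities by multilevel (Louvain) modularity optimization; and
6. contracts each network into its coarse-grained community structure
   (CGCS), the community-level graph with edge-count weights.

A synthetic-data module generates expression matrices and benchmark graphs
with known ground truth, so that each stage — and the pipeline end to end —
is testable without access to any particular microarray deposit.

# The synthetic-data model

`generate_modular_expression()` draws, for each of $M$ modules, one latent
factor per sample, and sets gene $i$ of module $m$ in sample $s$ to

$$x_{is} = b_i + \sigma\left(s_i\sqrt{c}\,f_{ms} + \sqrt{1-c}\,\varepsilon_{is}\right),$$

with baseline $b_i \sim N(8, 1)$ on a log2-intensity-like scale, marginal
noise scale $\sigma$ (`noise_sd`, default 1), within-module correlation
target $c$ (`module_corr`), loading sign $s_i = \pm 1$ alternating within
each module, and $f, \varepsilon \sim N(0,1)$ independent. Two properties
make this convenient for testing:

* the population correlation between two genes of one module is exactly
  $\pm c$, and the marginal variance of every gene is exactly $\sigma^2$;
* half of each module's genes load negatively, so within-module
  correlations arise with both signs and exercise the absolute-value edge
  rule downstream.

Differential expression is planted by adding $\pm d\sigma$ (`effect_size`
$d$, split 50/50 up/down) to a random `de_fraction` of genes in group A
only. Random draws come from per-gene and per-module sub-streams of one
integer seed, so enlarging a simulation leaves the values of previously
generated genes unchanged.

Defaults mirror a small two-group microarray cohort: 7 samples per group,
`module_corr = 0.8`, `de_fraction = 0.05`, `effect_size = 3`,
`noise_sd = 1`. The generator deliberately does **not** model array-specific
artifacts (dye bias, spot flags, batch effects) or heavy-tailed intensity
distributions; passing tests on this generator demonstrate correctness of
the pipeline's computations and recoverability of clean planted structure,
not robustness to every pathology of real array data.

What the generator *cannot* hide is the small-sample geometry of such
designs: with 7 samples per group, the 8 centered module factors live in a
6-dimensional sample space and are therefore necessarily pairwise
correlated in-sample (chance factor correlations of 0.6–0.8 are routine).
Cross-module gene correlations of comparable size follow, and some pairs
exceed any workable threshold. Community recovery on the full-universe
networks consequently plateaus around an adjusted Rand index of roughly
0.7–0.9 against the planted modules, varying with the seed, and the
partition maximizing modularity can genuinely differ from the planted one
(we verified that the planted partition often scores *lower* modularity on
the realized network than the detected optimum). This is an identifiability
limit of 7-sample designs, not an optimizer failure.

Benchmark graph generators complete the module: a planted-partition model
(`generate_planted_partition_graph()`, requiring $p_{in} > p_{out}$), a
preferential-attachment generator (`generate_scale_free_graph()`, positive
control for the power-law test) and an Erdős–Rényi generator
(`generate_er_graph()`, negative control).

# Differential expression screen

`differential_expression()` performs an unpaired two-sample t-test per gene,
Student's pooled-variance variant by default (Welch optional), two-sided,
with pairwise missing-value removal. Following common practice for this
kind of screen, significance defaults to unadjusted $p < 0.05$; a
Benjamini–Hochberg column is available (`adjust = TRUE`) for reporting.
Degenerate genes are handled explicitly: constant in both groups with equal
means gives $t = 0, p = 1$; zero variance with unequal means gives $p = 0$;
genes with fewer than two finite values in a group are excluded as
untestable and listed in an attribute rather than failing the pipeline.
"Up" means the first configured group's mean is larger; group order is
fixed by the group factor's level order to avoid sign ambiguity. The test
operates on whatever scale the input matrix is on (typically log
intensities) and applies no transformation of its own.

# Network construction and threshold selection

Within one group, `correlation_matrix()` computes all pairwise Pearson
correlations over that group's samples only (pairwise-complete; pairs with
fewer than three complete observations are undefined and can never form an
edge; zero-variance genes are excluded). `build_network()` places an edge
wherever $|r| \ge \tau$ — covariation counts whether positive or negative,
and the signed $r$ is kept as an edge attribute — and then restricts to the
largest connected component, breaking size ties toward the component
containing the lexicographically smallest gene identifier. Dropping
isolated nodes and minor components reflects the convention that the
analyzed network is the major component.

`select_threshold()` operationalizes the qualitative rule that the network
should hold together while being insensitive to small changes of $\tau$:
over an ascending grid it returns the largest $\tau$ such that

* the giant component covers at least `min_component_frac` (default 0.8)
  of the nodes that still have any edge at $\tau$, and
* the community partition is stable: the adjusted Rand index between the
  partitions at neighboring grid points is at least `stability_min`
  (default 0.8).

The ARI criterion is our concrete proxy for "topological structure does not
change significantly"; the perturbation defaults to one grid step. When two
compared partitions are both trivial (a single community each) the ARI's
chance correction degenerates 0/0; we define stability as perfect in that
case, since the partitions are identical. If no grid point qualifies, a
structured error carries the full per-$\tau$ report so the caller can relax
the grid deliberately rather than silently.

Default grids (DE: 0.930–0.980 by 0.005; CO: 0.990–0.998 by 0.001) mirror
the ranges appropriate for cohorts of real microarray size, where tens of
thousands of gene pairs demand strict thresholds. For the bundled
2000-gene, 7-sample synthetic studies we use wider, lower grids (DE:
0.70–0.95 by 0.05; CO: 0.90–0.98 by 0.01), chosen a priori from the null
sampling distribution of $r$ at $n = 7$: the grid must bracket the
percolation region, and at its lower end chance edges
($P(|r| \ge \tau \mid \rho = 0)$) must stay well below the expected
within-module edge density. Connectivity is reported as $k = 2L/N$, exactly
the mean degree.

# Scale-free diagnostics

`powerlaw_fit_ks()` fits a discrete power law $P(k) \propto k^{-\alpha}$,
$k \ge x_{min}$, by exact discrete maximum likelihood (the normalizing
Hurwitz zeta is computed by direct summation plus an Euler–Maclaurin tail,
accurate to ~1e-12), choosing $x_{min}$ to minimize the K-S distance
between empirical and fitted tail CDFs. Candidate $x_{min}$ values must
leave at least 10 tail observations and 10 distinct tail values, matching
the intent that the fit describe a genuine tail. The goodness-of-fit
p-value is the standard semi-parametric bootstrap: synthetic samples draw
tail values from the fitted law and body values from the empirical body,
each replicate is refit from scratch, and $p$ is the fraction of replicate
K-S distances at least as large as the observed one. Note the bootstrap is
honest about preferential-attachment graphs: their degree law is only
asymptotically a power law, so individual instances are sometimes rejected;
calibration holds in aggregate (and Erdős–Rényi degree sequences are
rejected essentially always).

# Concentric degrees and the hub / VIP / high-hub hierarchy

For a node $u$, $k_0$ is its degree and $k_1$ counts the edges from $u$'s
immediate neighborhood (ring 1) to nodes at shortest-path distance 2
(ring 2) — the connections *leaving* the neighborhood. Edges among ring-1
nodes and edges back to $u$ are excluded; on trees
$k_1 = \sum_{v \in N(u)} (\deg v - 1)$ exactly. The implementation uses the
sparse identity that $(A^2)_{uw}$ counts the ring-1 intermediaries of each
ring-2 node $w$, and is verified against a breadth-first-search oracle.

Categories are assigned from the joint $(k_0, k_1)$ distribution with
quantile thresholds $T_{k_0}, T_{k_1}$ (`hub_quantile`, default 0.9) and
$L_{k_0}$ (`vip_k0_quantile`, default 0.5): **high-hub** if
$k_0 \ge T_{k_0}$ and $k_1 \ge T_{k_1}$; **hub** if $k_0 \ge T_{k_0}$ only;
**VIP** if $k_0 \le L_{k_0}$ and $k_1 \ge T_{k_1}$ (few links, but they
lead to highly connected nodes); **other** otherwise. The quantiles are
nearest-rank over the *distinct* degree values: on degree distributions
with massive ties (a star's leaves, power-law networks' many degree-1
nodes), raw-vector quantiles collapse to the smallest value and would
promote every leaf; distinct-value quantiles keep thresholds at attained
values while preserving the intended "top of the degree ladder" reading —
on a 10-node star this classifies the center as a hub and the leaves as
VIPs, matching the concept that VIPs connect only to hubs. When either
degree is constant across the graph the rule carries no information and all
nodes are labelled `other`, with a warning.

# Community structure and coarse graining

`modularity()` evaluates the Newman–Girvan quality
$Q = \sum_c (e_c/L - (d_c/2L)^2)$ on the unweighted graph (edges are
thresholded to presence/absence upstream, so the unweighted form is the
primary one). `detect_communities()` runs the multilevel algorithm at
resolution 1 under `n_restarts` (default 10) seeded random vertex orders
and keeps the best-Q partition; the same seed always reproduces the same
partition, and ties prefer the earliest restart. On small graphs the
restart scheme attains the exhaustively enumerated optimum in ≥95% of runs
(tested over all partitions of 7-node graphs). Partition quality and
stability comparisons use the adjusted Rand index and normalized mutual
information (`compare_partitions()`).

`coarse_grain()` contracts each community to one node: diagonal mixing
matrix entries are intra-community edge counts, off-diagonal entries
inter-community edge counts, and each inter-community weight fraction is
the edge count divided by the total $L$ — so edge conservation
$\sum_c e_c + \sum_{c<c'} e_{cc'} = L$ holds exactly by construction and is
property-tested. Communities are lettered A, B, C, … in decreasing size
(ties by index), and `top_communities()` restricts a CGCS to the $k$
largest communities plus an optional keep-list, mirroring the reporting
convention of showing the top communities by size while retaining smaller
ones that contain notable hubs.

# Pipeline and reporting

`run_pipeline()` wires the stages together from a configuration list (or
YAML file): read → optional universe filter → DE screen → per group ×
{DE, CO}: correlation → threshold selection → network → connectivity →
power-law fit → hierarchy → communities → CGCS. Every artifact is plain
text (TSV/GraphML/JSON); every stage logs its row/node/edge counts; any
stage failure aborts with the stage name attached as a structured
condition. Reruns with identical inputs, configuration and seed produce
byte-identical `report.json` files. The bootstrap p-value is off by default
in the pipeline (`powerlaw$bootstrap_reps = 0`) because it dominates
runtime on large networks; the fit itself (alpha, xmin, K-S distance) is
always reported.

The R functions themselves are the package's interface; the pipeline is a
single call from a config, so no separate shell entry point is shipped.

# Numerical choices and limitations

* Problem sizes in the test-suite and acceptance analyses (2000-gene
  studies, 5000-node benchmark graphs, 100-replicate bootstraps) were
  chosen so the whole suite runs in minutes on one CPU while keeping every
  statistical check well-powered.
* Undefined correlations (constant genes, short pairs) are treated as
  "below any threshold", never as errors, so sparse missingness degrades a
  network gracefully.
* The modularity resolution is fixed at 1 (the classical definition);
  known resolution-limit effects on very large networks are out of scope.
* Concentric degrees stop at level 1 ($k_2, k_3, \ldots$ are not
  computed), and no betweenness/eigenvector centralities are offered.
* Exact reproduction of any particular published network's node counts,
  modularity values or gene categorizations requires that study's deposited
  expression data; with synthetic data those statistics are data-dependent
  context, and the package's claims are therefore about the computations
  (e.g. $k = 2L/N$ arithmetic, edge conservation, oracle equivalence) and
  about recovery of planted structure under stated conditions.
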