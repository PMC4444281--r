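# Concentric node degrees and the hub / VIP / high-hub categorization.
#
# k0 is the ordinary node degree. k1, the first-level concentric degree,
# counts the connections leaving a node's immediate neighborhood: edges with
# one endpoint among the node's neighbors (ring 1) and the other at
# shortest-path distance 2 (ring 2). Edges inside ring 1 and edges back to
# the node itself are not counted.

# k0 and k1 for every node at once. With 0/1 adjacency A, (A^2)[u, w] is the
# number of common neighbors of u and w, i.e. the number of ring1->w edges;
# summing it over the ring-2 nodes of u (reachable in 2 steps but not
# adjacent and not u itself) counts each ring1->ring2 edge exactly once.
concentric_degrees_all <- function(net) {
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  k0 <- Matrix::rowSums(a)
  a2 <- a %*% a
  ring2 <- (a2 > 0) & (a == 0)  # includes the diagonal wherever k0 > 0
  # a2[u, u] = k0(u), so subtracting k0 removes the diagonal contribution
  k1 <- Matrix::rowSums(a2 * ring2) - k0
  data.frame(node = igraph::V(net)$name,
             k0 = as.integer(k0), k1 = as.integer(k1),
             stringsAsFactors = FALSE)
}

#' Concentric node degrees k0 and k1
#'
#' For `node`, `k0` is its degree and `k1` is the number of edges from its
#' immediate neighbors (ring 1) to nodes at shortest-path distance 2
#' (ring 2) — the connections leaving the neighborhood. Edges among
#' neighbors and edges back to the node are excluded.
#'
#' @param net An [igraph::igraph] with vertex names.
#' @param node A vertex name (or vector of names).
#' @return A named list with integer vectors `k0` and `k1` (one entry per
#'   requested node).
#' @examples
#' path <- igraph::make_graph(~ a - b, b - c, c - d)
#' concentric_degrees(path, "b")  # k0 = 2, k1 = 1 (the c-d edge)
#' @export
concentric_degrees <- function(net, node) {
  missing_nodes <- setdiff(node, igraph::V(net)$name)
  if (length(missing_nodes)) {
    stopf("node(s) not in the network: %s", paste(missing_nodes, collapse = ", "),
          class = "gcntools_lookup_error")
  }
  all_deg <- concentric_degrees_all(net)
  i <- match(node, all_deg$node)
  list(k0 = setNames(all_deg$k0[i], node), k1 = setNames(all_deg$k1[i], node))
}

# Nearest-rank quantile taken over the distinct values of x, so thresholds
# are attained values and massive ties (e.g. many degree-1 leaves) do not
# drag a "high" threshold down to the floor of the distribution.
distinct_quantile <- function(x, q) {
  u <- sort(unique(x))
  u[ceiling(q * length(u))]
}

#' Categorize nodes as hubs, VIPs, high-hubs, or other
#'
#' Computes `(k0, k1)` for every node and applies threshold rules on the
#' joint distribution: with `Tk0` and `Tk1` the `hub_quantile` quantiles of
#' `k0` and `k1`, and `Lk0` the `vip_k0_quantile` quantile of `k0` (all
#' nearest-rank over distinct values, so thresholds are attained):
#'
#' * high-hub: `k0 >= Tk0` and `k1 >= Tk1` (highly connected and feeding a
#'   well-connected neighborhood);
#' * hub: `k0 >= Tk0` and `k1 < Tk1`;
#' * VIP: `k0 <= Lk0` and `k1 >= Tk1` (few links of its own, but those links
#'   lead to highly connected nodes);
#' * other: everything else.
#'
#' When either degree is constant across the graph the thresholds carry no
#' information and all nodes are labelled `other` (with a warning).
#'
#' @param net An [igraph::igraph] with vertex names.
#' @param hub_quantile Upper quantile defining "high" `k0`/`k1` (default 0.9).
#' @param vip_k0_quantile Quantile defining "low" `k0` for VIPs (default 0.5).
#' @return A data frame with columns `node`, `k0`, `k1`, `category`
#'   (factor with levels `high-hub`, `hub`, `VIP`, `other`), sorted by
#'   category then decreasing `k1` and `k0`.
#' @export
classify_nodes <- function(net, hub_quantile = 0.9, vip_k0_quantile = 0.5) {
  assert_number(hub_quantile, "hub_quantile", lower = 0, upper = 1,
                open_lower = TRUE, open_upper = TRUE)
  assert_number(vip_k0_quantile, "vip_k0_quantile", lower = 0, upper = 1,
                open_lower = TRUE, open_upper = TRUE)
  if (igraph::vcount(net) == 0) stopf("empty network")
  deg <- concentric_degrees_all(net)
  lv <- c("high-hub", "hub", "VIP", "other")
  if (length(unique(deg$k0)) < 2 || length(unique(deg$k1)) < 2) {
    warning("degree quantiles collapse (constant k0 or k1); all nodes labelled 'other'")
    deg$category <- factor("other", levels = lv)
  } else {
    tk0 <- distinct_quantile(deg$k0, hub_quantile)
    tk1 <- distinct_quantile(deg$k1, hub_quantile)
    lk0 <- distinct_quantile(deg$k0, vip_k0_quantile)
    deg$category <- factor(
      ifelse(deg$k0 >= tk0 & deg$k1 >= tk1, "high-hub",
      ifelse(deg$k0 >= tk0, "hub",
      ifelse(deg$k0 <= lk0 & deg$k1 >= tk1, "VIP", "other"))),
      levels = lv)
    attr(deg, "thresholds") <- c(Tk0 = tk0, Tk1 = tk1, Lk0 = lk0)
  }
  deg[order(deg$category, -deg$k1, -deg$k0), , drop = FALSE]
}

#' Per-node hierarchy table
#'
#' One row per node with `k0`, `k1` and its category — the backing data for
#' a k0-vs-k1 scatter plot of the network hierarchy.
#'
#' @inheritParams classify_nodes
#' @return A data frame with columns `node`, `k0`, `k1`, `category`.
#' @export
hierarchy_table <- function(net, hub_quantile = 0.9, vip_k0_quantile = 0.5) {
  tab <- classify_nodes(net, hub_quantile, vip_k0_quantile)
  rownames(tab) <- NULL
  tab
}
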