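two_triangles <- function(bridge = FALSE) {
  edges <- c("a", "b", "b", "c", "c", "a", "d", "e", "e", "f", "f", "d")
  if (bridge) edges <- c(edges, "c", "d")
  igraph::make_graph(edges, directed = FALSE)
}

test_that("modularity matches its defining formula on hand-worked cases", {
  g <- two_triangles()
  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity(g, part), 0.5)                 # 2 * (3/6 - (6/12)^2)
  expect_equal(modularity(g, part), oracle_modularity(g, part[igraph::V(g)$name]))

  # a single community always has Q = 0
  expect_equal(modularity(g, setNames(rep(1, 6), igraph::V(g)$name)), 0)

  # singleton communities: Q = -sum (deg_i / 2L)^2 < 0
  singletons <- setNames(seq_len(6), igraph::V(g)$name)
  expect_equal(modularity(g, singletons), -sum((igraph::degree(g) / 12)^2))
  expect_lt(modularity(g, singletons), 0)
})

test_that("modularity agrees with the brute-force oracle on random partitions", {
  set.seed(5)
  for (i in 1:20) {
    g <- generate_er_graph(12, 0.3, seed = i)
    if (igraph::ecount(g) == 0) next
    memb <- sample(1:3, 12, replace = TRUE)
    names(memb) <- igraph::V(g)$name
    expect_equal(modularity(g, memb), oracle_modularity(g, memb),
                 tolerance = 1e-12)
    expect_gte(modularity(g, memb), -0.5)
    expect_lte(modularity(g, memb), 1)
  }
})

test_that("an edgeless graph has Q = 0 with a warning", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  expect_warning(q <- modularity(g, c(a = 1, b = 2, c = 1)), "edgeless")
  expect_equal(q, 0)
})

test_that("community detection finds the exact optimum on two bridged cliques", {
  # two 6-cliques plus one bridge
  c1 <- igraph::make_full_graph(6)
  c2 <- igraph::make_full_graph(6)
  g <- igraph::disjoint_union(c1, c2)
  g <- igraph::add_edges(g, c(6, 7))
  igraph::V(g)$name <- paste0("v", 1:12)
  part <- detect_communities(g, seed = 1)
  expect_equal(part$n_communities, 2)
  expect_equal(sort(table(part$membership), decreasing = TRUE),
               sort(table(rep(1:2, each = 6)), decreasing = TRUE),
               ignore_attr = TRUE)
  # clique split is the global optimum (exhaustive over <= 4-part partitions
  # is infeasible at 12 nodes; verify against the analytic Q of the split)
  clique_part <- setNames(rep(1:2, each = 6), igraph::V(g)$name)
  expect_equal(part$q, modularity(g, clique_part), tolerance = 1e-12)
})

test_that("complete graphs stay one community", {
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("v", 1:6)
  part <- detect_communities(k6, seed = 2)
  expect_equal(part$n_communities, 1)
  expect_equal(part$q, 0)
  # brute force confirms no split does better
  expect_equal(oracle_max_modularity(k6), 0, tolerance = 1e-12)
})

test_that("detected q always equals modularity recomputed on the partition", {
  for (s in 1:10) {
    g <- generate_planted_partition_graph(60, 3, 0.5, 0.05, seed = s)$graph
    g <- suppressMessages(gcntools:::giant_component(g))
    part <- detect_communities(g, seed = s)
    expect_equal(part$q, modularity(g, part), tolerance = 1e-12)
    expect_identical(sort(unique(unname(part$membership))),
                     seq_len(part$n_communities) - 1L)
  }
})

test_that("community detection is deterministic for a fixed seed", {
  g <- generate_planted_partition_graph(100, 4, 0.4, 0.05, seed = 3)$graph
  g <- suppressMessages(gcntools:::giant_component(g))
  p1 <- detect_communities(g, seed = 7, n_restarts = 5)
  p2 <- detect_communities(g, seed = 7, n_restarts = 5)
  expect_identical(p1, p2)
})

test_that("single-node graphs yield one community with q = 0", {
  g <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g)$name <- "v1"
  part <- detect_communities(g, seed = 1)
  expect_equal(part$n_communities, 1)
  expect_equal(part$q, 0)
})

test_that("partition comparison: permuted labels, trivial cases, and the ARI formula", {
  a <- setNames(c(1, 1, 2, 2, 3, 3), paste0("v", 1:6))
  a_perm <- setNames(c(9, 9, 4, 4, 7, 7), paste0("v", 1:6))
  cp <- compare_partitions(a, a_perm)
  expect_equal(cp$ari, 1)
  expect_equal(cp$nmi, 1)

  all_one <- setNames(rep(1, 6), paste0("v", 1:6))
  singletons <- setNames(1:6, paste0("v", 1:6))
  expect_equal(compare_partitions(all_one, singletons)$ari, 0)

  # hand contingency ((2,1),(1,2)) across 6 nodes
  pa <- setNames(c(1, 1, 1, 2, 2, 2), paste0("v", 1:6))
  pb <- setNames(c(1, 1, 2, 1, 2, 2), paste0("v", 1:6))
  expect_equal(compare_partitions(pa, pb)$ari, oracle_ari(pa, pb))
  expect_equal(compare_partitions(pa, pb)$ari, -1 / 9, tolerance = 1e-12)

  bad <- setNames(1:5, paste0("v", 2:6))
  expect_error(compare_partitions(a, bad), "v1",
               class = "gcntools_node_mismatch_error")
})

test_that("planted partitions are recovered almost perfectly", {
  bench <- generate_planted_partition_graph(200, 4, 0.5, 0.01, seed = 7)
  g <- suppressMessages(gcntools:::giant_component(bench$graph))
  part <- detect_communities(g, seed = 7)
  truth <- bench$truth$community_of_node[names(part$membership)]
  expect_gte(compare_partitions(part$membership, truth)$nmi, 0.9)
})

test_that("coarse graining counts intra/inter edges and conserves L", {
  g <- two_triangles(bridge = TRUE)
  cg <- coarse_grain(g, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))
  expect_equal(sort(cg$communities$intra_edges), c(3, 3))
  expect_equal(nrow(cg$inter), 1)
  expect_equal(cg$inter$edges, 1)
  expect_equal(cg$inter$weight_fraction, 1 / 7)
  expect_equal(cg$total_edges, 7)

  single <- coarse_grain(g, setNames(rep(1, 6), igraph::V(g)$name))
  expect_equal(nrow(single$inter), 0)
  expect_equal(single$communities$intra_edges, 7)
})

test_that("edge conservation holds for arbitrary graph/partition pairs", {
  set.seed(99)
  for (i in 1:100) {
    g <- generate_er_graph(sample(5:40, 1), runif(1, 0.05, 0.5), seed = i)
    memb <- setNames(sample(1:4, igraph::vcount(g), replace = TRUE),
                     igraph::V(g)$name)
    cg <- coarse_grain(g, memb)
    expect_identical(sum(cg$communities$intra_edges) + sum(cg$inter$edges),
                     as.integer(igraph::ecount(g)))
    expect_equal(sum(cg$communities$size), igraph::vcount(g))
    expect_true(all(cg$inter$weight_fraction >= 0 & cg$inter$weight_fraction <= 1))
  }
})

test_that("top_communities keeps the k largest plus an explicit keep-list", {
  # communities of sizes 10, 5, 2 with a few inter edges
  memb <- setNames(rep(1:3, times = c(10, 5, 2)), paste0("v", 1:17))
  edges <- data.frame(from = c("v1", "v2", "v11", "v16", "v1", "v1", "v11"),
                      to = c("v2", "v3", "v12", "v17", "v11", "v16", "v16"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = names(memb)))
  cg <- coarse_grain(g, memb)
  top2 <- top_communities(cg, 2)
  expect_setequal(top2$communities$size, c(10, 5))
  expect_true(all(top2$inter$comm_a %in% top2$communities$community))

  with_keep <- top_communities(cg, 2, keep = "C")
  expect_equal(nrow(with_keep$communities), 3)

  expect_warning(all_kept <- top_communities(cg, 10), "exceeds")
  expect_equal(nrow(all_kept$communities), nrow(cg$communities))

  expect_equal(top_communities(cg, 3), cg)
})

test_that("community letters order by size with stable tie-breaks", {
  memb <- setNames(c(0, 0, 0, 1, 1, 2, 2, 2, 2), paste0("v", 1:9))
  part <- structure(list(membership = memb, q = 0, n_communities = 3),
                    class = "gcn_partition")
  lett <- community_letters(part)
  expect_equal(unname(lett[c("2", "0", "1")]), c("A", "B", "C"))
})
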