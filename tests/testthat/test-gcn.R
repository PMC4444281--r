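# Correlation matrices, thresholded network construction, threshold
# selection, connectivity and the degree table.

em_from_rows <- function(rows, groups) {
  vals <- do.call(rbind, rows)
  colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  expression_matrix(vals, groups)
}

corr_from_matrix <- function(r) {
  # hand-built correlation_matrix for direct network tests
  structure(list(r = r, n_pairs = matrix(10, nrow(r), ncol(r)), group = "E"),
            class = "correlation_matrix")
}

make_em_gcn <- function(n_genes, n_per_group, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 2 * n_per_group), n_genes,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 paste0("s", seq_len(2 * n_per_group))))
  expression_matrix(vals, rep(c("E", "L"), each = n_per_group))
}

test_that("perfect linear relations give r of exactly +/- 1 and hand value sqrt(3)/2", {
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  em <- em_from_rows(list(gx = x, gy = 2 * x + 1, gz = -x),
                     rep(c("E", "L"), each = 4))
  r <- correlation_matrix(em, "E")$r
  expect_equal(r["gx", "gy"], 1)
  expect_equal(r["gx", "gz"], -1)

  em2 <- em_from_rows(list(gx = c(1, 2, 3, 9, 9, 9), gy = c(1, 2, 2, 9, 9, 9)),
                      c("E", "E", "E", "L", "L", "L"))
  r2 <- correlation_matrix(em2, "E")$r
  expect_equal(r2["gx", "gy"], sqrt(3) / 2, tolerance = 1e-12)
})

test_that("correlation is invariant to positive affine per-gene rescaling", {
  em <- make_em_gcn(20, 6, seed = 8)
  r1 <- correlation_matrix(em, "E")$r
  scaled <- em$values * runif(20, 0.5, 3) + rnorm(20)
  em2 <- expression_matrix(scaled, em$group_of_sample)
  r2 <- correlation_matrix(em2, "E")$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("zero-variance genes are excluded and short pairs are NA", {
  em <- em_from_rows(list(gconst = c(5, 5, 5, 5, 1, 2, 3, 4),
                          ga = c(1, 2, 3, 4, 1, 2, 3, 4),
                          gb = c(2, 1, 4, 3, 1, 2, 3, 4)),
                     rep(c("E", "L"), each = 4))
  expect_message(cm <- correlation_matrix(em, "E"), "zero-variance")
  expect_false("gconst" %in% rownames(cm$r))

  em2 <- em_from_rows(list(ga = c(1, 2, NA, NA, 1, 2, 3, 4),
                           gb = c(2, 1, 3, NA, 1, 2, 3, 4),
                           gc = c(1, 3, 2, 4, 1, 2, 3, 4)),
                      rep(c("E", "L"), each = 4))
  cm2 <- correlation_matrix(em2, "E")
  expect_true(is.na(cm2$r["ga", "gb"]))  # only 2 complete pairs
  expect_equal(cm2$n_pairs["ga", "gb"], 2)
})

test_that("thresholding follows the |r| rule and keeps the giant component", {
  r <- diag(3)
  rownames(r) <- colnames(r) <- c("g1", "g2", "g3")
  r["g1", "g2"] <- r["g2", "g1"] <- -0.99  # negative: |r| must count
  r["g1", "g3"] <- r["g3", "g1"] <- 0.50
  r["g2", "g3"] <- r["g3", "g2"] <- 0.30
  cm <- corr_from_matrix(r)

  net <- suppressMessages(build_network(cm, 0.9))
  expect_setequal(igraph::V(net)$name, c("g1", "g2"))
  expect_equal(igraph::ecount(net), 1)
  expect_equal(net$tau, 0.9)

  tri <- build_network(cm, 0.2)
  expect_equal(igraph::vcount(tri), 3)
  expect_equal(igraph::ecount(tri), 3)

  expect_error(build_network(cm, 0.999), class = "gcntools_empty_network_error")
})

test_that("edge sets shrink monotonically as tau rises", {
  sim <- generate_modular_expression(synthetic_spec(
    n_genes = 60, n_modules = 3, module_corr = 0.7, seed = 3))
  cm <- correlation_matrix(sim$expr, "E")
  taus <- c(0.3, 0.5, 0.7, 0.9)
  edge_sets <- lapply(taus, function(tau) {
    a <- abs(cm$r); a[is.na(a)] <- 0
    idx <- which(a >= tau & upper.tri(a), arr.ind = TRUE)
    paste(rownames(cm$r)[idx[, 1]], rownames(cm$r)[idx[, 2]])
  })
  for (i in seq_along(taus)[-1]) {
    expect_true(all(edge_sets[[i]] %in% edge_sets[[i - 1]]))
  }
})

test_that("connectivity equals 2L/N and the mean degree", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(connectivity(tri), 2)
  g <- generate_er_graph(80, 0.1, seed = 2)
  expect_equal(connectivity(g), mean(igraph::degree(g)))
  expect_equal(connectivity(g), 2 * igraph::ecount(g) / igraph::vcount(g))
})

test_that("degree table is normalized and satisfies the handshake lemma", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:5)
  tab <- degree_distribution_table(star)
  expect_equal(tab, data.frame(degree = c(1L, 4L), count = c(4L, 1L),
                               freq = c(0.8, 0.2)))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("v", 1:4)
  expect_equal(degree_distribution_table(k4),
               data.frame(degree = 3L, count = 4L, freq = 1))
  g <- generate_er_graph(60, 0.15, seed = 4)
  tab2 <- degree_distribution_table(g)
  expect_equal(sum(tab2$freq), 1)
  expect_equal(sum(tab2$degree * tab2$count), 2 * igraph::ecount(g))
})

test_that("threshold selection picks the top of the grid for scale-invariant structure", {
  # one perfect module: every |r| = 1, so any tau gives the complete graph
  n <- 12
  r <- matrix(1, n, n) * outer(rep_len(c(1, -1), n), rep_len(c(1, -1), n))
  diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("g", seq_len(n))
  sel <- select_threshold(corr_from_matrix(r), tau_grid = seq(0.5, 0.9, 0.1),
                          seed = 1)
  expect_equal(sel$tau, 0.9)
  expect_true(all(sel$report$giant_frac == 1))
})

test_that("threshold selection recovers two planted blocks stably", {
  sim <- generate_modular_expression(synthetic_spec(
    n_genes = 200, n_modules = 2, module_corr = 0.9, de_fraction = 0, seed = 5))
  cm <- correlation_matrix(sim$expr, "E")
  sel <- select_threshold(cm, tau_grid = seq(0.50, 0.95, 0.05), seed = 1)
  net <- suppressMessages(build_network(cm, sel$tau))
  part <- detect_communities(net, seed = 1)
  expect_equal(part$n_communities, 2)
  truth <- sim$truth$module_of_gene[names(part$membership)]
  # 7 samples per group leave a little assignment noise at the block edges
  expect_gte(compare_partitions(part$membership, truth)$ari, 0.9)
  rep_row <- sel$report[sel$report$tau == sel$tau, ]
  expect_true(is.na(rep_row$ari_lo) || rep_row$ari_lo >= 0.9)
})

test_that("a grid above every |r| raises a structured error with the report", {
  sim <- generate_modular_expression(synthetic_spec(
    n_genes = 30, n_modules = 2, module_corr = 0.3, seed = 6))
  cm <- correlation_matrix(sim$expr, "E")
  err <- tryCatch(select_threshold(cm, tau_grid = c(0.9985, 0.999), seed = 1),
                  gcntools_no_threshold_error = function(e) e)
  expect_s3_class(err, "gcntools_no_threshold_error")
  expect_true(is.data.frame(err$report))
})
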