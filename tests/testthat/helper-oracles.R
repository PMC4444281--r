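# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# BFS-ring oracle for concentric degrees: label rings by shortest-path
# distance from `node`, then count edges with one endpoint at distance 1 and
# the other at distance 2.
oracle_concentric <- function(g, node) {
  d <- igraph::distances(g, v = node)[1, ]
  el <- igraph::as_edgelist(g, names = TRUE)
  d1 <- d[el[, 1]]
  d2 <- d[el[, 2]]
  k1 <- sum((d1 == 1 & d2 == 2) | (d1 == 2 & d2 == 1))
  c(k0 = sum(d == 1), k1 = k1)
}

# All set partitions of 1..n as a list of membership vectors (restricted
# growth strings).
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(memb, next_label) {
    i <- length(memb) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible(NULL))
    }
    for (lab in seq_len(next_label)) {
      recurse(c(memb, lab), max(next_label, lab + 1))
    }
  }
  recurse(integer(0), 1)
  out
}

# Modularity straight from its definition, independent of igraph.
oracle_modularity <- function(g, memb) {
  el <- igraph::as_edgelist(g, names = FALSE)
  L <- nrow(el)
  if (L == 0) return(0)
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(memb)) {
    in_c <- which(memb == c)
    e_c <- sum(el[, 1] %in% in_c & el[, 2] %in% in_c)
    d_c <- sum(deg[in_c])
    q <- q + e_c / L - (d_c / (2 * L))^2
  }
  q
}

# Best achievable modularity over all partitions (small n only).
oracle_max_modularity <- function(g) {
  parts <- enumerate_partitions(igraph::vcount(g))
  max(vapply(parts, function(p) oracle_modularity(g, p), numeric(1)))
}

# Closed-form adjusted Rand index from the contingency table.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Exhaustive discrete power-law fit over all candidate xmin values with a
# two-stage alpha grid search (coarse then fine); the normalizer is a
# truncated sum plus the integral tail bound.
oracle_plfit <- function(x, min_tail = 10, min_distinct = 2) {
  zeta_direct <- function(s, a) {
    n_terms <- 20000
    sum((a + 0:(n_terms - 1))^(-s)) + (a + n_terms)^(1 - s) / (s - 1)
  }
  grid_best <- function(alphas, tail_vals, xm) {
    ll <- vapply(alphas, function(al) {
      -length(tail_vals) * log(zeta_direct(al, xm)) - al * sum(log(tail_vals))
    }, numeric(1))
    alphas[which.max(ll)]
  }
  best <- NULL
  for (xm in sort(unique(x))) {
    tail_vals <- x[x >= xm]
    if (length(tail_vals) < min_tail || length(unique(tail_vals)) < min_distinct) next
    coarse <- grid_best(seq(1.1, 10, by = 0.05), tail_vals, xm)
    alpha <- grid_best(seq(coarse - 0.05, coarse + 0.05, by = 0.001),
                       tail_vals, xm)
    support <- xm:max(tail_vals)
    pmf <- support^(-alpha) / zeta_direct(alpha, xm)
    emp <- cumsum(tabulate(tail_vals - xm + 1, nbins = length(support))) /
      length(tail_vals)
    d <- max(abs(emp - cumsum(pmf)))
    if (is.null(best) || d < best$ks) best <- list(alpha = alpha, xmin = xm, ks = d)
  }
  best
}

# Random simple graph helper for property tests.
random_test_graph <- function(n, p, seed) {
  g <- gcntools::generate_er_graph(n, p, seed = seed)
  g
}
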