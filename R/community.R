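# Community detection by multilevel modularity optimization, partition
# comparison, and the coarse-grained community structure (CGCS).

#' Newman-Girvan modularity of a node partition
#'
#' `Q = sum_c [ e_c / L - (d_c / 2L)^2 ]` over communities `c`, where `e_c`
#' is the number of edges inside `c`, `d_c` the total degree of its nodes,
#' and `L` the edge count: the intra-community edge fraction minus its
#' expectation under the degree-preserving random model.
#'
#' @param net An [igraph::igraph] with vertex names.
#' @param assignment Community labels: a named vector covering every node
#'   (any label type), or a [detect_communities()] partition.
#' @return The modularity `Q` (a number in `[-0.5, 1]`). An edgeless graph
#'   yields 0 with a warning.
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' igraph::V(g)$name <- letters[1:6]
#' modularity(g, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))  # 0.5
#' @export
modularity <- function(net, assignment) {
  memb <- as_membership(net, assignment)
  if (igraph::ecount(net) == 0) {
    warning("modularity of an edgeless graph defined as 0")
    return(0)
  }
  igraph::modularity(net, memb)
}

# Normalize any partition representation to a 1-based integer membership
# vector aligned with V(net), erroring on coverage mismatches.
as_membership <- function(net, assignment) {
  if (inherits(assignment, "gcn_partition")) assignment <- assignment$membership
  nodes <- igraph::V(net)$name
  if (is.null(names(assignment))) {
    if (length(assignment) != length(nodes)) {
      stopf("unnamed assignment must have one label per node (%d nodes, %d labels)",
            length(nodes), length(assignment))
    }
    names(assignment) <- nodes
  }
  missing_nodes <- setdiff(nodes, names(assignment))
  if (length(missing_nodes)) {
    stopf("assignment is missing node(s): %s",
          paste(missing_nodes, collapse = ", "))
  }
  as.integer(factor(as.character(assignment[nodes])))
}

#' Detect communities by seeded multilevel modularity optimization
#'
#' Runs the multilevel (Louvain) algorithm — greedy local node moves
#' maximizing the modularity gain, followed by graph aggregation, iterated
#' to convergence — `n_restarts` times under seeded random vertex orders,
#' and returns the partition with the highest modularity. The same seed and
#' restart count always return the identical partition.
#'
#' @param net A connected [igraph::igraph] with vertex names.
#' @param seed Integer seed.
#' @param n_restarts Number of randomized restarts (default 10).
#' @return An object of class `gcn_partition`: list with `membership`
#'   (named, 0-based contiguous community indices), `q` (its modularity),
#'   and `n_communities`.
#' @examples
#' bench <- generate_planted_partition_graph(60, 3, 0.6, 0.02, seed = 1)
#' part <- detect_communities(bench$graph, seed = 1)
#' part$n_communities
#' @export
detect_communities <- function(net, seed = 1, n_restarts = 10) {
  assert_number(n_restarts, "n_restarts", lower = 1, integer = TRUE)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  if (n == 1 || igraph::ecount(net) == 0) {
    memb <- setNames(rep(0L, n), nodes)
    return(structure(list(membership = memb, q = 0, n_communities = min(n, 1L)),
                     class = "gcn_partition"))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(n)  # new id of each old vertex
      g2 <- igraph::permute(net, perm)
      cl <- igraph::cluster_louvain(g2)
      memb <- igraph::membership(cl)[perm]  # back to original order
      q <- igraph::modularity(net, memb)
      if (is.null(best) || q > best$q + 1e-15) {
        best <- list(membership = memb, q = q)
      }
    }
  })
  memb <- as.integer(factor(best$membership, levels = unique(best$membership))) - 1L
  names(memb) <- nodes
  q <- igraph::modularity(net, memb + 1L)
  structure(list(membership = memb, q = q,
                 n_communities = length(unique(memb))),
            class = "gcn_partition")
}

#' @export
print.gcn_partition <- function(x, ...) {
  cat(sprintf("gcn_partition: %d communities over %d nodes, Q = %.4f\n",
              x$n_communities, length(x$membership), x$q))
  invisible(x)
}

#' Compare two partitions by adjusted Rand index and normalized mutual information
#'
#' Both indices equal 1 for identical partitions up to relabeling; the ARI
#' is chance-corrected (0 in expectation for independent partitions).
#'
#' @param a,b Partitions over the same node set: `gcn_partition` objects or
#'   named label vectors.
#' @return A list with `ari` and `nmi`.
#' @export
compare_partitions <- function(a, b) {
  la <- if (inherits(a, "gcn_partition")) a$membership else a
  lb <- if (inherits(b, "gcn_partition")) b$membership else b
  if (is.null(names(la)) || is.null(names(lb))) {
    stopf("partitions must be named by node")
  }
  only_a <- setdiff(names(la), names(lb))
  only_b <- setdiff(names(lb), names(la))
  if (length(only_a) || length(only_b)) {
    stopf("node sets differ; only in a: {%s}; only in b: {%s}",
          paste(only_a, collapse = ", "), paste(only_b, collapse = ", "),
          class = "gcntools_node_mismatch_error")
  }
  common <- names(la)
  ca <- as.integer(factor(as.character(la[common])))
  cb <- as.integer(factor(as.character(lb[common])))
  list(ari = adjusted_rand_index(ca, cb), nmi = normalized_mutual_info(ca, cb))
}

# Closed-form indices from the contingency table. (Computed directly: the
# usual graph-library comparison routine rejects the all-singletons
# partition, a legitimate input here.)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n_pairs <- comb2(length(a))
  expected <- sum_a * sum_b / n_pairs
  denom <- (sum_a + sum_b) / 2 - expected
  # denom is 0 only when both partitions are all-singletons or both are
  # all-in-one, i.e. they are identical
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

normalized_mutual_info <- function(a, b) {
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha + hb == 0) return(1)  # both partitions trivial and identical
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}

#' Community letter labels in descending size order
#'
#' Communities are reported as letters A, B, C, ... (then AA, AB, ...)
#' ordered by decreasing node count, ties broken by community index.
#'
#' @param part A `gcn_partition`.
#' @return Named character vector mapping community index (as character) to
#'   letter.
#' @export
community_letters <- function(part) {
  sizes <- table(part$membership)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  idx <- names(sizes)[ord]
  letters_seq <- make_letter_labels(length(idx))
  setNames(letters_seq, idx)
}

make_letter_labels <- function(n) {
  single <- LETTERS
  if (n <= 26) return(single[seq_len(n)])
  double <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, double)[seq_len(n)]
}

#' Contract a network into its coarse-grained community structure
#'
#' Contracts each community to a single node; edges accumulate as
#' connection weights. Equivalent to reading the partition's mixing matrix
#' as an adjacency matrix: diagonal entries are intra-community edge counts,
#' off-diagonal entries inter-community edge counts. `weight_fraction` is
#' each inter-community count divided by the total edge count `L`.
#'
#' @param net An [igraph::igraph] with vertex names.
#' @param part A partition of `net` (`gcn_partition` or named labels).
#' @return An object of class `coarse_network`: list with `communities`
#'   (data frame: `community`, `letter`, `size`, `intra_edges`), `inter`
#'   (data frame: `comm_a`, `comm_b`, `edges`, `weight_fraction`, with
#'   `comm_a < comm_b`), and `total_edges`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, c - d)
#' cg <- coarse_grain(g, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))
#' cg$inter  # one bridge edge, weight fraction 1/7
#' @export
coarse_grain <- function(net, part) {
  memb <- as_membership(net, part)  # 1-based codes
  codes <- sort(unique(memb))
  sizes <- tabulate(memb, nbins = max(codes))[codes]
  el <- igraph::as_edgelist(net, names = TRUE)
  ca <- memb[match(el[, 1], igraph::V(net)$name)]
  cb <- memb[match(el[, 2], igraph::V(net)$name)]
  lo <- pmin(ca, cb)
  hi <- pmax(ca, cb)
  intra <- vapply(codes, function(c) sum(lo == c & hi == c), integer(1))
  inter_mask <- lo != hi
  L <- igraph::ecount(net)
  if (any(inter_mask)) {
    key <- paste(lo[inter_mask], hi[inter_mask])
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " "))
    inter <- data.frame(comm_a = as.integer(parts[, 1]) - 1L,
                        comm_b = as.integer(parts[, 2]) - 1L,
                        edges = as.integer(tab))
    inter <- inter[order(inter$comm_a, inter$comm_b), , drop = FALSE]
    rownames(inter) <- NULL
    inter$weight_fraction <- inter$edges / L
  } else {
    inter <- data.frame(comm_a = integer(0), comm_b = integer(0),
                        edges = integer(0), weight_fraction = numeric(0))
  }
  # report communities with 0-based indices to match gcn_partition
  comm <- data.frame(community = codes - 1L, size = sizes,
                     intra_edges = intra)
  sizes_named <- setNames(comm$size, comm$community)
  lett <- make_letter_labels(nrow(comm))
  ord <- order(-comm$size, comm$community)
  comm$letter <- NA_character_
  comm$letter[ord] <- lett
  comm <- comm[, c("community", "letter", "size", "intra_edges")]
  structure(list(communities = comm, inter = inter, total_edges = L),
            class = "coarse_network")
}

#' @export
print.coarse_network <- function(x, ...) {
  cat(sprintf("coarse_network: %d communities, %d edges (%d inter-community)\n",
              nrow(x$communities), x$total_edges, sum(x$inter$edges)))
  invisible(x)
}

#' Restrict a coarse network to its largest communities
#'
#' Keeps the `k` communities with the most nodes (ties broken by community
#' index), plus any communities named in `keep` — mirroring reports that
#' show the top communities by size but retain extra ones containing
#' relevant hubs. Weight fractions keep their original denominator (the
#' source network's total edge count).
#'
#' @param coarse A [coarse_grain()] result.
#' @param k Number of largest communities to keep.
#' @param keep Optional vector of community letters (or 0-based indices) to
#'   retain regardless of size.
#' @return A `coarse_network` restricted to the selected communities.
#' @export
top_communities <- function(coarse, k, keep = NULL) {
  assert_number(k, "k", lower = 1, integer = TRUE)
  comm <- coarse$communities
  if (k >= nrow(comm)) {
    if (k > nrow(comm)) {
      warning(sprintf("k = %d exceeds the %d communities; keeping all", k, nrow(comm)))
    }
    sel <- comm$community
  } else {
    ord <- order(-comm$size, comm$community)
    sel <- comm$community[ord][seq_len(k)]
  }
  if (!is.null(keep)) {
    extra <- comm$community[comm$letter %in% as.character(keep) |
                              comm$community %in% suppressWarnings(as.integer(keep))]
    sel <- union(sel, extra)
  }
  inter <- coarse$inter[coarse$inter$comm_a %in% sel &
                          coarse$inter$comm_b %in% sel, , drop = FALSE]
  rownames(inter) <- NULL
  structure(list(communities = comm[comm$community %in% sel, , drop = FALSE],
                 inter = inter, total_edges = coarse$total_edges),
            class = "coarse_network")
}
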