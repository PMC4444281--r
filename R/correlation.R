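# Pairwise Pearson correlation over one sample group.

#' Pearson correlation matrix of genes within one sample group
#'
#' Computes all pairwise Pearson correlations between genes using only the
#' samples of `group`, with pairwise-complete handling of missing values.
#' Genes with zero variance within the group are excluded (with a message):
#' their correlation is undefined. Pairs with fewer than three complete
#' sample pairs have undefined correlation and are recorded as `NA`, which
#' every thresholding rule treats as "below any threshold".
#'
#' @param em An [expression_matrix()].
#' @param group One of the two group labels of `em`.
#' @return An object of class `correlation_matrix`: list with `r` (symmetric
#'   correlation matrix, unit diagonal, `NA` where undefined), `n_pairs`
#'   (integer matrix of complete-pair counts) and `group`.
#' @examples
#' sim <- generate_modular_expression(
#'   synthetic_spec(n_genes = 20, n_modules = 2, seed = 1))
#' cm <- correlation_matrix(sim$expr, "E")
#' range(cm$r[upper.tri(cm$r)])
#' @export
correlation_matrix <- function(em, group) {
  x <- group_values(em, group)
  if (ncol(x) < 3) stopf("group '%s' has fewer than 3 samples", group)
  v <- apply(x, 1, function(row) var(row, na.rm = TRUE))
  constant <- !is.na(v) & v == 0
  if (any(constant)) {
    message(sprintf("correlation_matrix: excluding %d zero-variance gene(s) in group %s",
                    sum(constant), group))
    x <- x[!constant, , drop = FALSE]
  }
  xt <- t(x)
  r <- suppressWarnings(cor(xt, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(xt))
  r[n_pairs < 3] <- NA_real_
  diag(r) <- 1
  # clamp floating-point spill just outside [-1, 1]
  r[!is.na(r) & r > 1] <- 1
  r[!is.na(r) & r < -1] <- -1
  structure(list(r = r, n_pairs = n_pairs, group = group),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d genes, group %s\n", nrow(x$r), x$group))
  invisible(x)
}
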