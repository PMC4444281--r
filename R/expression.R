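# Gene-universe filtering and the two-group differential-expression screen.

#' Restrict an expression matrix to a caller-supplied gene universe
#'
#' Keeps the rows named in `keep_genes`, preserving the original row order.
#' Typical use: restricting to the set of validly annotated genes before any
#' network is built.
#'
#' @param em An [expression_matrix()].
#' @param keep_genes Non-empty character vector of gene identifiers.
#' @return The row-subset [expression_matrix()].
#' @export
filter_gene_universe <- function(em, keep_genes) {
  if (length(keep_genes) == 0) stopf("'keep_genes' must be non-empty")
  keep <- genes_of(em) %in% keep_genes
  if (!any(keep)) {
    stopf("no genes left: 'keep_genes' shares no identifiers with the matrix",
          class = "gcntools_empty_universe_error")
  }
  dropped <- sum(!keep)
  if (dropped > 0) message(sprintf("filter_gene_universe: dropped %d of %d genes",
                                   dropped, nrow(em$values)))
  expression_matrix(em$values[keep, , drop = FALSE], em$group_of_sample)
}

#' Two-group differential expression screen by per-gene t-test
#'
#' Runs an unpaired two-sample t-test per gene between the two sample groups,
#' with missing values removed pairwise per gene. The default is Student's
#' pooled-variance test; Welch's unequal-variance test is available via
#' `variant`. `direction` is `"up"` when the group-A mean exceeds the group-B
#' mean (group A = first group level of `em`), `"down"` when it is lower, and
#' `NA` when the means tie. Genes constant in both groups with equal means
#' get `t = 0`, `p = 1`; genes with fewer than two finite values in either
#' group are excluded as untestable (their identifiers are kept in the
#' `"untestable"` attribute of the result).
#'
#' @param em An [expression_matrix()].
#' @param alpha Significance level for the `significant` flag (default 0.05,
#'   unadjusted, the conventional microarray screen).
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param adjust If `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column `p_adj` (reporting only; `significant` still uses raw p).
#' @return A data frame with columns `gene`, `t_stat`, `p_value`,
#'   `direction`, `significant` (and optionally `p_adj`), one row per
#'   testable gene, in input gene order.
#' @examples
#' vals <- rbind(gA = c(1:7, 4:10))
#' colnames(vals) <- paste0("s", 1:14)
#' em <- expression_matrix(vals, rep(c("E", "L"), each = 7))
#' differential_expression(em)
#' @export
differential_expression <- function(em, alpha = 0.05,
                                    variant = c("student", "welch"),
                                    adjust = FALSE) {
  variant <- match.arg(variant)
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  ga <- group_levels(em)[1]
  gb <- group_levels(em)[2]
  xa <- group_values(em, ga)
  xb <- group_values(em, gb)

  row_stats <- function(x) {
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mean = m, var = v)
  }
  sa <- row_stats(xa)
  sb <- row_stats(xb)

  testable <- sa$n >= 2 & sb$n >= 2
  if (any(!testable)) {
    message(sprintf("differential_expression: %d untestable gene(s) excluded (< 2 finite values in a group)",
                    sum(!testable)))
  }
  na <- sa$n[testable]; nb <- sb$n[testable]
  ma <- sa$mean[testable]; mb <- sb$mean[testable]
  va <- sa$var[testable]; vb <- sb$var[testable]
  diff <- ma - mb

  if (variant == "student") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }

  t_stat <- diff / se
  # zero pooled SD: equal means -> no evidence (t = 0, p = 1); unequal
  # means with zero variance -> infinitely strong evidence (p = 0)
  degen <- !is.finite(t_stat)
  t_stat[degen & diff == 0] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[degen & diff == 0] <- 1
  p[degen & diff != 0] <- 0
  df[!is.finite(df)] <- NA_real_

  direction <- ifelse(diff > 0, "up", ifelse(diff < 0, "down", NA_character_))
  res <- data.frame(gene = genes_of(em)[testable],
                    t_stat = t_stat,
                    p_value = p,
                    direction = direction,
                    significant = p < alpha,
                    stringsAsFactors = FALSE)
  if (adjust) res$p_adj <- p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  attr(res, "untestable") <- genes_of(em)[!testable]
  attr(res, "groups") <- c(ga, gb)
  res
}

#' Write a differential-expression table as TSV
#'
#' @param de Result of [differential_expression()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
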