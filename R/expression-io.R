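# Readers and writers for the plain-text interchange formats: expression TSV
# (first column = gene ID, header row = sample IDs) and a two-column
# sample-to-group map TSV.

#' Read an expression matrix and its sample-to-group map from TSV files
#'
#' The expression file is tab-separated with a header row of sample
#' identifiers and gene identifiers in the first column. Non-numeric cells
#' become missing values; genes whose rows are entirely missing are dropped
#' (with a message reporting the count). The group map is a two-column TSV
#' (sample, group) covering every sample with exactly two group labels; the
#' order in which labels first appear fixes which group is "A".
#'
#' @param path Path to the expression TSV.
#' @param group_map_path Path to the sample-to-group TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, group_map_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3) stopf("expression file '%s' needs a gene column and >= 2 samples", path)
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stopf("duplicate gene identifier(s) in '%s': %s", path,
          paste(dup, collapse = ", "), class = "gcntools_parse_error")
  }
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df))
  dimnames(vals) <- list(genes, names(df)[-1])

  gm <- utils::read.delim(group_map_path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(gm) < 2) stopf("group map '%s' needs two columns (sample, group)", group_map_path)
  groups <- setNames(gm[[2]], gm[[1]])
  missing <- setdiff(colnames(vals), names(groups))
  if (length(missing)) {
    stopf("group map '%s' is missing sample(s): %s", group_map_path,
          paste(missing, collapse = ", "), class = "gcntools_parse_error")
  }

  all_na <- rowSums(!is.na(vals)) == 0
  if (any(all_na)) {
    message(sprintf("dropping %d gene(s) with no finite values", sum(all_na)))
    vals <- vals[!all_na, , drop = FALSE]
  }
  expression_matrix(vals, groups[colnames(vals)])
}

#' Write an expression matrix as TSV
#'
#' First column `gene`, remaining columns the samples; values written in full
#' precision. Round-trips through [read_expression_matrix()].
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene = genes_of(em),
                   format(em$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sample-to-group map as a two-column TSV
#'
#' @inheritParams write_expression_matrix
#' @return Invisibly, `path`.
#' @export
write_group_map <- function(em, path) {
  df <- data.frame(sample = samples_of(em),
                   group = as.character(em$group_of_sample),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
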