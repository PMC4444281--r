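#' Expression matrix with sample group labels
#'
#' Container for a genes-by-samples matrix of (typically log-scale) expression
#' intensities together with a two-group assignment of samples. The first
#' level of the group factor is treated as "group A" everywhere a sign or
#' direction depends on group order (e.g. the direction of differential
#' expression).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must carry
#'   unique row and column names.
#' @param group_of_sample Character or factor vector, one entry per sample
#'   (named by sample or in column order), with exactly two distinct labels.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `group_of_sample` (a named factor whose level
#'   order fixes which group is "A").
#' @examples
#' vals <- matrix(rnorm(12), 3, 4,
#'                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(vals, c(s1 = "E", s2 = "E", s3 = "L", s4 = "L"))
#' em
#' @export
expression_matrix <- function(values, group_of_sample) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stopf("'values' must have gene row names and sample column names")
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stopf("duplicate gene identifier(s): %s", paste(unique(dup), collapse = ", "))
  }
  dup <- samples[duplicated(samples)]
  if (length(dup)) {
    stopf("duplicate sample identifier(s): %s", paste(unique(dup), collapse = ", "))
  }
  grp <- group_of_sample
  if (!is.null(names(grp))) {
    missing <- setdiff(samples, names(grp))
    if (length(missing)) {
      stopf("no group assigned to sample(s): %s", paste(missing, collapse = ", "))
    }
    grp <- grp[samples]
  } else if (length(grp) != length(samples)) {
    stopf("'group_of_sample' must name every sample (%d samples, %d labels)",
          length(samples), length(grp))
  }
  if (!is.factor(grp)) grp <- factor(grp, levels = unique(as.character(grp)))
  grp <- droplevels(grp)
  if (nlevels(grp) != 2) {
    stopf("exactly two groups required, found %d (%s)",
          nlevels(grp), paste(levels(grp), collapse = ", "))
  }
  if (any(table(grp) < 2)) {
    small <- names(which(table(grp) < 2))
    stopf("group '%s' has fewer than 2 samples", small[1])
  }
  names(grp) <- samples
  structure(list(values = values, group_of_sample = grp),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$group_of_sample)
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

genes_of <- function(em) rownames(em$values)
samples_of <- function(em) colnames(em$values)
group_levels <- function(em) levels(em$group_of_sample)

# Columns belonging to one group, as a genes x samples submatrix.
group_values <- function(em, group) {
  if (!group %in% group_levels(em)) {
    stopf("unknown group '%s' (groups: %s)", group,
          paste(group_levels(em), collapse = ", "))
  }
  em$values[, em$group_of_sample == group, drop = FALSE]
}
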