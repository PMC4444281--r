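# Plain-text graph and result writers: edge-list TSV, GraphML, partition
# TSV, degree table TSV and JSON summaries.

#' Write a network as an edge-list TSV
#'
#' Columns `node_a`, `node_b` and, when present, the signed correlation `r`
#' of each edge.
#'
#' @param net An [igraph::igraph] with vertex names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2], stringsAsFactors = FALSE)
  if ("r" %in% igraph::edge_attr_names(net)) {
    df$r <- igraph::E(net)$r
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV back into a graph
#'
#' Inverse of [write_edge_list()]; an `r` column, if present, becomes an
#' edge attribute.
#'
#' @param path Path to the edge-list TSV.
#' @return A simple undirected [igraph::igraph].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Write a network as GraphML
#'
#' The selected threshold `tau` (when present) travels as a graph attribute.
#'
#' @inheritParams write_edge_list
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a partition as TSV with community letters
#'
#' Columns `node`, `community` (0-based index) and `letter` (size-ordered
#' label).
#'
#' @param part A `gcn_partition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(part, path) {
  lett <- community_letters(part)
  df <- data.frame(node = names(part$membership),
                   community = part$membership,
                   letter = unname(lett[as.character(part$membership)]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition TSV back into a membership vector
#'
#' @param path Path written by [write_partition()].
#' @return Named integer vector of community indices.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(as.integer(df$community), df$node)
}

#' Write a coarse-grained community structure as TSV
#'
#' Weighted community edge list: `comm_a`, `comm_b` (letters), `edges`,
#' `weight_fraction`.
#'
#' @param coarse A [coarse_grain()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coarse_network <- function(coarse, path) {
  lett <- setNames(coarse$communities$letter,
                   coarse$communities$community)
  df <- coarse$inter
  df$comm_a <- unname(lett[as.character(df$comm_a)])
  df$comm_b <- unname(lett[as.character(df$comm_b)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
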