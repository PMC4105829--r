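#' Write an edge table to TSV
#'
#' Writes the edges of a network, or the rows of a comparison result, as a
#' tab-separated table sorted by ascending p-value. The file round-trips
#' through [read_edge_table()].
#'
#' @param x a [phenotype_network()], `comparison_result`, or plain edge data
#'   frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(x, path) {
  df <- if (inherits(x, "phenotype_network")) x$edges
        else if (is.data.frame(x)) as.data.frame(x)
        else stop("cannot write an edge table for class ",
                  paste(class(x), collapse = "/"), call. = FALSE)
  ord_col <- intersect(c("perm_pvalue", "pvalue"), names(df))
  if (nrow(df) && length(ord_col))
    df <- df[order(df[[ord_col[1]]]), , drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open output path: ", path, call. = FALSE))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge table written by [write_edge_table()]
#'
#' @param path path to a TSV edge table.
#' @return Data frame.
#' @export
read_edge_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Convert a network to an igraph object
#'
#' Undirected networks become undirected igraph graphs with edge attributes
#' `pcor` and `pvalue` and node attribute `degree`. Partially directed
#' networks become directed graphs in which every edge carries a `direction`
#' attribute (`"directed"` or `"undirected"`); oriented edges run
#' source -> sink.
#'
#' @param x a [phenotype_network()], `directed_network`, or
#'   `comparison_result`.
#' @return An igraph graph.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "phenotype_network")) {
    e <- x$edges
    g <- igraph::graph_from_data_frame(
      e[c("node1", "node2", "pcor", "pvalue")],
      directed = FALSE,
      vertices = data.frame(name = x$nodes, stringsAsFactors = FALSE)
    )
  } else if (inherits(x, "directed_network")) {
    e <- x$edges
    from <- ifelse(e$directed, e$source, e$node1)
    to <- ifelse(e$directed, e$sink, e$node2)
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, pcor = e$pcor, pvalue = e$pvalue,
                 log_ratio = e$log_ratio,
                 direction = ifelse(e$directed, "directed", "undirected"),
                 stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = x$nodes, spv = as.numeric(x$spv),
                            stringsAsFactors = FALSE)
    )
  } else if (inherits(x, "comparison_result")) {
    keep <- x$edge_class != "absent"
    e <- as.data.frame(x)[keep, , drop = FALSE]
    nodes <- sort(unique(c(x$node1, x$node2)))
    g <- igraph::graph_from_data_frame(
      e[c("node1", "node2", "pcor_A", "pcor_B", "perm_pvalue", "edge_class")],
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
    )
  } else {
    stop("cannot convert class ", paste(class(x), collapse = "/"),
         " to igraph", call. = FALSE)
  }
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export a network as GraphML or DOT
#'
#' Edge attributes (`pcor`, `pvalue`, plus `direction`/`edge_class` where
#' applicable) and the node `degree` attribute are included. GraphML files
#' round-trip through igraph; DOT files render with Graphviz, distinguishing
#' directed and undirected edges.
#'
#' @param x a [phenotype_network()], `directed_network`, or
#'   `comparison_result`.
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(x, path, format = c("graphml", "dot")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown graph format: ", format[1], " (use 'graphml' or 'dot')",
         call. = FALSE))
  g <- as_igraph(x)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
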