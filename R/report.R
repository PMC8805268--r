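# Gene-level statistical epistasis network assembly and export.

#' Build the gene-level epistasis network
#'
#' Nodes are the genes appearing in any retained effect (marginal PIP above
#' the threshold or endpoint of a retained interaction), with their marginal
#' PIP as a vertex attribute; edges are the gene pairs whose interaction PIP
#' exceeds the threshold, weighted by that PIP.
#'
#' @param ps an `epistasis_fit`.
#' @param threshold PIP threshold (default 0: any inclusion event).
#' @return an undirected [igraph::igraph] with `pip` vertex and edge
#'   attributes.
#' @export
build_epistasis_network <- function(ps, threshold = 0) {
  sel <- select_effects(ps, threshold = threshold)
  nodes <- sort(unique(c(sel$genes$gene, sel$pairs$gene1, sel$pairs$gene2)))
  vs <- data.frame(name = nodes,
                   pip = as.numeric(ps$marginal_pip[nodes]),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(sel$pairs[, c("gene1", "gene2")],
                                     directed = FALSE, vertices = vs)
  igraph::E(g)$pip <- sel$pairs$pip
  g
}

#' Export an epistasis network
#'
#' * `graphml`: full network with PIP attributes (accepted by Cytoscape and
#'   similar viewers).
#' * `edge_tsv`: `gene1`, `gene2`, `pip`, sorted by decreasing PIP then
#'   lexicographically.
#' * `gene_list`: one gene symbol per line (the plain search-term format of
#'   gene-network web services).
#'
#' @param net an igraph network from [build_epistasis_network()].
#' @param path output file.
#' @param fmt `"graphml"`, `"edge_tsv"` or `"gene_list"`.
#' @export
export_network <- function(net, path, fmt = c("graphml", "edge_tsv",
                                              "gene_list")) {
  fmt <- match.arg(fmt)
  if (fmt == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else if (fmt == "edge_tsv") {
    if (igraph::ecount(net)) {
      ends <- igraph::as_edgelist(net)
      df <- data.frame(gene1 = pmin(ends[, 1L], ends[, 2L]),
                       gene2 = pmax(ends[, 1L], ends[, 2L]),
                       pip = igraph::E(net)$pip, stringsAsFactors = FALSE)
      df <- df[order(-df$pip, df$gene1, df$gene2), , drop = FALSE]
    } else {
      df <- data.frame(gene1 = character(), gene2 = character(),
                       pip = numeric())
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(sort(igraph::V(net)$name), path)
  }
  invisible(path)
}
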