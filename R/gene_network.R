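# Within-gene SNP network inference (MRMR greedy ranking, MRNET
# symmetrization) and the network statistics reported per gene.

#' Greedy maximum-relevance-minimum-redundancy ranking
#'
#' For a target SNP, ranks all other SNPs of the gene by the incremental MRMR
#' rule: the first pick maximises relevance `u_j = Syn(j, target)`, each
#' subsequent pick maximises `u_j - r_j` where the redundancy
#' `r_j = mean_{k in S} Syn(j, k)` is taken over the already selected set S.
#' Ties are broken toward the lower node index.
#'
#' @param s synergy matrix (symmetric, zero diagonal).
#' @param target target node: column index or SNP id.
#' @return data.frame with columns `node` (index), `snp` (id, if named) and
#'   `score` (the MRMR score at selection time), in selection order.
#' @export
mrmr_rank <- function(s, target) {
  W <- unclass(s)
  m <- ncol(W)
  if (m < 2L) stop("need at least two SNPs")
  if (is.character(target)) target <- match(target, colnames(W))
  if (is.na(target) || target < 1L || target > m)
    stop("target out of range")
  rel <- W[, target]
  cand <- setdiff(seq_len(m), target)
  sel <- integer(0)
  scores <- numeric(0)
  S <- integer(0)
  while (length(cand)) {
    sc <- if (!length(S)) rel[cand]
          else rel[cand] - rowMeans(W[cand, S, drop = FALSE])
    pick <- which.max(sc)            # first maximum: lower node index wins
    sel <- c(sel, cand[pick])
    scores <- c(scores, sc[pick])
    S <- c(S, cand[pick])
    cand <- cand[-pick]
  }
  data.frame(node = sel,
             snp = if (is.null(colnames(W))) as.character(sel)
                   else colnames(W)[sel],
             score = scores, stringsAsFactors = FALSE)
}

#' Infer the within-gene SNP network (MRNET)
#'
#' Runs [mrmr_rank()] with every node as target; the directed score of edge
#' `j -> target` is j's selection-time MRMR score, the undirected weight is
#' the maximum of the two directions, and edges with non-positive weight are
#' removed.  Isolated nodes stay in the node list.
#'
#' @param s synergy matrix.
#' @return an object of class `gene_graph`: list with `gene_id`, `nodes`
#'   (SNP ids) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
infer_network <- function(s) {
  W <- unclass(s)
  m <- ncol(W)
  if (m < 2L) stop("need at least two SNPs")
  ids <- colnames(W)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  D <- matrix(0, m, m)
  for (t in seq_len(m)) {
    r <- mrmr_rank(s, t)
    D[cbind(r$node, t)] <- r$score
  }
  U <- pmax(D, t(D))
  keep <- which(upper.tri(U) & U > 0, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1L]], to = ids[keep[, 2L]],
                      weight = U[keep], stringsAsFactors = FALSE)
  structure(list(gene_id = attr(s, "gene_id"), nodes = ids, edges = edges),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %s: %d nodes, %d edges\n",
              x$gene_id %||% "?", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a gene graph to igraph
#'
#' @param g a `gene_graph`.
#' @return an undirected [igraph::igraph] with a `weight` edge attribute.
#' @export
as_igraph <- function(g) {
  gr <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = data.frame(name = g$nodes))
  if (nrow(g$edges)) igraph::E(gr)$weight <- g$edges$weight
  gr
}

#' Within-gene network statistics
#'
#' Density (realised over possible edges), mean distance (average unweighted
#' shortest-path length over connected pairs) and global transitivity
#' (3 x triangles / connected triples).  Statistics that are undefined on the
#' graph (no connected pair, no connected triple) are returned as `NA` rather
#' than raising an error.
#'
#' @param g a `gene_graph`.
#' @return named list with `density`, `mean_distance`, `transitivity`.
#' @export
network_properties <- function(g) {
  if (length(g$nodes) < 2L) stop("need at least two nodes")
  gr <- as_igraph(g)
  dens <- igraph::edge_density(gr)
  md <- if (nrow(g$edges) == 0L) NA_real_
        else igraph::mean_distance(gr, weights = NA, directed = FALSE,
                                   unconnected = TRUE)   # hop counts, not
                                                         # synergy weights
  tr <- igraph::transitivity(gr, type = "global")
  if (is.nan(md)) md <- NA_real_
  if (is.nan(tr)) tr <- NA_real_
  list(density = dens, mean_distance = md, transitivity = tr)
}

#' Network-property table over genes
#'
#' @param graphs named list of `gene_graph` objects.
#' @return data.frame with one row per gene: `gene`, `n_snps`, `n_edges`,
#'   `density`, `mean_distance`, `transitivity`.
#' @export
network_properties_table <- function(graphs) {
  rows <- lapply(graphs, function(g) {
    p <- network_properties(g)
    data.frame(gene = g$gene_id %||% NA_character_,
               n_snps = length(g$nodes), n_edges = nrow(g$edges),
               density = p$density, mean_distance = p$mean_distance,
               transitivity = p$transitivity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a gene graph
#'
#' @param g a `gene_graph`.
#' @param path output file.
#' @param format `"edge_tsv"` (columns `from`, `to`, `weight`) or
#'   `"graphml"`.
#' @export
write_gene_graph <- function(g, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gr <- as_igraph(g)
    if (nrow(g$edges)) igraph::E(gr)$weight <- g$edges$weight
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}
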