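#' Weighted undirected gene network
#'
#' Edges are unordered gene pairs with a nonnegative weight. Pairs are
#' canonicalized (lexicographically smaller id first) and stored sorted, so
#' serialized outputs are deterministic. Self-loops and duplicate pairs are
#' rejected.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`
#'   (or a 0-row data.frame / NULL for an empty network).
#' @param nodes character vector of node ids; defaults to the edge
#'   endpoints. Every endpoint must be in `nodes`.
#' @param method_tag label of the producing algorithm (used in SIF output).
#' @return object of class `gene_network` with elements `nodes`, `edges`,
#'   `method_tag`.
#' @export
gene_network <- function(edges = NULL, nodes = NULL, method_tag = "edge") {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = as.character(edges$gene_a),
                        gene_b = as.character(edges$gene_b),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and >= 0")
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edge: ", sub("\r", "--", key[duplicated(key)][1L]))
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- sort(unique(as.character(nodes)))
  missing <- setdiff(c(edges$gene_a, edges$gene_b), nodes)
  if (length(missing)) stop("edge endpoint not in nodes: ", missing[1L])
  structure(list(nodes = nodes, edges = edges, method_tag = method_tag),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network [%s]: %d nodes, %d edges\n",
              x$method_tag, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges / nodes
#' @param net a `gene_network`.
#' @return integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

#' Write a network to SIF, weighted edge-list TSV, or GML
#'
#' Edge order is deterministic (lexicographic by canonical endpoint pair).
#' SIF interaction lines are `nodeA <tab> method_tag <tab> nodeB`; isolated
#' nodes are written as bare single-node lines. The edge TSV has header
#' `gene_a  gene_b  weight`.
#'
#' @param network a `gene_network`.
#' @param path output file path.
#' @param format one of `"sif"`, `"edge_tsv"`, `"gml"`.
#' @return invisibly, the path.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "sif", "gml")) {
  if (length(format) == 1L && !format %in% c("edge_tsv", "sif", "gml"))
    stop("unknown network format '", format, "' (use sif, edge_tsv or gml)")
  format <- match.arg(format)
  e <- network$edges
  con <- file(path, "w")
  on.exit(close(con))
  fmt_w <- function(w) vapply(w, function(x)
    base::format(x, digits = 12, trim = TRUE, scientific = FALSE), "")
  if (format == "edge_tsv") {
    writeLines("gene_a\tgene_b\tweight", con)
    if (nrow(e))
      writeLines(paste(e$gene_a, e$gene_b, fmt_w(e$weight), sep = "\t"), con)
  } else if (format == "sif") {
    if (nrow(e))
      writeLines(paste(e$gene_a, network$method_tag, e$gene_b, sep = "\t"), con)
    isolated <- setdiff(network$nodes, c(e$gene_a, e$gene_b))
    if (length(isolated)) writeLines(isolated, con)
  } else {
    idx <- stats::setNames(seq_along(network$nodes) - 1L, network$nodes)
    writeLines("graph [", con)
    writeLines("  directed 0", con)
    for (nd in network$nodes)
      writeLines(sprintf('  node [ id %d label "%s" ]', idx[[nd]], nd), con)
    if (nrow(e))
      writeLines(sprintf("  edge [ source %d target %d weight %s ]",
                         idx[e$gene_a], idx[e$gene_b], fmt_w(e$weight)), con)
    writeLines("]", con)
  }
  invisible(path)
}

#' Read a network from a weighted edge-list TSV
#'
#' @param path file written by [write_network()] with `format = "edge_tsv"`.
#' @param method_tag label to attach.
#' @return a `gene_network`.
#' @export
read_network <- function(path, method_tag = "edge") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(df)))
    stop("edge TSV must have columns gene_a, gene_b, weight")
  gene_network(df, method_tag = method_tag)
}

# internal: gene_network -> igraph, keeping isolated nodes and weights
.as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
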