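#' Hub genes of an inferred network
#'
#' Nodes ranked by degree descending; ties broken by weighted degree (sum
#' of incident edge weights) descending, then lexicographically by gene id.
#' High-degree nodes are the candidate coordinating regulators of the
#' inferred network.
#'
#' @param network a `gene_network`.
#' @param k number of hubs to return (fewer if the network is smaller).
#' @return character vector of gene ids, best first (empty for an empty
#'   network).
#' @export
hub_genes <- function(network, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  ids <- network$nodes
  if (length(ids) == 0L) return(character())
  e <- network$edges
  deg <- stats::setNames(numeric(length(ids)), ids)
  wdeg <- deg
  if (nrow(e)) {
    td <- table(c(e$gene_a, e$gene_b))
    deg[names(td)] <- as.numeric(td)
    wa <- tapply(e$weight, e$gene_a, sum)
    wb <- tapply(e$weight, e$gene_b, sum)
    wdeg[names(wa)] <- wdeg[names(wa)] + wa
    wdeg[names(wb)] <- wdeg[names(wb)] + wb
  }
  ord <- order(-deg, -wdeg, ids)
  ids[ord][seq_len(min(k, length(ids)))]
}

#' Nominated-edge backbone of a weighted network
#'
#' Keeps an edge iff it is the strongest incident edge of at least one of
#' its endpoints (ties kept), the same maximal-edge principle C3NET applies
#' to mutual information. Inference methods that retain every positive
#' score produce a halo of weak edges around the real structure; on such
#' dense weighted networks raw degree is dominated by that halo, while the
#' backbone concentrates degree on nodes that many partners *nominate* —
#' the behaviour wanted for hub detection. At most `n_nodes` edges survive.
#'
#' @param network a `gene_network`.
#' @return a `gene_network` on the same node set.
#' @export
network_backbone <- function(network) {
  e <- network$edges
  if (nrow(e) == 0L) return(network)
  best <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  ba <- tapply(e$weight, e$gene_a, max)
  bb <- tapply(e$weight, e$gene_b, max)
  best[names(ba)] <- pmax(best[names(ba)], ba)
  best[names(bb)] <- pmax(best[names(bb)], bb)
  keep <- e[e$weight >= pmin(best[e$gene_a], best[e$gene_b]), , drop = FALSE]
  gene_network(keep, nodes = network$nodes, method_tag = network$method_tag)
}

#' Ego subnetwork around a gene
#'
#' Induced subgraph on all nodes within graph distance `radius` of `gene`
#' (the hub-centered neighborhoods used to inspect inferred networks in
#' detail).
#'
#' @param network a `gene_network`.
#' @param gene center gene id (must be a node).
#' @param radius neighborhood radius (>= 1).
#' @return a `gene_network` restricted to the neighborhood.
#' @export
ego_subnetwork <- function(network, gene, radius = 1L) {
  if (radius < 1L) stop("radius must be >= 1")
  if (!gene %in% network$nodes) stop("unknown gene: ", gene)
  ig <- .as_igraph(network)
  keep <- igraph::ego(ig, order = radius, nodes = gene)[[1L]]$name
  e <- network$edges
  e <- e[e$gene_a %in% keep & e$gene_b %in% keep, , drop = FALSE]
  gene_network(e, nodes = keep, method_tag = network$method_tag)
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b nonempty character vectors of gene ids.
#' @return list with `shared` (count), `percent_of_a`, `percent_of_b`
#'   (percentages), `jaccard`.
#' @export
gene_set_overlap <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(set_a) == 0L || length(set_b) == 0L) stop("gene sets must be nonempty")
  shared <- length(intersect(set_a, set_b))
  list(shared = shared,
       percent_of_a = 100 * shared / length(set_a),
       percent_of_b = 100 * shared / length(set_b),
       jaccard = shared / length(union(set_a, set_b)))
}

#' Hypergeometric gene-set enrichment
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' drawing at least the observed number of annotated genes when sampling
#' `|query|` genes without replacement from the universe; q-values are
#' Benjamini-Hochberg adjusted across the tested terms. Annotation gene
#' sets are intersected with the universe before testing.
#'
#' @param query gene set of interest (must be a subset of `universe`).
#' @param universe background gene set.
#' @param annotations named list of term -> gene id vectors, or a
#'   data.frame with columns `term_id`, `gene_id`.
#' @return data.frame with columns `term_id`, `annotated_in_universe`,
#'   `annotated_in_query`, `query_size`, `universe_size`, `p_value`,
#'   `q_value`, sorted by q then p then term.
#' @export
enrich <- function(query, universe, annotations) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  if (is.data.frame(annotations)) {
    if (!all(c("term_id", "gene_id") %in% names(annotations)))
      stop("annotation data.frame needs columns term_id, gene_id")
    annotations <- split(as.character(annotations$gene_id),
                         as.character(annotations$term_id))
  }
  U <- length(universe)
  n <- length(query)
  res <- lapply(names(annotations), function(term) {
    ann <- intersect(unique(annotations[[term]]), universe)
    K <- length(ann)
    k <- length(intersect(ann, query))
    p <- stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
    data.frame(term_id = term, annotated_in_universe = K,
               annotated_in_query = k, query_size = n, universe_size = U,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recovery of a ground-truth network by an inferred network
#'
#' Ground-truth regulator-target edges are treated as undirected and
#' restricted to the inferred network's node set; every unordered node pair
#' is an evaluable pair. Reports precision and recall of the inferred edge
#' set, average-precision AUPR over the weight-ranked edge list (ties
#' broken lexicographically), and the random baseline (truth-edge density
#' among evaluable pairs, which is the expected precision of a random
#' ranking).
#'
#' @param inferred a `gene_network`.
#' @param truth a [generate_ground_truth()] result (or any list with an
#'   `edges` data.frame containing `regulator`, `target`).
#' @return list with `precision`, `recall`, `aupr`, `random_baseline`,
#'   `n_truth_edges`, `n_inferred_edges`.
#' @export
recovery_metrics <- function(inferred, truth) {
  te <- truth$edges
  if (NROW(te) == 0L) stop("ground truth has no edges")
  nodes <- inferred$nodes
  if (!any(c(te$regulator, te$target) %in% nodes))
    stop("inferred and truth node sets do not overlap")
  a <- pmin(te$regulator, te$target)
  b <- pmax(te$regulator, te$target)
  in_nodes <- a %in% nodes & b %in% nodes
  truth_keys <- unique(paste(a[in_nodes], b[in_nodes], sep = "\r"))
  n_truth <- length(truth_keys)
  n_pairs <- choose(length(nodes), 2)
  baseline <- if (n_pairs > 0) n_truth / n_pairs else 0

  e <- inferred$edges
  if (nrow(e) == 0L)
    return(list(precision = NA_real_, recall = 0, aupr = 0,
                random_baseline = baseline, n_truth_edges = n_truth,
                n_inferred_edges = 0L))
  keys <- paste(e$gene_a, e$gene_b, sep = "\r")
  hit <- keys %in% truth_keys
  precision <- sum(hit) / nrow(e)
  recall <- if (n_truth > 0) sum(hit) / n_truth else NA_real_
  ord <- order(-e$weight, e$gene_a, e$gene_b)
  hit_ranked <- hit[ord]
  prec_at <- cumsum(hit_ranked) / seq_along(hit_ranked)
  aupr <- if (n_truth > 0) sum(prec_at[hit_ranked]) / n_truth else NA_real_
  list(precision = precision, recall = recall, aupr = aupr,
       random_baseline = baseline, n_truth_edges = n_truth,
       n_inferred_edges = nrow(e))
}
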