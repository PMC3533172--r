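# Network inference from a mutual-information matrix or expression values.
# All methods return symmetric, self-loop-free, nonnegative-weighted
# gene_network objects with deterministic (lexicographic) tie-breaking.

# build a gene_network from a symmetric weight matrix, keeping w > 0
.network_from_matrix <- function(w, ids, method_tag) {
  ut <- upper.tri(w)
  keep <- which(ut & w > 0, arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[keep[, 1L]], gene_b = ids[keep[, 2L]],
                      weight = w[keep], stringsAsFactors = FALSE)
  gene_network(edges, nodes = ids, method_tag = method_tag)
}

#' MRNET: maximum-relevance / minimum-redundancy network inference
#'
#' For each target gene i, candidates are ranked by greedy MRMR forward
#' selection: the first pick maximizes the relevance `MI(i, j)`; every later
#' pick maximizes `s_j = MI(i, j) - mean_{k in S} MI(j, k)` over the
#' not-yet-selected candidates, where S is the already-selected set
#' (relevance to the target penalized by redundancy with what is already
#' in). Selection runs through *all* candidates, recording each candidate's
#' (possibly negative) score at the moment it is selected. The undirected
#' edge weight is the larger of the two directional scores,
#' `w_ij = max(s_i(j), s_j(i))`, and only edges with positive weight are
#' kept. Argmax ties are broken lexicographically by gene id.
#'
#' @param mim a [build_mim()] result or symmetric MI matrix.
#' @param normalize rescale positive weights by the maximum weight to [0, 1].
#' @return a `gene_network` with `method_tag = "mrnet"`.
#' @export
mrnet <- function(mim, normalize = FALSE) {
  m <- .as_mim_matrix(mim)
  ids <- rownames(m)
  g <- nrow(m)
  scores <- matrix(-Inf, g, g)   # scores[i, j] = score of j when target is i
  for (i in seq_len(g)) {
    remaining <- setdiff(seq_len(g), i)
    redsum <- numeric(g)         # sum of MI(j, k) over selected k
    n_sel <- 0L
    while (length(remaining)) {
      s <- m[i, remaining] - if (n_sel > 0L) redsum[remaining] / n_sel else 0
      pick <- remaining[order(-s, ids[remaining])][1L]
      scores[i, pick] <- s[match(pick, remaining)]
      redsum <- redsum + m[, pick]
      n_sel <- n_sel + 1L
      remaining <- remaining[remaining != pick]
    }
  }
  w <- pmax(scores, t(scores))
  w[w < 0 | !is.finite(w)] <- 0
  if (normalize && max(w) > 0) w <- w / max(w)
  .network_from_matrix(w, ids, "mrnet")
}

#' CLR: context likelihood of relatedness
#'
#' Each MI value is z-scored against the background MI distribution of both
#' genes: with `mu_i`, `sigma_i` the mean and (population, divide-by-m)
#' standard deviation of gene i's off-diagonal MI row,
#' `z_i(j) = max(0, (MI_ij - mu_i) / sigma_i)` (and 0 where `sigma_i = 0`),
#' and the edge weight is `sqrt(z_i(j)^2 + z_j(i)^2)`. Edges with positive
#' weight are kept.
#'
#' @inheritParams mrnet
#' @return a `gene_network` with `method_tag = "clr"`.
#' @export
clr <- function(mim) {
  m <- .as_mim_matrix(mim)
  g <- nrow(m)
  if (g < 3L) stop("CLR needs at least 3 genes for background statistics")
  off <- m
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sigma <- sqrt(rowMeans((off - mu)^2, na.rm = TRUE))
  z <- (m - mu) / ifelse(sigma > 0, sigma, 1)
  z[sigma == 0, ] <- 0
  z[z < 0] <- 0
  diag(z) <- 0
  w <- sqrt(z^2 + t(z)^2)
  .network_from_matrix(w, rownames(m), "clr")
}

#' ARACNE: data-processing-inequality pruning of an MI network
#'
#' Starts from all positive-MI edges. For every gene triple whose three MIs
#' are all positive, the weakest edge is marked for removal if it is
#' strictly below the smaller of the other two minus the tolerance
#' (`MI_ij < min(MI_ik, MI_jk) - eps`); ties survive. All marked edges are
#' removed simultaneously after scanning every triple, so the result does
#' not depend on scan order. Surviving edges keep their MI as weight.
#'
#' @inheritParams mrnet
#' @param eps DPI tolerance, >= 0 (default 0).
#' @return a `gene_network` with `method_tag = "aracne"`.
#' @export
aracne <- function(mim, eps = 0) {
  if (eps < 0) stop("eps must be >= 0")
  m <- .as_mim_matrix(mim)
  g <- nrow(m)
  drop <- matrix(FALSE, g, g)
  for (i in seq_len(g - 1L)) {
    for (j in seq.int(i + 1L, g)) {
      if (m[i, j] <= 0) next
      k <- which(m[i, ] > 0 & m[j, ] > 0)
      k <- k[k != i & k != j]
      if (length(k) && any(m[i, j] < pmin(m[i, k], m[j, k]) - eps))
        drop[i, j] <- drop[j, i] <- TRUE
    }
  }
  w <- m
  w[drop] <- 0
  .network_from_matrix(w, rownames(m), "aracne")
}

#' C3NET: conservative core of significant, row-maximal MI edges
#'
#' Two steps. (1) Significance: the critical value `c` is the `(1 - alpha)`
#' empirical quantile (inverse ECDF) of the permutation-null MI sample; all
#' MI values `<= c` are zeroed. (2) Core: an edge (i, j) is kept iff its
#' surviving MI equals the row maximum of gene i or of gene j (ties keep
#' every maximal edge). Each gene nominates at most one maximal value, so
#' the edge count never exceeds the gene count.
#'
#' @inheritParams mrnet
#' @param null_mis nonempty numeric sample from [permutation_null()].
#' @param alpha significance level in (0, 1).
#' @return a `gene_network` with `method_tag = "c3net"`.
#' @export
c3net <- function(mim, null_mis, alpha = 0.05) {
  if (length(null_mis) == 0L) stop("null_mis must be a nonempty sample")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- .as_mim_matrix(mim)
  crit <- stats::quantile(null_mis, probs = 1 - alpha, type = 1, names = FALSE)
  m[m <= crit] <- 0
  g <- nrow(m)
  keep <- matrix(FALSE, g, g)
  for (i in seq_len(g)) {
    rmax <- max(m[i, ])
    if (rmax > 0) keep[i, m[i, ] == rmax] <- TRUE
  }
  keep <- keep | t(keep)
  w <- m
  w[!keep] <- 0
  .network_from_matrix(w, rownames(m), "c3net")
}

#' Relevance network: direct thresholding of the MI matrix
#'
#' Keeps every edge with `MI > threshold` (strict), weight = MI.
#'
#' @inheritParams mrnet
#' @param threshold nonnegative MI cutoff (bits).
#' @return a `gene_network` with `method_tag = "relnet"`.
#' @export
relevance_network <- function(mim, threshold = 0) {
  if (threshold < 0) stop("threshold must be >= 0")
  m <- .as_mim_matrix(mim)
  m[m <= threshold] <- 0
  .network_from_matrix(m, rownames(m), "relnet")
}

#' Correlation network
#'
#' Pearson or Spearman correlation of all gene pairs; edges where
#' `|r| > threshold` (strict), weight `|r|`. Constant genes have undefined
#' correlation; their coefficients are set to 0 with a warning.
#'
#' @param values genes x samples matrix (>= 3 samples).
#' @param method `"pearson"` or `"spearman"`.
#' @param threshold absolute-correlation cutoff in [0, 1].
#' @return a `gene_network` with `method_tag = "corr"`.
#' @export
correlation_network <- function(values, method = c("pearson", "spearman"),
                                threshold = 0.5) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (ncol(values) < 3L) stop("need at least 3 samples")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ids <- rownames(values)
  if (is.null(ids)) ids <- .gene_ids(nrow(values))
  constant <- apply(values, 1L, function(x) min(x) == max(x))
  r <- suppressWarnings(stats::cor(t(values), method = method))
  if (any(constant)) {
    warning("constant gene(s) assigned correlation 0: ",
            paste(ids[constant], collapse = ", "))
    r[constant, ] <- 0
    r[, constant] <- 0
  }
  r[is.na(r)] <- 0
  w <- abs(r)
  w[w <= threshold] <- 0
  diag(w) <- 0
  .network_from_matrix(w, ids, paste0("corr_", method))
}

#' Partial-correlation filtering of a correlation network
#'
#' Builds the Pearson correlation network at the *high* threshold, then
#' tests every edge against first-order partial correlations: for each edge
#' (i, j) and each third gene k adjacent (at the high threshold) to both i
#' and j, `r_ij.k = (r_ij - r_ik r_jk) / sqrt((1 - r_ik^2)(1 - r_jk^2))`.
#' The edge is removed if some conditioning gene drives `|r_ij.k|` below
#' the *low* threshold — the signature of an indirect association mediated
#' by k. Surviving edges are weighted by their minimum `|r_ij.k|` over the
#' tested k (or `|r_ij|` if no third gene qualified). A conditioning gene
#' with `|r_ik| = 1` would zero the denominator and is skipped with a
#' warning.
#'
#' @param values genes x samples matrix (>= 4 samples).
#' @param high_threshold correlation needed to propose an edge.
#' @param low_threshold partial correlation below which an edge is deemed
#'   indirect; `0 <= low < high <= 1`.
#' @return a `gene_network` with `method_tag = "pcor"`.
#' @export
partial_correlation_filter <- function(values, high_threshold = 0.5,
                                       low_threshold = 0.2) {
  if (!(low_threshold >= 0 && low_threshold < high_threshold && high_threshold <= 1))
    stop("need 0 <= low_threshold < high_threshold <= 1")
  values <- as.matrix(values)
  if (ncol(values) < 4L) stop("need at least 4 samples")
  ids <- rownames(values)
  if (is.null(ids)) ids <- .gene_ids(nrow(values))
  r <- suppressWarnings(stats::cor(t(values)))
  r[is.na(r)] <- 0
  g <- nrow(r)
  adj <- abs(r) > high_threshold
  diag(adj) <- FALSE
  w <- matrix(0, g, g)
  for (i in seq_len(g - 1L)) {
    for (j in seq.int(i + 1L, g)) {
      if (!adj[i, j]) next
      ks <- which(adj[i, ] & adj[j, ])
      ks <- ks[ks != i & ks != j]
      singular <- ks[abs(r[i, ks]) >= 1 - 1e-12 | abs(r[j, ks]) >= 1 - 1e-12]
      if (length(singular)) {
        warning(sprintf("skipping conditioning gene(s) perfectly correlated with %s or %s",
                        ids[i], ids[j]))
        ks <- setdiff(ks, singular)
      }
      if (length(ks)) {
        pc <- abs((r[i, j] - r[i, ks] * r[j, ks]) /
                    sqrt((1 - r[i, ks]^2) * (1 - r[j, ks]^2)))
        if (any(pc < low_threshold)) next
        w[i, j] <- w[j, i] <- min(pc)
      } else {
        w[i, j] <- w[j, i] <- abs(r[i, j])
      }
    }
  }
  rownames(w) <- colnames(w) <- ids
  .network_from_matrix(w, ids, "pcor")
}
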