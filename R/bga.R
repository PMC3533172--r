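#' Between-group analysis (BGA) of an expression matrix
#'
#' BGA ordinates *group means* rather than individual samples: genes are
#' centered across all samples, the group-mean matrix is formed, rows are
#' weighted by `sqrt(n_g / N)` so unbalanced groups do not dominate, and the
#' weighted matrix is decomposed by SVD. This is a PCA of group centroids;
#' the per-axis `variance_fraction` is the fraction of *between-group*
#' inertia (the quantity BGA decomposes), not of total sample variance.
#' Individual samples and genes are projected onto the group axes.
#'
#' The axis sign is fixed deterministically: the largest-magnitude gene
#' loading on each axis is made positive.
#'
#' @param x an [expression_experiment()] or a genes x samples numeric
#'   matrix.
#' @param groups group label per sample (character/factor, length = number
#'   of samples), or — when `x` is an experiment — metadata column name(s)
#'   such as `"condition"` or `c("condition", "tissue")`, pasted to form
#'   the labels.
#' @param n_axes number of axes to retain; default all non-null axes
#'   (at most `min(groups - 1, genes)`).
#' @return object of class `bga`: list with `group_scores` (groups x axes),
#'   `sample_scores` (samples x axes), `gene_loadings` (genes x axes,
#'   orthonormal columns), `variance_fraction` (over all non-null axes,
#'   sums to 1), `axes`, `group_labels`, `group_sizes`.
#' @export
between_group_analysis <- function(x, groups, n_axes = NULL) {
  if (inherits(x, "ExpressionExperiment")) {
    if (is.character(groups) && length(groups) <= 2L &&
        all(groups %in% names(x$samples))) {
      groups <- do.call(paste, c(x$samples[groups], sep = "."))
    }
    values <- x$values
  } else {
    values <- as.matrix(x)
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("`groups` must give one label per sample")
  tab <- table(groups)
  if (length(tab) < 2L) stop("degenerate design: need at least 2 groups")
  if (any(tab == 0L)) stop("grouping error: empty group")

  n <- ncol(values)
  centered <- values - rowMeans(values)        # center each gene
  labels <- names(tab)
  sizes <- as.integer(tab)
  # group-mean matrix, groups x genes
  M <- t(vapply(labels, function(g)
    rowMeans(centered[, groups == g, drop = FALSE]), numeric(nrow(values))))
  W <- M * sqrt(sizes / n)
  sv <- svd(W)
  max_axes <- min(length(labels) - 1L, nrow(values))
  d <- sv$d[seq_len(max_axes)]
  tol <- max(sv$d) * 1e-12
  nonnull <- sum(d > tol)
  if (is.null(n_axes)) n_axes <- nonnull
  if (n_axes > max_axes)
    stop("n_axes exceeds min(groups - 1, genes) = ", max_axes)
  keep <- seq_len(n_axes)

  V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading positive per axis
  for (k in keep) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- rownames(values)
  colnames(V) <- paste0("axis", keep)

  group_scores <- M %*% V
  rownames(group_scores) <- labels
  sample_scores <- t(centered) %*% V
  rownames(sample_scores) <- colnames(values)
  vf <- if (nonnull > 0) d[seq_len(nonnull)]^2 / sum(d[seq_len(nonnull)]^2) else numeric()

  structure(list(group_scores = group_scores, sample_scores = sample_scores,
                 gene_loadings = V, variance_fraction = vf,
                 axes = n_axes, group_labels = labels,
                 group_sizes = stats::setNames(sizes, labels)),
            class = "bga")
}

#' @export
print.bga <- function(x, ...) {
  cat(sprintf("bga: %d groups, %d axes retained\n", length(x$group_labels), x$axes))
  if (length(x$variance_fraction))
    cat("  between-group variance fraction:",
        paste(sprintf("%.3f", utils::head(x$variance_fraction, x$axes)), collapse = " "), "\n")
  invisible(x)
}

#' Stress-to-control centroid distances on the leading BGA axes
#'
#' Euclidean distance between each stress group's centroid and its matched
#' control centroid on the first `k` axes, sorted descending: the larger the
#' distance, the stronger the transcriptome reprogramming under that
#' stress. By default every non-control group is paired with the single
#' group labelled `control_label`; an explicit `pairing` (named vector
#' stress-group -> control-group) covers composite groupings such as
#' condition x tissue.
#'
#' @param result a [between_group_analysis()] result.
#' @param k number of leading axes to use (default 2).
#' @param control_label label of the control group.
#' @param pairing optional named character vector mapping each stress group
#'   to its control group.
#' @return data.frame with columns `group`, `control`, `distance`, sorted
#'   by decreasing distance.
#' @export
group_separation_summary <- function(result, k = 2L, control_label = "control",
                                     pairing = NULL) {
  if (k > ncol(result$group_scores))
    stop("k exceeds the number of retained axes")
  gs <- result$group_scores[, seq_len(k), drop = FALSE]
  labels <- rownames(gs)
  if (is.null(pairing)) {
    stress_groups <- setdiff(labels, control_label)
    if (!control_label %in% labels)
      stop("pairing error: no control group '", control_label, "'")
    pairing <- stats::setNames(rep(control_label, length(stress_groups)), stress_groups)
  }
  missing <- setdiff(c(names(pairing), unname(pairing)), labels)
  if (length(missing)) stop("pairing error: unknown group '", missing[1L], "'")
  d <- vapply(names(pairing), function(g)
    sqrt(sum((gs[g, ] - gs[pairing[[g]], ])^2)), numeric(1))
  out <- data.frame(group = names(pairing), control = unname(pairing),
                    distance = unname(d), stringsAsFactors = FALSE)
  out <- out[order(-out$distance, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
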