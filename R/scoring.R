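#' Log2 fold changes for one stress across its time course
#'
#' LFC(g, t) = mean over stress replicates minus mean over matched control
#' replicates of the log2 expression values at time t (a difference of log2
#' means, since values are already on log2 scale).
#'
#' @param exp an [expression_experiment()].
#' @param tissue tissue label.
#' @param stress stress condition label.
#' @return genes x time numeric matrix; column names are the time points.
#' @export
log_fold_changes <- function(exp, tissue, stress) {
  s <- exp$samples
  st <- s$tissue == tissue & s$condition == stress
  ct <- s$tissue == tissue & s$condition == "control"
  if (!any(st)) stop(sprintf("no samples for (tissue=%s, stress=%s)", tissue, stress))
  times <- sort(unique(s$time_h[st]))
  lfc <- matrix(NA_real_, nrow(exp$values), length(times),
                dimnames = list(rownames(exp$values), format(times, trim = TRUE)))
  for (k in seq_along(times)) {
    si <- st & s$time_h == times[k]
    ci <- ct & s$time_h == times[k]
    if (!any(ci))
      stop(sprintf("missing control for (tissue=%s, stress=%s, time_h=%g)",
                   tissue, stress, times[k]))
    lfc[, k] <- rowMeans(exp$values[, si, drop = FALSE]) -
      rowMeans(exp$values[, ci, drop = FALSE])
  }
  lfc
}

#' Per-gene stress score from a log-fold-change matrix
#'
#' The canonical score sums absolute log2 fold changes over the time
#' course, `S(g) = sum_t |LFC(g, t)|`, so up- and down-regulation both
#' raise the score. With `absolute = FALSE` the signed sum `sum_t LFC(g, t)`
#' is returned instead (the literal reading of the score as a sum of signed
#' log ratios, under which opposite responses cancel).
#'
#' @param lfc genes x time matrix from [log_fold_changes()].
#' @param absolute sum `|LFC|` (default) or signed LFC.
#' @return named numeric vector of per-gene scores.
#' @export
stress_score <- function(lfc, absolute = TRUE) {
  if (ncol(lfc) < 1L) stop("need at least one time point")
  if (absolute) rowSums(abs(lfc)) else rowSums(lfc)
}

# dense rank, 1 = largest
.dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))

#' Abiotic stress matrix: score every gene under every stress
#'
#' Assembles one stress-score column per stress condition (sum of absolute
#' log2 fold changes over time, see [stress_score()]), then summarizes each
#' gene by the median score across stresses (`global_score`) and dense-ranks
#' genes by descending global score (rank 1 = most stress-regulated; an even
#' number of stresses gives the midpoint-mean median).
#'
#' @param exp an [expression_experiment()].
#' @param tissue tissue label.
#' @param stresses stress conditions to score; default all present in the
#'   tissue.
#' @param absolute passed to [stress_score()].
#' @return object of class `stress_score_matrix`: list with `scores`
#'   (genes x stresses), `global_score`, `ranks` (dense, descending),
#'   `tissue`.
#' @export
abiotic_stress_matrix <- function(exp, tissue, stresses = NULL, absolute = TRUE) {
  s <- exp$samples
  present <- sort(setdiff(unique(s$condition[s$tissue == tissue]), "control"))
  if (is.null(stresses)) stresses <- present
  if (length(stresses) == 0L)
    stop(sprintf("no stress conditions found in tissue '%s'", tissue))
  miss <- setdiff(stresses, present)
  if (length(miss)) stop("stress not present in tissue: ", paste(miss, collapse = ", "))
  scores <- vapply(stresses, function(st)
    stress_score(log_fold_changes(exp, tissue, st), absolute = absolute),
    numeric(nrow(exp$values)))
  scores <- matrix(scores, nrow = nrow(exp$values),
                   dimnames = list(rownames(exp$values), stresses))
  global <- apply(scores, 1L, stats::median)
  structure(list(scores = scores, global_score = global,
                 ranks = .dense_rank_desc(global), tissue = tissue),
            class = "stress_score_matrix")
}

#' @export
print.stress_score_matrix <- function(x, ...) {
  cat(sprintf("stress_score_matrix [%s]: %d genes x %d stresses\n",
              x$tissue, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Top-N regulated and bottom-N unregulated gene sets
#'
#' Top = the `n` genes of highest global score, bottom = the `n` of lowest;
#' ties are broken lexicographically by gene id so the selection is
#' deterministic. The sets are disjoint whenever `2n <= number of genes`.
#'
#' @param matrix a [abiotic_stress_matrix()] result.
#' @param n set size.
#' @return list with character vectors `top` and `bottom`.
#' @export
select_top_bottom <- function(matrix, n) {
  ids <- names(matrix$global_score)
  if (n > length(ids)) stop("n exceeds the number of genes")
  g <- matrix$global_score
  top <- ids[order(-g, ids)][seq_len(n)]
  bottom <- ids[order(g, ids)][seq_len(n)]
  list(top = top, bottom = bottom)
}

#' Median-expression fold-change ranking (variant ranking)
#'
#' A second published-style ranking: per stress, take the median log2
#' expression over the whole time course for the stress and the matched
#' control arms, form `LFC_med = median(stress) - median(control)` per gene,
#' rank genes per stress by `|LFC_med|` descending (dense ranks), and report
#' a consensus rank = median of the per-stress ranks. Reported alongside the
#' canonical [abiotic_stress_matrix()] ranking rather than instead of it.
#'
#' @inheritParams abiotic_stress_matrix
#' @return list with `lfc_med` (genes x stresses), `ranks` (genes x
#'   stresses, dense per stress), `consensus_rank` (per gene).
#' @export
median_fold_change_ranks <- function(exp, tissue, stresses = NULL) {
  s <- exp$samples
  present <- sort(setdiff(unique(s$condition[s$tissue == tissue]), "control"))
  if (is.null(stresses)) stresses <- present
  if (length(stresses) == 0L)
    stop(sprintf("no stress conditions found in tissue '%s'", tissue))
  ctrl <- s$tissue == tissue & s$condition == "control"
  ctrl_med <- apply(exp$values[, ctrl, drop = FALSE], 1L, stats::median)
  lfc_med <- vapply(stresses, function(st) {
    si <- s$tissue == tissue & s$condition == st
    if (!any(si)) stop("stress not present in tissue: ", st)
    apply(exp$values[, si, drop = FALSE], 1L, stats::median) - ctrl_med
  }, numeric(nrow(exp$values)))
  lfc_med <- matrix(lfc_med, nrow = nrow(exp$values),
                    dimnames = list(rownames(exp$values), stresses))
  ranks <- apply(abs(lfc_med), 2L, .dense_rank_desc)
  dimnames(ranks) <- dimnames(lfc_med)
  consensus <- apply(ranks, 1L, stats::median)
  list(lfc_med = lfc_med, ranks = ranks, consensus_rank = consensus)
}
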