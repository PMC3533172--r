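#' Expression experiment container
#'
#' Bundles a log2-scale expression matrix (genes x samples) with per-sample
#' metadata. Expression values are assumed to be normalized and on log2
#' scale, so a fold change between two sample groups is a *difference* of
#' values, never a ratio. Control samples carry the reserved condition label
#' `"control"`; every (tissue, stress, time) group must have a matched
#' control group at the same tissue and time.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row
#'   names are taken as gene ids if `gene_ids` is missing.
#' @param samples data.frame with columns `sample_id`, `tissue`,
#'   `condition`, `time_h`, `replicate`; one row per column of `values`,
#'   in the same order (or any order — rows are matched by `sample_id`
#'   against `colnames(values)` when both are present).
#' @param gene_ids character vector of unique gene identifiers.
#'
#' @return An object of class `ExpressionExperiment`: a list with elements
#'   `values` (matrix with gene ids as rownames, sample ids as colnames)
#'   and `samples` (the metadata data.frame, ordered as the columns).
#' @export
expression_experiment <- function(values, samples, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) stop("gene_ids are required (or set rownames on `values`)")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("expression values must all be finite numbers")

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "condition", "time_h", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id: ", samples$sample_id[duplicated(samples$sample_id)][1L])
  if (!is.null(colnames(values))) {
    absent <- setdiff(colnames(values), samples$sample_id)
    if (length(absent))
      stop("sample missing from metadata: ", paste(absent, collapse = ", "))
    if (nrow(samples) != ncol(values))
      stop("metadata has ", nrow(samples), " rows but the matrix has ",
           ncol(values), " columns")
    samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  } else {
    if (nrow(samples) != ncol(values))
      stop("metadata has ", nrow(samples), " rows but the matrix has ",
           ncol(values), " columns")
    colnames(values) <- samples$sample_id
  }
  if (!is.numeric(samples$time_h) || any(samples$time_h <= 0))
    stop("time_h must be positive hours")

  rownames(values) <- gene_ids
  exp <- structure(list(values = values, samples = samples),
                   class = "ExpressionExperiment")
  .check_matched_controls(exp)
  exp
}

.check_matched_controls <- function(exp) {
  s <- exp$samples
  stress <- s[s$condition != "control", , drop = FALSE]
  ctrl <- s[s$condition == "control", , drop = FALSE]
  if (nrow(stress) == 0L) return(invisible(TRUE))
  key <- function(d) paste(d$tissue, d$time_h)
  bad <- !(key(stress) %in% key(ctrl))
  if (any(bad)) {
    b <- stress[which(bad)[1L], ]
    stop(sprintf("no matched control for (tissue=%s, condition=%s, time_h=%g)",
                 b$tissue, b$condition, b$time_h))
  }
  invisible(TRUE)
}

#' @export
print.ExpressionExperiment <- function(x, ...) {
  s <- x$samples
  cat(sprintf("ExpressionExperiment: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  tissues: %s\n", paste(sort(unique(s$tissue)), collapse = ", ")))
  cat(sprintf("  conditions: %s\n", paste(sort(unique(s$condition)), collapse = ", ")))
  cat(sprintf("  time points (h): %s\n", paste(sort(unique(s$time_h)), collapse = ", ")))
  invisible(x)
}

#' Genes, samples, stresses and tissues of an experiment
#' @param exp an `ExpressionExperiment`.
#' @return character vector of identifiers / labels.
#' @export
genes <- function(exp) rownames(exp$values)

#' @rdname genes
#' @export
stresses <- function(exp) sort(setdiff(unique(exp$samples$condition), "control"))

#' @rdname genes
#' @export
tissues <- function(exp) sort(unique(exp$samples$tissue))

#' Subset an experiment by tissue and/or condition
#'
#' @param exp an `ExpressionExperiment`.
#' @param tissue,condition optional label(s) to keep.
#' @param validate if `FALSE`, skip the matched-control invariant (used for
#'   stress-only working subsets).
#' @return a list with `values` (matrix subset) and `samples`.
#' @export
subset_samples <- function(exp, tissue = NULL, condition = NULL, validate = FALSE) {
  keep <- rep(TRUE, nrow(exp$samples))
  if (!is.null(tissue)) keep <- keep & exp$samples$tissue %in% tissue
  if (!is.null(condition)) keep <- keep & exp$samples$condition %in% condition
  out <- list(values = exp$values[, keep, drop = FALSE],
              samples = exp$samples[keep, , drop = FALSE])
  rownames(out$samples) <- NULL
  if (validate) expression_experiment(out$values, out$samples) else out
}

#' Read an expression experiment from matrix + metadata TSV files
#'
#' The matrix file is tab-separated with a header whose first cell is
#' `gene_id` and whose remaining cells are sample ids; the metadata file has
#' one row per sample with columns `sample_id`, `tissue`, `condition`,
#' `time_h`, `replicate`.
#'
#' @param matrix_path path to the expression TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @return an [expression_experiment()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix must have a gene_id column and >= 1 sample")
  gene_ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 gene_ids[bad[["row"]]], colnames(vals)[bad[["col"]]]))
  }
  rownames(num) <- gene_ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_experiment(num, meta)
}

#' Write an expression experiment to matrix + metadata TSV files
#'
#' @param exp an `ExpressionExperiment`.
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, the experiment.
#' @export
write_expression <- function(exp, matrix_path, metadata_path) {
  df <- data.frame(gene_id = rownames(exp$values),
                   format(exp$values, digits = 12, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(exp$samples, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(exp)
}
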