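#' Infer a network from expression values by a named method
#'
#' Dispatch point shared by [run_pipeline()] and interactive use. MI-based
#' methods (`mrnet`, `clr`, `aracne`, `c3net`, `relnet`) first build a
#' mutual-information matrix; `corr` and `pcor` work on the values
#' directly.
#'
#' For `mrnet` and `aracne` the MI matrix is significance-filtered first:
#' MI values at or below the `(1 - mi_alpha)` quantile of a permutation
#' null (see [permutation_null()]) are zeroed before inference. Discrete
#' empirical MI has a positive bias that grows with the bin count, so on
#' moderate sample sizes *every* pair shows positive MI; without the filter
#' the greedy retention rule (keep any positive score) produces a dense
#' halo of near-zero-weight edges around the real structure, which drowns
#' degree-based downstream summaries. The same idea is the first step of
#' C3NET and of the original ARACNE formulation. Set `mi_alpha = NULL` to
#' run on the raw MI matrix.
#'
#' @param values genes x samples matrix.
#' @param method one of `"mrnet"`, `"clr"`, `"aracne"`, `"c3net"`,
#'   `"relnet"`, `"corr"`, `"pcor"`.
#' @param n_bins,disc_method,estimator MI settings (see [build_mim()]).
#' @param alpha C3NET significance level.
#' @param mi_alpha significance level of the MI permutation-null filter
#'   applied before `mrnet` / `aracne` (`NULL` disables it).
#' @param n_null_pairs permutation pairs for the permutation nulls.
#' @param eps ARACNE tolerance.
#' @param threshold relevance / correlation threshold.
#' @param corr_method correlation flavor for `"corr"`.
#' @param high_threshold,low_threshold partial-correlation thresholds.
#' @param seed seed for the permutation null.
#' @return a `gene_network`.
#' @export
infer_network <- function(values, method,
                          n_bins = NULL, disc_method = "equal_frequency",
                          estimator = "empirical",
                          alpha = 0.05, mi_alpha = 0.05,
                          n_null_pairs = 1000L, eps = 0,
                          threshold = 0.5, corr_method = "pearson",
                          high_threshold = 0.5, low_threshold = 0.2,
                          seed = 1L) {
  supported <- c("mrnet", "clr", "aracne", "c3net", "relnet", "corr", "pcor")
  if (!method %in% supported)
    stop("unknown inference method '", method, "'; supported: ",
         paste(supported, collapse = ", "))
  if (method %in% c("corr", "pcor")) {
    return(switch(method,
      corr = correlation_network(values, method = corr_method, threshold = threshold),
      pcor = partial_correlation_filter(values, high_threshold, low_threshold)))
  }
  mim <- build_mim(values, n_bins = n_bins, disc_method = disc_method,
                   estimator = estimator)
  if (method %in% c("mrnet", "aracne") && !is.null(mi_alpha)) {
    null_mis <- permutation_null(values, n_pairs = n_null_pairs,
                                 n_bins = n_bins, disc_method = disc_method,
                                 estimator = estimator, seed = seed)
    crit <- stats::quantile(null_mis, probs = 1 - mi_alpha, type = 1, names = FALSE)
    mim$mim[mim$mim <= crit] <- 0
  }
  switch(method,
    mrnet = mrnet(mim),
    clr = clr(mim),
    aracne = aracne(mim, eps = eps),
    relnet = relevance_network(mim, threshold = threshold),
    c3net = c3net(mim,
                  permutation_null(values, n_pairs = n_null_pairs,
                                   n_bins = n_bins, disc_method = disc_method,
                                   estimator = estimator, seed = seed),
                  alpha = alpha))
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML mirrors the `config` argument of [run_pipeline()]: either a
#' `simulation:` block (fields of [simulation_config()]) or `matrix_path:`
#' plus `metadata_path:`, with optional `tissues`, `top_n`, `method`,
#' `method_args`, `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return a config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full scoring / ordination / inference pipeline
#'
#' Per tissue: abiotic stress matrix -> top-N / bottom-N selection -> BGA
#' on all tissue samples grouped by condition -> network inference over the
#' top-N gene set -> hub list. All artifacts are written under
#' `config$out_dir` and summarized in a manifest (parameter echo, seed,
#' output checksums). Identical config and seed give identical artifacts
#' and checksums.
#'
#' @param config list with elements: `simulation` (arguments of
#'   [simulation_config()]) *or* `matrix_path` + `metadata_path`;
#'   optional `tissues` (default: all in the data), `top_n` (default 100),
#'   `method` (default `"mrnet"`), `method_args` (list passed to
#'   [infer_network()]), `seed` (default 1), `out_dir` (required).
#' @return the manifest, invisibly also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  top_n <- if (is.null(config$top_n)) 100L else as.integer(config$top_n)
  if (top_n < 2L) stop("top_n must be >= 2")
  method <- if (is.null(config$method)) "mrnet" else config$method
  supported <- c("mrnet", "clr", "aracne", "c3net", "relnet", "corr", "pcor")
  if (!method %in% supported)
    stop("unknown inference method '", method, "'; supported: ",
         paste(supported, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$simulation)) {
      sim_cfg <- do.call(simulation_config,
                         c(config$simulation[setdiff(names(config$simulation), "seed")],
                           list(seed = seed)))
      truth <- generate_ground_truth(sim_cfg)
      sim <- simulate_experiment(sim_cfg, truth)
      exp <- sim$experiment
    } else {
      if (is.null(config$matrix_path) || is.null(config$metadata_path))
        stop("config needs either `simulation` or matrix_path + metadata_path")
      exp <- read_expression(config$matrix_path, config$metadata_path)
      truth <- NULL; sim <- NULL
    }
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tiss <- if (is.null(config$tissues)) tissues(exp) else config$tissues
    outputs <- list()

    for (ti in tiss) {
      td <- file.path(config$out_dir, ti)
      dir.create(td, recursive = TRUE, showWarnings = FALSE)

      stage <- paste0("score[", ti, "]")
      asm <- abiotic_stress_matrix(exp, ti)
      sel <- select_top_bottom(asm, min(top_n, nrow(asm$scores)))
      sc <- data.frame(gene_id = rownames(asm$scores), asm$scores,
                       global_score = asm$global_score, rank = asm$ranks,
                       check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.table(sc, file.path(td, "scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(sel$top, file.path(td, "top_genes.txt"))
      writeLines(sel$bottom, file.path(td, "bottom_genes.txt"))

      stage <- paste0("bga[", ti, "]")
      sub <- subset_samples(exp, tissue = ti)
      bga <- between_group_analysis(sub$values, sub$samples$condition, n_axes = 2L)
      utils::write.table(
        data.frame(group = rownames(bga$group_scores), bga$group_scores),
        file.path(td, "bga_group_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(axis = seq_along(bga$variance_fraction),
                   variance_fraction = bga$variance_fraction),
        file.path(td, "bga_variance.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

      stage <- paste0("infer[", ti, "]")
      top_values <- sub$values[sel$top, , drop = FALSE]
      net <- do.call(infer_network,
                     c(list(values = top_values, method = method, seed = seed),
                       config$method_args))
      write_network(net, file.path(td, "network.tsv"), "edge_tsv")
      write_network(net, file.path(td, "network.sif"), "sif")

      stage <- paste0("hubs[", ti, "]")
      hubs <- hub_genes(network_backbone(net), k = 5L)
      writeLines(hubs, file.path(td, "hubs.txt"))

      outputs[[ti]] <- list(
        scores = file.path(ti, "scores.tsv"),
        top_genes = file.path(ti, "top_genes.txt"),
        bottom_genes = file.path(ti, "bottom_genes.txt"),
        bga_group_scores = file.path(ti, "bga_group_scores.tsv"),
        bga_variance = file.path(ti, "bga_variance.tsv"),
        network = file.path(ti, "network.tsv"),
        network_sif = file.path(ti, "network.sif"),
        hubs = file.path(ti, "hubs.txt"))
    }
    list(exp = exp, outputs = outputs, tissues = tiss)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  files <- unlist(result$outputs)
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("stressnet")),
    seed = seed, top_n = top_n, method = method,
    method_args = config$method_args,
    tissues = result$tissues,
    simulation = config$simulation,
    files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
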