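#' Simulation configuration for a multi-stress time-course design
#'
#' Encodes the shape of a multi-stress, multi-time-point, two-tissue
#' microarray study with matched controls per time point: several stress
#' series sampled on a common time grid in shoot and root tissue, with a
#' minority of stress-responsive genes driven by designated hub regulators.
#'
#' Defaults follow that design: 9 stress conditions, six time points between
#' 0.5 and 24 h, shoot and root tissue, 2 replicate arrays per
#' condition-time (a typical replication level for this kind of series),
#' responsive genes peaking at |log2 FC| = 2 over noise of sd 0.5 log2
#' units.
#'
#' @param n_genes total number of genes.
#' @param n_hubs number of designated hub regulators.
#' @param targets_per_hub regulated targets per hub (disjoint target sets).
#' @param n_stresses number of stress conditions (each gets a matched
#'   control series per tissue and time point).
#' @param time_points_h strictly increasing sampling times in hours.
#' @param tissues tissue labels.
#' @param n_replicates replicate arrays per condition-time-tissue.
#' @param responsive_fraction fraction of genes acting as stress-responsive
#'   "drivers" (hubs plus free genes); targets of responsive hubs become
#'   responsive through propagation.
#' @param effect_size_log2 peak |log2 fold change| of a responsive driver.
#' @param noise_sd measurement noise sd, log2 units.
#' @param background_corr exchangeable correlation of noise across genes
#'   within one array (0 = independent noise).
#' @param tissue_overlap fraction of one tissue's free drivers re-used in
#'   the other tissue (hubs respond in both tissues).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 100L, n_hubs = 5L, targets_per_hub = 5L,
                              n_stresses = 9L,
                              time_points_h = c(0.5, 1, 3, 6, 12, 24),
                              tissues = c("shoot", "root"),
                              n_replicates = 2L,
                              responsive_fraction = 0.1,
                              effect_size_log2 = 2,
                              noise_sd = 0.5,
                              background_corr = 0,
                              tissue_overlap = 0.1,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_hubs = as.integer(n_hubs),
              targets_per_hub = as.integer(targets_per_hub),
              n_stresses = as.integer(n_stresses),
              time_points_h = as.numeric(time_points_h),
              tissues = as.character(tissues),
              n_replicates = as.integer(n_replicates),
              responsive_fraction = responsive_fraction,
              effect_size_log2 = effect_size_log2,
              noise_sd = noise_sd, background_corr = background_corr,
              tissue_overlap = tissue_overlap, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L || n_stresses < 1L || n_replicates < 1L || length(tissues) < 1L)
      stop("all design counts must be positive")
    if (n_hubs < 0L || targets_per_hub < 0L) stop("n_hubs and targets_per_hub must be >= 0")
    if (responsive_fraction <= 0 || responsive_fraction > 1)
      stop("responsive_fraction must be in (0, 1]")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
    if (background_corr < 0 || background_corr >= 1) stop("background_corr must be in [0, 1)")
    if (is.unsorted(time_points_h, strictly = TRUE) || any(time_points_h <= 0))
      stop("time points must be strictly increasing positive hours")
  })
  structure(cfg, class = "simulation_config")
}

# canonical stress vocabulary; recycled with suffixes past nine conditions
.stress_names <- function(n) {
  base <- c("heat", "wound", "uvb", "genotoxic", "drought",
            "salt", "osmotic", "cold", "oxidative")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("stress", seq_len(n - length(base))))
}

.gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a ground-truth regulatory network
#'
#' Each hub regulates `targets_per_hub` distinct non-hub targets (target
#' sets disjoint across hubs), with sign drawn +/-1 with equal probability
#' and strength uniform on [0.5, 1]. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return object of class `ground_truth`: list with `edges` (data.frame
#'   `regulator`, `target`, `sign`, `strength`), `hub_ids`, `gene_ids`.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_needed <- config$n_hubs * config$targets_per_hub
  if (n_needed > config$n_genes - config$n_hubs)
    stop("infeasible sizes: n_hubs * targets_per_hub must be <= n_genes - n_hubs")
  ids <- .gene_ids(config$n_genes)
  set.seed(config$seed)
  hubs <- if (config$n_hubs > 0L) sort(sample(ids, config$n_hubs)) else character()
  pool <- setdiff(ids, hubs)
  targets <- if (n_needed > 0L) sample(pool, n_needed) else character()
  edges <- data.frame(
    regulator = rep(hubs, each = config$targets_per_hub),
    target = targets,
    sign = if (n_needed > 0L) sample(c(-1, 1), n_needed, replace = TRUE) else numeric(),
    strength = if (n_needed > 0L) stats::runif(n_needed, 0.5, 1) else numeric(),
    stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, hub_ids = hubs, gene_ids = ids),
            class = "ground_truth")
}

# transient pulse response peaking at t_peak with unit peak height
.pulse <- function(t, t_peak) (t / t_peak) * exp(1 - t / t_peak)

#' Simulate a stress/control time-course experiment
#'
#' Control samples are gene baselines (drawn once, N(8, 1) log2 units) plus
#' noise. In each tissue a fixed driver set — all hubs plus free genes up
#' to `responsive_fraction * n_genes` — responds to every stress with a
#' transient pulse `e_g * f(t)`, `f(t) = (t/t_peak) exp(1 - t/t_peak)`;
#' the peak time `t_peak` is drawn from the time grid and the signed
#' amplitude `e_g = +/- effect_size_log2` is redrawn per stress. In each
#' stress sample, every ground-truth target receives `sign * strength`
#' times its regulator's *realized* response — the added profile plus the
#' regulator's stochastic deviation in that sample — plus its own
#' independent noise. Propagating the realized regulator value (as
#' gene-network simulators generally do) makes the regulator an observed
#' parent in the Markov sense: targets of one hub are conditionally
#' independent given the hub, so the embedded edges describe the
#' conditional-dependence structure of the data they generate. At
#' `noise_sd -> 0` the target's stress profile equals `sign * strength`
#' times the regulator's added profile exactly. Free-driver sets of the
#' two tissues overlap by `tissue_overlap`.
#'
#' @param config a [simulation_config()].
#' @param truth a [generate_ground_truth()] result consistent with `config`.
#' @return list with `experiment` (an [expression_experiment()]) and
#'   `labels` (per tissue, a logical genes x stresses matrix marking
#'   responsive genes).
#' @export
simulate_experiment <- function(config, truth = generate_ground_truth(config)) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "ground_truth"))
  ids <- truth$gene_ids
  if (length(ids) != config$n_genes) stop("truth inconsistent with config: gene count")
  stress_names <- .stress_names(config$n_stresses)
  times <- config$time_points_h

  set.seed(config$seed + 1L)
  baseline <- stats::rnorm(config$n_genes, mean = 8, sd = 1)
  names(baseline) <- ids

  # per-tissue driver sets: all hubs + free genes up to the responsive fraction
  n_drivers <- max(config$n_hubs, round(config$responsive_fraction * config$n_genes))
  free_pool <- setdiff(ids, c(truth$hub_ids, truth$edges$target))
  n_free <- min(n_drivers - config$n_hubs, length(free_pool))
  drivers <- list()
  prev_free <- NULL
  for (ti in config$tissues) {
    if (is.null(prev_free) || n_free == 0L) {
      fr <- if (n_free > 0L) sample(free_pool, n_free) else character()
    } else {
      n_shared <- min(round(config$tissue_overlap * n_free), length(prev_free))
      shared <- if (n_shared > 0L) sample(prev_free, n_shared) else character()
      rest <- setdiff(free_pool, prev_free)
      fr <- c(shared, sample(rest, min(n_free - n_shared, length(rest))))
    }
    drivers[[ti]] <- c(truth$hub_ids, fr)
    prev_free <- fr
  }

  by_reg <- split(truth$edges, truth$edges$regulator)

  meta <- list(); cols <- list(); labels <- list()
  for (ti in config$tissues) {
    driver_set <- drivers[[ti]]
    # responsive = drivers plus targets of responsive hubs (hubs always drive)
    resp_targets <- truth$edges$target[truth$edges$regulator %in% driver_set]
    responsive <- union(driver_set, resp_targets)
    lab <- matrix(FALSE, config$n_genes, config$n_stresses,
                  dimnames = list(ids, stress_names))
    lab[responsive, ] <- TRUE
    labels[[ti]] <- lab

    te <- truth$edges[truth$edges$regulator %in% driver_set, , drop = FALSE]
    for (cond in c(stress_names, "control")) {
      added <- matrix(0, config$n_genes, length(times), dimnames = list(ids, NULL))
      if (cond != "control" && config$effect_size_log2 > 0) {
        e <- sample(c(-1, 1), length(driver_set), replace = TRUE) * config$effect_size_log2
        tp <- sample(times, length(driver_set), replace = TRUE)
        for (d in seq_along(driver_set))
          added[driver_set[d], ] <- e[d] * .pulse(times, tp[d])
      }
      for (k in seq_along(times)) {
        for (r in seq_len(config$n_replicates)) {
          eps <- stats::rnorm(config$n_genes, 0, 1)
          if (config$background_corr > 0) {
            shared <- stats::rnorm(1)
            eps <- sqrt(config$background_corr) * shared +
              sqrt(1 - config$background_corr) * eps
          }
          val <- baseline + added[, k] + config$noise_sd * eps
          if (cond != "control" && nrow(te)) {
            # realized regulator response = added profile + its noise deviation
            reg_dev <- added[te$regulator, k] +
              config$noise_sd * eps[match(te$regulator, ids)]
            val[te$target] <- val[te$target] + te$sign * te$strength * reg_dev
          }
          sid <- sprintf("%s_%s_t%g_r%d", ti, cond, times[k], r)
          cols[[sid]] <- val
          meta[[sid]] <- data.frame(sample_id = sid, tissue = ti, condition = cond,
                                    time_h = times[k], replicate = r,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- ids
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  list(experiment = expression_experiment(values, samples), labels = labels)
}

#' Three-gene Gaussian Markov chain fixture
#'
#' Generates `g1 -> g2 -> g3` with `X ~ N(0,1)`,
#' `Y = rho X + sqrt(1-rho^2) e`, `Z = rho Y + sqrt(1-rho^2) e'`, so
#' `cor(g1, g3) = rho^2` while the partial correlation of (g1, g3) given g2
#' is 0: the canonical indirect-edge scenario for network pruning.
#'
#' @param n_samples number of samples (>= 10).
#' @param rho chain correlation, |rho| < 1.
#' @param seed integer seed.
#' @return 3 x n matrix with rows `g1`, `g2`, `g3`.
#' @export
make_gaussian_chain <- function(n_samples, rho, seed = 1L) {
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  set.seed(seed)
  x <- stats::rnorm(n_samples)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n_samples)
  z <- rho * y + sqrt(1 - rho^2) * stats::rnorm(n_samples)
  m <- rbind(g1 = x, g2 = y, g3 = z)
  m
}
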