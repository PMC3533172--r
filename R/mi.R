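#' Discretize an expression matrix gene by gene
#'
#' Prerequisite of the discrete entropy/MI estimators. `equal_width` splits
#' each gene's observed range into `n_bins` equal intervals (last interval
#' right-closed); `equal_frequency` cuts at quantiles, resolving ties by
#' stable sample order so every bin holds (as nearly as possible) the same
#' number of samples. A constant gene falls entirely into bin 0.
#'
#' @param values genes x samples numeric matrix.
#' @param n_bins number of bins (>= 1); default `ceiling(sqrt(n_samples))`.
#' @param method `"equal_frequency"` (default) or `"equal_width"`.
#' @return object of class `discretized_matrix`: list with `bins`
#'   (genes x samples integer matrix, indices in `[0, n_bins)`), `n_bins`,
#'   `method`.
#' @export
discretize <- function(values, n_bins = NULL,
                       method = c("equal_frequency", "equal_width")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  n <- ncol(values)
  if (n < 2L) stop("need at least 2 samples")
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  if (n_bins < 1L) stop("n_bins must be >= 1")
  bins <- matrix(0L, nrow(values), n, dimnames = dimnames(values))
  for (i in seq_len(nrow(values))) {
    x <- values[i, ]
    rng <- range(x)
    if (rng[1L] == rng[2L] || n_bins == 1L) next   # constant gene -> bin 0
    if (method == "equal_width") {
      w <- (rng[2L] - rng[1L]) / n_bins
      bins[i, ] <- pmin(as.integer(floor((x - rng[1L]) / w)), n_bins - 1L)
    } else {
      r <- rank(x, ties.method = "first")
      bins[i, ] <- as.integer(floor((r - 1) * n_bins / n))
    }
  }
  structure(list(bins = bins, n_bins = as.integer(n_bins), method = method),
            class = "discretized_matrix")
}

#' Discrete entropy from bin counts
#'
#' Estimators, all in bits:
#' * `empirical`: plug-in `H = -sum p log2 p`, with `0 log 0 = 0`;
#' * `miller_madow`: empirical plus the bias correction
#'   `(m - 1) / (2 n ln 2)` where `m` is the number of occupied bins and
#'   `n` the total count;
#' * `shrink`: James--Stein shrinkage of the frequencies toward the uniform
#'   distribution with analytic shrinkage intensity
#'   `lambda = (1 - sum p^2) / ((n - 1) sum (1/m - p)^2)` (clamped to
#'   [0, 1]; `m` = number of bins), then plug-in entropy of the shrunken
#'   frequencies.
#'
#' @param counts nonnegative bin-count vector with positive total.
#' @param estimator one of `"empirical"`, `"miller_madow"`, `"shrink"`.
#' @return entropy estimate in bits.
#' @export
entropy <- function(counts, estimator = c("empirical", "miller_madow", "shrink")) {
  estimator <- match.arg(estimator)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop("counts must have a positive total")
  p <- counts / n
  plug_in <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  switch(estimator,
    empirical = plug_in(p),
    miller_madow = plug_in(p) + (sum(counts > 0) - 1) / (2 * n * log(2)),
    shrink = {
      m <- length(counts)
      u <- 1 / m
      denom <- (n - 1) * sum((u - p)^2)
      lambda <- if (denom <= 0) 1 else min(1, max(0, (1 - sum(p^2)) / denom))
      plug_in(lambda * u + (1 - lambda) * p)
    })
}

#' Mutual information between two discretized genes
#'
#' `MI = H(X) + H(Y) - H(X, Y)` under the chosen entropy estimator, in
#' bits, clamped at 0 (corrected estimators can go slightly negative).
#'
#' @param x_bins,y_bins integer bin indices per sample (same length),
#'   indices starting at 0.
#' @param estimator passed to [entropy()].
#' @param nx,ny number of bin levels; default `max(bins) + 1`. Only the
#'   `shrink` estimator is sensitive to empty trailing levels.
#' @return MI estimate in bits (>= 0).
#' @export
mutual_information <- function(x_bins, y_bins,
                               estimator = c("empirical", "miller_madow", "shrink"),
                               nx = max(x_bins) + 1L, ny = max(y_bins) + 1L) {
  estimator <- match.arg(estimator)
  if (length(x_bins) != length(y_bins)) stop("x_bins and y_bins must have equal length")
  if (length(x_bins) < 2L) stop("need at least 2 samples")
  cx <- tabulate(x_bins + 1L, nbins = nx)
  cy <- tabulate(y_bins + 1L, nbins = ny)
  cxy <- tabulate(x_bins * ny + y_bins + 1L, nbins = nx * ny)
  mi <- entropy(cx, estimator) + entropy(cy, estimator) - entropy(cxy, estimator)
  max(mi, 0)
}

#' Mutual information matrix over all gene pairs
#'
#' Discretizes once and computes pairwise MI for every unordered gene pair;
#' the matrix is symmetric with diagonal fixed at 0 by convention.
#'
#' @param values genes x samples numeric matrix (log2 expression).
#' @param n_bins,disc_method passed to [discretize()]; `n_bins` defaults to
#'   `ceiling(sqrt(n_samples))`.
#' @param estimator passed to [entropy()].
#' @return object of class `mim`: list with `genes`, `mim` (symmetric
#'   matrix, bits), `estimator_tag`, `discretization_tag`, `n_bins`.
#' @export
build_mim <- function(values, n_bins = NULL,
                      disc_method = c("equal_frequency", "equal_width"),
                      estimator = c("empirical", "miller_madow", "shrink")) {
  disc_method <- match.arg(disc_method)
  estimator <- match.arg(estimator)
  values <- as.matrix(values)
  g <- nrow(values)
  if (g < 2L) stop("need at least 2 genes")
  ids <- rownames(values)
  if (is.null(ids)) ids <- .gene_ids(g)
  d <- discretize(values, n_bins = n_bins, method = disc_method)
  nb <- d$n_bins
  m <- matrix(0, g, g, dimnames = list(ids, ids))
  for (i in seq_len(g - 1L)) {
    xi <- d$bins[i, ]
    for (j in seq.int(i + 1L, g)) {
      m[i, j] <- m[j, i] <- mutual_information(xi, d$bins[j, ], estimator,
                                               nx = nb, ny = nb)
    }
  }
  structure(list(genes = ids, mim = m, estimator_tag = estimator,
                 discretization_tag = disc_method, n_bins = nb),
            class = "mim")
}

#' @export
print.mim <- function(x, ...) {
  cat(sprintf("mim: %d genes (%s estimator, %s, %d bins)\n",
              length(x$genes), x$estimator_tag, x$discretization_tag, x$n_bins))
  invisible(x)
}

# accept a mim object or a plain symmetric matrix with rownames
.as_mim_matrix <- function(mim) {
  m <- if (inherits(mim, "mim")) mim$mim else as.matrix(mim)
  if (nrow(m) != ncol(m)) stop("MI matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) stop("MI matrix must be symmetric")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- .gene_ids(nrow(m))
  diag(m) <- 0
  m
}

#' Permutation null distribution of MI
#'
#' Repeatedly picks a random gene pair, permutes one gene's samples (which
#' destroys any dependence while keeping both marginals), and records the
#' MI estimate. The pooled sample approximates the null distribution of the
#' estimator under independence and provides the significance cutoff used
#' by [c3net()].
#'
#' @param values genes x samples matrix.
#' @param n_pairs number of permuted pairs (>= 100).
#' @param n_bins,disc_method,estimator as in [build_mim()].
#' @param seed integer seed; the sample is deterministic given it.
#' @return numeric vector of `n_pairs` null MI values (bits).
#' @export
permutation_null <- function(values, n_pairs = 1000L, n_bins = NULL,
                             disc_method = c("equal_frequency", "equal_width"),
                             estimator = c("empirical", "miller_madow", "shrink"),
                             seed = 1L) {
  disc_method <- match.arg(disc_method)
  estimator <- match.arg(estimator)
  if (n_pairs < 100L) stop("n_pairs must be >= 100")
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least 2 genes")
  d <- discretize(values, n_bins = n_bins, method = disc_method)
  n <- ncol(values)
  set.seed(seed)
  vapply(seq_len(n_pairs), function(k) {
    ij <- sample(nrow(values), 2L)
    mutual_information(d$bins[ij[1L], ], d$bins[ij[2L], sample(n)],
                       estimator, nx = d$n_bins, ny = d$n_bins)
  }, numeric(1))
}
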