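# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use the most literal formulation of
# each definition (explicit loops, fresh recomputation per step) rather
# than the package's vectorized/incremental code paths.

# plug-in entropy of a count vector, bits
oracle_entropy <- function(counts, estimator = "empirical") {
  n <- sum(counts)
  h <- 0
  for (c in counts) if (c > 0) h <- h - (c / n) * log2(c / n)
  if (estimator == "miller_madow") h <- h + (sum(counts > 0) - 1) / (2 * n * log(2))
  h
}

# MI from raw bin vectors via an explicitly assembled joint table
oracle_mi <- function(x, y, estimator = "empirical") {
  xs <- sort(unique(x)); ys <- sort(unique(y))
  J <- matrix(0, length(xs), length(ys))
  for (k in seq_along(x)) {
    i <- match(x[k], xs); j <- match(y[k], ys)
    J[i, j] <- J[i, j] + 1
  }
  mi <- oracle_entropy(rowSums(J), estimator) + oracle_entropy(colSums(J), estimator) -
    oracle_entropy(as.vector(J), estimator)
  max(mi, 0)
}

# straight-line greedy MRMR trace; returns the symmetric weight matrix
oracle_mrnet_weights <- function(m, ids = rownames(m)) {
  g <- nrow(m)
  S <- matrix(-Inf, g, g)
  for (i in seq_len(g)) {
    sel <- integer(0)
    cand <- setdiff(seq_len(g), i)
    while (length(cand)) {
      sc <- numeric(length(cand))
      for (a in seq_along(cand)) {
        j <- cand[a]
        red <- 0
        for (k in sel) red <- red + m[j, k]
        sc[a] <- if (length(sel)) m[i, j] - red / length(sel) else m[i, j]
      }
      best <- max(sc)
      tied <- cand[sc == best]
      j <- tied[order(ids[tied])][1L]
      S[i, j] <- sc[match(j, cand)]
      sel <- c(sel, j)
      cand <- cand[cand != j]
    }
  }
  W <- pmax(S, t(S))
  W[W < 0] <- 0
  diag(W) <- 0
  dimnames(W) <- list(ids, ids)
  W
}

# ARACNE by exhaustive triple enumeration
oracle_aracne_weights <- function(m, eps = 0) {
  g <- nrow(m)
  keep <- m > 0
  for (i in seq_len(g)) for (j in seq_len(g)) for (k in seq_len(g)) {
    if (i < j && k != i && k != j &&
        m[i, j] > 0 && m[i, k] > 0 && m[j, k] > 0 &&
        m[i, j] < min(m[i, k], m[j, k]) - eps)
      keep[i, j] <- keep[j, i] <- FALSE
  }
  w <- m
  w[!keep] <- 0
  diag(w) <- 0
  w
}

# hypergeometric upper tail by summing binomial coefficients
oracle_hyper_tail <- function(k, K, U, n) {
  xs <- seq.int(k, min(n, K))
  xs <- xs[xs >= max(0, n - (U - K))]
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(U - K, n - xs)) / choose(U, n)
}

# random symmetric MI-like matrix with zero diagonal
random_mim <- function(g, ids = sprintf("g%02d", seq_len(g))) {
  m <- matrix(0, g, g, dimnames = list(ids, ids))
  vals <- stats::runif(g * (g - 1) / 2, 0, 1)
  m[upper.tri(m)] <- vals
  m + t(m)
}

# weight matrix of a gene_network, for comparing against oracle matrices
network_weight_matrix <- function(net) {
  w <- matrix(0, length(net$nodes), length(net$nodes),
              dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    w[cbind(net$edges$gene_a, net$edges$gene_b)] <- net$edges$weight
    w[cbind(net$edges$gene_b, net$edges$gene_a)] <- net$edges$weight
  }
  w
}

# small expression experiment fixture: g genes, one stress, matched controls
toy_experiment <- function(values_stress, values_control, tissue = "shoot",
                           stress = "salt", times = seq_len(ncol(values_stress))) {
  g <- nrow(values_stress)
  ids <- rownames(values_stress)
  if (is.null(ids)) ids <- sprintf("AT%dG%05d", seq_len(g), seq_len(g) * 10)
  v <- cbind(values_stress, values_control)
  sm <- data.frame(
    sample_id = c(paste0("s", seq_len(ncol(values_stress))),
                  paste0("c", seq_len(ncol(values_control)))),
    tissue = tissue,
    condition = rep(c(stress, "control"), c(ncol(values_stress), ncol(values_control))),
    time_h = c(times, times),
    replicate = 1L, stringsAsFactors = FALSE)
  colnames(v) <- sm$sample_id
  rownames(v) <- ids
  expression_experiment(v, sm)
}
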