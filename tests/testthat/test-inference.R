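mim3 <- function(ab, bc, ac, ids = c("g1", "g2", "g3")) {
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m["g1", "g2"] <- m["g2", "g1"] <- ab
  m["g2", "g3"] <- m["g3", "g2"] <- bc
  m["g1", "g3"] <- m["g3", "g1"] <- ac
  m
}

test_that("MRNET reproduces the worked greedy trace", {
  net <- mrnet(mim3(0.8, 0.7, 0.3))
  # g2 selects g1 (0.8) then g3 (0.7 - 0.3 = 0.4); g1-g3 never scores positive
  expect_equal(net$edges$gene_a, c("g1", "g2"))
  expect_equal(net$edges$gene_b, c("g2", "g3"))
  expect_equal(net$edges$weight, c(0.8, 0.7))

  expect_equal(n_edges(mrnet(mim3(0, 0, 0))), 0L)
  two <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mrnet(two)$edges$weight, 0.5)
  asym <- mim3(0.8, 0.7, 0.3); asym[1, 2] <- 0.9
  expect_error(mrnet(asym), "symmetric")
})

test_that("MRNET equals the brute-force greedy trace on exhaustive 3-gene grids", {
  grid <- seq(0, 0.9, by = 0.1)
  for (ab in grid) for (bc in grid) for (ac in grid) {
    m <- mim3(ab, bc, ac)
    expect_identical(network_weight_matrix(mrnet(m)), oracle_mrnet_weights(m))
  }
})

test_that("MRNET and ARACNE equal their oracles on random 4-6 gene matrices", {
  set.seed(17)
  for (rep in 1:50) {
    g <- sample(4:6, 1)
    m <- random_mim(g)
    expect_identical(network_weight_matrix(mrnet(m)), oracle_mrnet_weights(m))
    expect_equal(network_weight_matrix(aracne(m)), oracle_aracne_weights(m))
  }
})

test_that("ARACNE prunes the weakest edge of each triangle, keeping ties", {
  net <- aracne(mim3(0.9, 0.8, 0.3))
  expect_equal(nrow(net$edges), 2L)
  expect_false(any(net$edges$gene_a == "g1" & net$edges$gene_b == "g3"))
  # exact ties survive the strict inequality
  expect_equal(n_edges(aracne(mim3(0.5, 0.5, 0.5))), 3L)
  # eps widens the tolerance: 0.3 < 0.8 - 0.6 fails, so the edge survives
  expect_equal(n_edges(aracne(mim3(0.9, 0.8, 0.3), eps = 0.6)), 3L)
  expect_error(aracne(mim3(0.9, 0.8, 0.3), eps = -1), ">= 0")
})

test_that("CLR z-scores rows with the population sigma convention", {
  net <- clr(mim3(0.9, 0.5, 0.1))
  # row g1 = (0.9, 0.1): mu 0.5, sigma 0.4 -> z1(g2) = 1, z1(g3) = 0
  # row g2 = (0.9, 0.5): mu 0.7, sigma 0.2 -> z2(g1) = 1
  # weight(g1, g2) = sqrt(1 + 1)
  w <- network_weight_matrix(net)
  expect_equal(w["g1", "g2"], sqrt(2))
  # all equal off-diagonals: sigma 0 everywhere, no network
  expect_equal(n_edges(clr(mim3(0.4, 0.4, 0.4))), 0L)
  expect_equal(w, t(w))
})

test_that("C3NET keeps only significant row-maximal edges", {
  null <- seq(0, 0.99, by = 0.01)        # 95% quantile ~ 0.95
  m <- mim3(0.9, 0.5, 0.2) * 2           # MIs 1.8, 1.0, 0.4 all above
  net <- c3net(m, null, alpha = 0.999)   # critical value ~ 0
  # g1g2 = 1.8 is max for g1 and g2; g2g3 = 1.0 is max for g3; g1g3 dropped
  expect_equal(paste(net$edges$gene_a, net$edges$gene_b),
               c("g1 g2", "g2 g3"))
  # everything below the critical value: empty network
  expect_equal(n_edges(c3net(mim3(0.2, 0.1, 0.05), null, alpha = 0.05)), 0L)
  expect_error(c3net(m, numeric(), 0.05), "nonempty")
  expect_error(c3net(m, null, 1.5), "alpha")
})

test_that("C3NET structural bound and relevance containment hold on random matrices", {
  set.seed(18)
  for (rep in 1:100) {
    g <- sample(3:8, 1)
    m <- random_mim(g)
    null <- runif(200, 0, 0.5)
    crit <- stats::quantile(null, 0.95, type = 1, names = FALSE)
    net <- c3net(m, null, alpha = 0.05)
    expect_lte(n_edges(net), g)
    rel <- relevance_network(m, crit)
    key <- function(n) paste(n$edges$gene_a, n$edges$gene_b)
    expect_true(all(key(net) %in% key(rel)))
  }
})

test_that("relevance network thresholds strictly", {
  m <- mim3(0.9, 0.5, 0.2)
  expect_equal(n_edges(relevance_network(m, 0)), 3L)       # complete graph
  expect_equal(n_edges(relevance_network(m, 0.9)), 0L)     # >= max: empty
  expect_equal(n_edges(relevance_network(m, 0.5)), 1L)     # strict >
})

test_that("correlation networks capture linear and monotone dependence", {
  set.seed(19)
  x <- rnorm(50)
  v <- rbind(g1 = x, g2 = 2 * x, g3 = x^3, g4 = rep(1, 50))
  expect_warning(net_p <- correlation_network(v, "pearson", 0.99), "constant")
  w <- network_weight_matrix(net_p)
  expect_equal(w["g1", "g2"], 1)
  expect_lt(w["g1", "g3"], 1)        # cubic is not perfectly linear
  suppressWarnings({
    net_s <- correlation_network(v, "spearman", 0.999)
    ws <- network_weight_matrix(net_s)
  })
  expect_equal(ws["g1", "g3"], 1)    # but perfectly monotone
  expect_equal(sum(w["g4", ]), 0)    # constant gene isolated
  expect_error(correlation_network(v[, 1:2], threshold = 0.5), "3 samples")
})

test_that("first-order partial correlation removes the indirect chain edge", {
  # exact arithmetic: r_ij = 0.64 through a mediator with r = 0.8 to both
  pc <- (0.64 - 0.8 * 0.8) / sqrt((1 - 0.64) * (1 - 0.64))
  expect_equal(pc, 0)
  removed <- sapply(1:20, function(s) {
    v <- make_gaussian_chain(2000, 0.8, seed = 500 + s)
    net <- partial_correlation_filter(v, 0.5, 0.2)
    key <- paste(net$edges$gene_a, net$edges$gene_b)
    !("g1 g3" %in% key) && all(c("g1 g2", "g2 g3") %in% key)
  })
  expect_gte(mean(removed), 0.95)
  expect_error(partial_correlation_filter(matrix(rnorm(9), 3), 0.2, 0.5), "low_threshold")
})

test_that("inference outputs are symmetric, self-loop-free and nonnegative", {
  set.seed(20)
  v <- matrix(rnorm(6 * 80), 6, 80, dimnames = list(paste0("g", 1:6), NULL))
  m <- build_mim(v)
  nets <- list(mrnet(m), clr(m), aracne(m), relevance_network(m, 0.01),
               c3net(m, permutation_null(v, 200, seed = 1), 0.2),
               correlation_network(v, "pearson", 0.1),
               partial_correlation_filter(v, 0.2, 0.05))
  for (net in nets) {
    expect_true(all(net$edges$weight >= 0))
    expect_true(all(net$edges$gene_a != net$edges$gene_b))
    expect_true(all(net$edges$gene_a < net$edges$gene_b))
  }
  # MRNET edges all carry positive MI; ARACNE is a sub-network of relnet(0)
  key <- function(n) paste(n$edges$gene_a, n$edges$gene_b)
  rel0 <- relevance_network(m, 0)
  expect_true(all(key(nets[[1]]) %in% key(rel0)))
  expect_true(all(key(nets[[3]]) %in% key(rel0)))
})
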