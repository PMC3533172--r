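star_network <- function(center = "hub", leaves = paste0("L", 1:6), w = 1) {
  gene_network(data.frame(gene_a = center, gene_b = leaves, weight = w),
               method_tag = "test")
}

test_that("hub ranking uses degree, then weighted degree, then gene id", {
  net <- star_network()
  expect_equal(hub_genes(net, 1), "hub")
  expect_equal(hub_genes(net, 3)[1], "hub")

  # equal degree, unequal weighted degree
  e <- data.frame(gene_a = c("a", "a", "a", "b", "b", "b"),
                  gene_b = c("x", "y", "z", "u", "v", "w"),
                  weight = c(0.7, 0.7, 0.7, 0.5, 0.25, 0.25))
  net2 <- gene_network(e)
  expect_equal(hub_genes(net2, 2), c("a", "b"))
  # permutation of the edge list does not change the ranking
  net3 <- gene_network(e[sample(nrow(e)), ])
  expect_equal(hub_genes(net3, 8), hub_genes(net2, 8))

  expect_equal(hub_genes(gene_network(NULL), 3), character())
  expect_error(hub_genes(net, 0), ">= 1")
})

test_that("the nominated-edge backbone keeps each node's strongest edge", {
  e <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                  weight = c(1.0, 0.8, 0.1))
  bb <- network_backbone(gene_network(e))
  # a-b is a's (and b's) best; a-c is c's best; b-c is nobody's best
  expect_equal(paste(bb$edges$gene_a, bb$edges$gene_b), c("a b", "a c"))
  expect_lte(n_edges(bb), n_nodes(bb))
  # backbone of a star is the star itself
  st <- star_network()
  expect_equal(n_edges(network_backbone(st)), 6L)
})

test_that("ego subnetworks are induced neighborhoods", {
  st <- star_network()
  whole <- ego_subnetwork(st, "hub", 1)
  expect_setequal(whole$nodes, st$nodes)
  expect_equal(n_edges(whole), 6L)
  leaf <- ego_subnetwork(st, "L1", 1)
  expect_setequal(leaf$nodes, c("L1", "hub"))
  expect_equal(n_edges(leaf), 1L)
  # radius 2 from a leaf reaches the whole star through the center
  expect_setequal(ego_subnetwork(st, "L1", 2)$nodes, st$nodes)
  iso <- gene_network(NULL, nodes = c("solo", "other"))
  sub <- ego_subnetwork(iso, "solo", 1)
  expect_equal(sub$nodes, "solo")
  expect_equal(n_edges(sub), 0L)
  expect_error(ego_subnetwork(st, "nope", 1), "unknown gene")
})

test_that("gene-set overlap statistics are exact and symmetric", {
  a <- paste0("g", 1:100)
  b <- c(paste0("g", 1:10), paste0("h", 1:90))
  ov <- gene_set_overlap(a, b)
  expect_equal(ov$shared, 10L)
  expect_equal(ov$percent_of_a, 10)
  expect_equal(ov$jaccard, 10 / 190)
  expect_equal(gene_set_overlap(b, a)$jaccard, ov$jaccard)
  expect_equal(gene_set_overlap(a, a)$jaccard, 1)
  expect_equal(gene_set_overlap(a, paste0("z", 1:5))$shared, 0L)
  expect_error(gene_set_overlap(a, character()), "nonempty")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- paste0("g", 1:20)
  ann <- list(T1 = paste0("g", 1:4),          # 4 annotated
              T2 = universe,                  # whole universe
              T3 = paste0("g", 15:20))
  query <- c(paste0("g", 1:3), "g10", "g11")  # 3 of T1's genes
  res <- enrich(query, universe, ann)
  p1 <- res$p_value[res$term_id == "T1"]
  expect_equal(p1, oracle_hyper_tail(3, 4, 20, 5), tolerance = 1e-12)
  # exact value: (C(4,3) C(16,2) + C(4,4) C(16,1)) / C(20,5) = 496/15504
  expect_equal(p1, 496 / 15504, tolerance = 1e-12)
  expect_equal(res$p_value[res$term_id == "T2"], 1)
  # single term: q equals p
  one <- enrich(query, universe, ann["T1"])
  expect_equal(one$q_value, one$p_value)
  expect_error(enrich(c(query, "zz"), universe, ann), "subset")
})

test_that("enrichment p-values match enumeration on every small table and BH is monotone", {
  for (U in c(5, 12, 25)) {
    for (K in 0:U) {
      for (n in seq(1, U, by = 3)) {
        lo <- max(0, n + K - U)
        for (k in lo:min(n, K)) {
          p_imp <- stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
          expect_equal(p_imp, oracle_hyper_tail(k, K, U, n), tolerance = 1e-10)
        }
      }
    }
  }
  set.seed(21)
  p <- runif(50)
  q <- stats::p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("recovery metrics are exact at the identity and boundary cases", {
  tr <- list(edges = data.frame(regulator = c("a", "a"), target = c("b", "c"),
                                stringsAsFactors = FALSE))
  exact <- gene_network(data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                                   weight = c(1, 0.5)))
  m <- recovery_metrics(exact, tr)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$aupr, 1)
  expect_equal(m$random_baseline, 2 / 3)

  empty <- gene_network(NULL, nodes = c("a", "b", "c"))
  expect_equal(recovery_metrics(empty, tr)$recall, 0)
  expect_error(recovery_metrics(exact, list(edges = NULL)), "no edges")
})

test_that("randomly ranked complete graphs score near the random baseline", {
  set.seed(22)
  nodes <- paste0("g", 1:15)
  pairs <- t(combn(nodes, 2))
  tr <- list(edges = data.frame(regulator = sample(nodes, 35, replace = TRUE)))
  tr$edges$target <- sapply(tr$edges$regulator, function(r) sample(setdiff(nodes, r), 1))
  tr$edges <- unique(tr$edges)
  auprs <- replicate(20, {
    net <- gene_network(data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                                   weight = sample(seq_len(nrow(pairs)))))
    recovery_metrics(net, tr)$aupr
  })
  base <- recovery_metrics(gene_network(
    data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], weight = 1)), tr)$random_baseline
  expect_equal(mean(auprs), base, tolerance = 0.5 * base)
})
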