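test_that("log fold changes are differences of replicate means on log2 scale", {
  # 2 genes, one stress at 2 time points, 2 replicates each arm
  v <- rbind(gX = c(3, 3, 5.5, 5.5, 2, 2, 7.5, 7.5),
             gY = c(1, 1, 1,   1,   1, 1, 1,   1))
  sm <- data.frame(sample_id = paste0("s", 1:8),
                   tissue = "shoot",
                   condition = rep(c("salt", "control"), each = 4),
                   time_h = rep(c(1, 1, 3, 3), 2),
                   replicate = rep(1:2, 4), stringsAsFactors = FALSE)
  colnames(v) <- sm$sample_id
  exp <- expression_experiment(v, sm)
  lfc <- log_fold_changes(exp, "shoot", "salt")
  expect_equal(unname(lfc["gX", ]), c(1, -2))     # 3-2 and 5.5-7.5
  expect_equal(unname(lfc["gY", ]), c(0, 0))      # identical arms

  # a stress time with no matched control is a named error
  sm2 <- sm; sm2$time_h[7:8] <- 6
  expect_error(expression_experiment(v, sm2), "time_h=3")
})

test_that("stress score sums absolute fold changes (signed sum behind a flag)", {
  lfc <- rbind(a = c(1, -2, 0, 1, -2, 0), b = rep(0, 6), c = c(0.5, rep(0, 5)))
  s <- stress_score(lfc)
  expect_equal(unname(s), c(6, 0, 0.5))
  expect_equal(unname(stress_score(lfc, absolute = FALSE)), c(-2, 0, 0.5))
  expect_equal(stress_score(lfc[, 1, drop = FALSE])[["c"]], 0.5)
})

test_that("abiotic stress matrix takes the median across stresses and dense ranks", {
  # craft an experiment whose per-stress scores are known exactly:
  # single replicate, single time point per stress
  ids <- c("g1", "g2", "g3")
  sm <- data.frame(sample_id = paste0("s", 1:4), tissue = "shoot",
                   condition = c("cold", "salt", "uvb", "control"),
                   time_h = 1, replicate = 1, stringsAsFactors = FALSE)
  v <- matrix(0, 3, 4, dimnames = list(ids, sm$sample_id))
  v[, 4] <- c(5, 5, 5)                       # shared control at time 1
  v[, 1] <- c(5, 15, 7)                      # cold scores (0, 10, 2)
  v[, 2] <- c(9, 15, 5)                      # salt scores (4, 10, 0)
  v[, 3] <- c(7, 15, 5)                      # uvb  scores (2, 10, 0)
  exp <- expression_experiment(v, sm)
  asm <- abiotic_stress_matrix(exp, "shoot")
  expect_equal(unname(asm$scores["g1", c("cold", "salt", "uvb")]), c(0, 4, 2))
  expect_equal(unname(asm$global_score["g1"]), 2)    # odd-count median
  expect_equal(unname(asm$global_score["g2"]), 10)
  # two-stress median is the midpoint mean
  asm2 <- abiotic_stress_matrix(exp, "shoot", stresses = c("cold", "salt"))
  expect_equal(unname(asm2$global_score["g1"]), 2)   # median of (0, 4)
  # single stress: global equals the stress column
  asm1 <- abiotic_stress_matrix(exp, "shoot", stresses = "uvb")
  expect_equal(asm1$global_score, asm1$scores[, "uvb"])
  # dense ranks, 1 = largest global score
  expect_equal(unname(asm$ranks), c(2, 1, 3))
  expect_error(abiotic_stress_matrix(exp, "root"), "no stress conditions")
})

test_that("top/bottom selection orders by score with lexicographic ties", {
  sc <- structure(list(global_score = c(a5 = 9, a4 = 7, a3 = 5, a2 = 3, a1 = 1)),
                  class = "stress_score_matrix")
  sel <- select_top_bottom(sc, 2)
  expect_equal(sel$top, c("a5", "a4"))
  expect_equal(sel$bottom, c("a1", "a2"))
  expect_equal(length(intersect(sel$top, sel$bottom)), 0L)
  # tie at the boundary: lexicographically smaller id enters
  sc2 <- structure(list(global_score = c(AT2G1 = 5, AT1G1 = 5, AT3G1 = 9)),
                   class = "stress_score_matrix")
  expect_equal(select_top_bottom(sc2, 2)$top, c("AT3G1", "AT1G1"))
  # n = gene count returns everything
  expect_setequal(select_top_bottom(sc, 5)$top, names(sc$global_score))
  expect_error(select_top_bottom(sc, 6), "exceeds")
})

test_that("median fold-change variant ranks genes by |median LFC|", {
  v_st <- rbind(g_hi = rep(5, 6) + 2, g_lo = rep(5, 6) + 0.5, g_fl = rep(5, 6))
  v_ct <- rbind(g_hi = rep(5, 6), g_lo = rep(5, 6), g_fl = rep(5, 6))
  exp <- toy_experiment(v_st, v_ct, times = c(0.5, 1, 3, 6, 12, 24))
  mfr <- median_fold_change_ranks(exp, "shoot")
  expect_equal(unname(mfr$lfc_med[, "salt"]), c(2, 0.5, 0))
  expect_equal(unname(mfr$consensus_rank), c(1, 2, 3))
  # constant gene has zero LFC and the worst rank
  expect_equal(unname(mfr$ranks["g_fl" == rownames(mfr$ranks), "salt"]), 3)
})

test_that("score invariances: label swap, constant shift, scaling monotonicity", {
  set.seed(42)
  lfc <- matrix(rnorm(30), 5, 6)
  expect_equal(stress_score(lfc), stress_score(-lfc))           # arm swap
  expect_equal(stress_score(lfc), stress_score(lfc[, 6:1]))     # time order
  expect_equal(stress_score(2.5 * lfc), 2.5 * stress_score(lfc))

  # adding a constant to both arms of one gene leaves its scores unchanged
  v_st <- matrix(rnorm(12, 8), 2, 6); v_ct <- matrix(rnorm(12, 8), 2, 6)
  e1 <- toy_experiment(v_st, v_ct)
  e2 <- toy_experiment(v_st + c(3, 0), v_ct + c(3, 0))
  expect_equal(abiotic_stress_matrix(e1, "shoot")$scores,
               abiotic_stress_matrix(e2, "shoot")$scores)
})

test_that("responsive genes dominate the top set on simulated data", {
  hits <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 60, n_stresses = 4, tissues = "shoot",
                             effect_size_log2 = 2, noise_sd = 0.5, seed = 100 + s)
    sim <- simulate_experiment(cfg)
    lab <- sim$labels$shoot
    resp <- rownames(lab)[rowSums(lab) > 0]
    asm <- abiotic_stress_matrix(sim$experiment, "shoot")
    mean(resp %in% select_top_bottom(asm, length(resp))$top)
  })
  expect_true(all(hits >= 0.8))
})
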