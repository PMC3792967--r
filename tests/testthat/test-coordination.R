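test_that("Fisher z test reproduces the worked example and identities", {
  ft <- fisher_z_test(0.9, 0, 50, 50)
  expect_equal(ft$z, (atanh(0.9)) / sqrt(2 / 47), tolerance = 1e-10)
  expect_equal(ft$z, 7.137, tolerance = 1e-3)
  expect_equal(signif(ft$p, 1), 1e-12)
  expect_equal(fisher_z_test(0.5, 0.5, 30, 30)$p, 1)
  # symmetric in arm order
  expect_equal(fisher_z_test(0.3, 0.7, 20, 25)$p,
               fisher_z_test(0.7, 0.3, 25, 20)$p)
  expect_warning(ft1 <- fisher_z_test(1, 0, 10, 10), "clipped")
  expect_true(is.finite(ft1$z))
})

test_that("correlation differences are computed per pair with Spearman rho", {
  set.seed(9)
  n <- 30
  x <- rnorm(n)
  arm_a <- rbind(g1 = x, g2 = x + rnorm(n, sd = 0.3), g3 = rnorm(n))
  arm_b <- rbind(g1 = rnorm(n), g2 = rnorm(n), g3 = rnorm(n))
  tab <- correlation_difference_table(arm_a, arm_b)
  expect_equal(nrow(tab), 3L)
  i <- tab$gene_a == "g1" & tab$gene_b == "g2"
  rho_ref <- stats::cor(arm_a["g1", ], arm_a["g2", ], method = "spearman")
  expect_equal(tab$rho_a[i], rho_ref, tolerance = 1e-10)
  expect_lt(tab$p[i], 0.01)
  # identical arms: all differences null
  tab0 <- correlation_difference_table(arm_a, arm_a)
  expect_equal(tab0$p, rep(1, 3))
  expect_error(correlation_difference_table(arm_a[, 1:3], arm_b), "4 samples")
})

test_that("binomial excess summary reproduces expected counts and p-values", {
  expect_equal(dysregulation_test(25, 276)$expected, 14)
  expect_equal(dysregulation_test(886, 17727)$expected, 886)
  expect_equal(dysregulation_test(2899, 57970)$expected, 2899)
  expect_equal(signif(dysregulation_test(25, 276)$p_binom, 2), 5.1e-3)
  # p_binom comes from raw counts via the exact two-sided binomial test
  expect_equal(dysregulation_test(25, 276)$p_binom,
               stats::binom.test(25, 276, 0.05)$p.value)
  s <- dysregulation_summary(c(0.01, 0.2, 0.6, 0.04), alpha = 0.05)
  expect_equal(s$observed, 2L)
  expect_equal(s$n, 4L)
})

test_that("sign test matches exact binomial tails", {
  expect_equal(sign_test_superiority(2:7, 1:6)$p, 0.5^6)
  expect_equal(sign_test_superiority(1:6, 2:7)$p, 1)
  r <- sign_test_superiority(c(2, 3, 4, 1, 1, 1), c(1, 2, 3, 2, 2, 2))
  expect_equal(r$p, 0.65625)
  expect_warning(r2 <- sign_test_superiority(c(1, 2), c(1, 1)), "tie")
  expect_equal(r2$n, 1L)
  expect_error(suppressWarnings(sign_test_superiority(1, 1)),
               "no comparisons")
})

test_that("rank-sum AUC equals brute-force pair counting", {
  set.seed(11)
  for (i in 1:5) {
    pos <- rnorm(sample(5:20, 1), mean = 0.5)
    neg <- rnorm(sample(5:20, 1))
    a <- inparkit:::rank_sum_auc(pos, neg)
    expect_equal(a$auc, mean(outer(pos, neg, ">")), tolerance = 1e-12)
    expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  }
  # perfect separation
  expect_equal(inparkit:::rank_sum_auc(2:4, -(1:3))$auc, 1)
})

test_that("a planted co-expression block is detected by correlation enrichment", {
  cfg <- tiny_null_config(seed = 22, coexpr_blocks = list(P03 = 0.8))
  sim <- simulate_expression(cfg)
  set.seed(3)
  ce <- correlation_enrichment(sim$study, cfg$sets$P03, n_perm = 199)
  expect_gt(ce$mean_abs_rho_set, ce$mean_abs_rho_null)
  expect_gt(ce$auc, 0.9)
  expect_lte(ce$p_perm, 0.01)
  # a random set from the same homogeneous background is unremarkable
  set.seed(4)
  ce0 <- correlation_enrichment(sim$study, sample(cfg$genes[61:100], 12),
                                n_perm = 199)
  expect_lt(abs(ce0$auc - 0.5), 0.2)
  expect_gt(ce0$p_perm, 0.05)
})

test_that("response-vector targets compare set genes against the remainder", {
  cfg <- tiny_null_config(seed = 23)
  sim <- simulate_expression(cfg)
  y <- colMeans(sim$study$exprs[cfg$sets$P02, ])  # driven by P02 genes
  set.seed(5)
  ce <- correlation_enrichment(sim$study, cfg$sets$P02, target = y,
                               n_perm = 199)
  expect_gt(ce$mean_abs_rho_set, ce$mean_abs_rho_null)
  expect_lte(ce$p_perm, 0.05)
})

test_that("planted dysregulated pairs produce a significant excess", {
  cfg <- tiny_config(seed = 24)
  sim <- simulate_expression(cfg)
  members <- unique(unlist(sim$truth$crossing_edges))
  res <- coordination_analysis(sim$study, members, "allergen")
  expect_lt(res$summary$p_binom, 0.05)
  expect_gt(res$summary$observed, res$summary$expected)
  # the diluent contrast carries no planted disruption
  res0 <- coordination_analysis(sim$study, members, "diluent")
  expect_gt(res0$summary$p_binom, 0.01)
})
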