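test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(seed = 11)
  d1 <- simulate_all(cfg)
  d2 <- simulate_all(cfg)
  expect_identical(d1$study$exprs, d2$study$exprs)
  expect_identical(d1$gwas, d2$gwas)
  expect_identical(as.data.frame(d1$graph), as.data.frame(d2$graph))
  expect_identical(d1$protein, d2$protein)
  expect_identical(d1$truth$de_effects, d2$truth$de_effects)
})

test_that("pure-noise generation shows null-scale correlations and no arm effects", {
  cfg <- tiny_null_config(seed = 3)
  sim <- simulate_expression(cfg)
  rk <- t(apply(sim$study$exprs, 1L, rank))
  rho <- stats::cor(t(rk))
  m <- mean(abs(rho[upper.tri(rho)]))
  n <- ncol(sim$study$exprs)
  # E|rho| under the null is sqrt(2 / (pi (n - 1)))
  expect_lt(abs(m - sqrt(2 / (pi * (n - 1)))), 0.03)
  de <- differential_expression(sim$study, "case_allergen-vs-case_diluent")
  expect_lt(mean(de$p < 0.05),
            0.05 + 3 * sqrt(0.05 * 0.95 / nrow(de)))
  expect_lt(max(abs(de$log2_ratio)), 1)
})

test_that("a planted log2 shift of -2 is recovered within 3 SE", {
  cfg <- synth_config(n_genes = 50, n_pathways = 2, pathway_size = 10,
                      n_samples_per_arm = 20,
                      de_effects = c(-2, rep(0, 9)),
                      coexpr_blocks = list(), dysreg_pairs = NULL,
                      ppi = list(n_crossing = 0L), protein = NULL,
                      seed = 5)
  sim <- simulate_expression(cfg)
  de <- differential_expression(sim$study, "case_allergen-vs-case_diluent")
  row <- de[de$gene == "g001", ]
  expect_lt(abs(row$log2_ratio - (-2)), 3 * row$se)
  # analytic SE of a two-group mean difference: sd * sqrt(2/n)
  expect_lt(abs(row$se - cfg$noise_sd * sqrt(2 / 20)), 0.1)
  expect_lt(row$q, 0.05)
})

test_that("GWAS generator handles degenerate and error inputs", {
  cfg0 <- tiny_null_config(seed = 2)
  cfg0$gwas$n_snps <- 0L
  g <- simulate_gwas(cfg0)
  expect_equal(nrow(g), 0L)
  cfg <- tiny_config(seed = 2)
  co <- gene_coordinates(cfg)
  expect_error(simulate_gwas(cfg, co[co$gene != "g001", ]), "g001")
})

test_that("planted GWAS SNPs land inside the designated gene windows", {
  cfg <- tiny_config(seed = 9)
  co <- gene_coordinates(cfg)
  g <- simulate_gwas(cfg, co)
  sc <- map_genes_to_best_snp(g, co, window = cfg$gwas$window)
  planted <- inparkit:::planted_gwas_genes(cfg)
  expect_true(all(planted %in% sc$gene))
})

test_that("interaction generator honours density and planted edges", {
  cfg <- tiny_config(seed = 4, ppi = list(density = 0, n_crossing = 3L))
  gr <- simulate_interactions(cfg)
  expect_equal(nrow(gr$edges), 3L)
  expect_true(all(gr$edges$type == "direct"))
  expect_setequal(gr$edges$node_a, c("g001", "g002", "g003"))

  # Erdos-Renyi count within 4 sd of density * C(n, 2)
  cfg2 <- synth_config(n_genes = 500, n_pathways = 5, pathway_size = 20,
                       de_pathway = NULL, coexpr_blocks = list(),
                       dysreg_pairs = NULL, protein = NULL,
                       ppi = list(density = 0.01, n_crossing = 0L),
                       seed = 9)
  gr2 <- simulate_interactions(cfg2)
  npairs <- choose(500, 2)
  expect_lt(abs(nrow(gr2$edges) - 0.01 * npairs),
            4 * sqrt(npairs * 0.01 * 0.99))

  # planted edges survive an edge-list writer/reader round trip
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write_edge_list(gr, tf)
  expect_identical(as.data.frame(read_edge_list(tf)), as.data.frame(gr))
})

test_that("infeasible correlation targets are repaired or rejected by name", {
  # conflicting triangle is non-PSD but repairable by eigenvalue clipping
  dp <- data.frame(gene_a = c("g001", "g002", "g001"),
                   gene_b = c("g002", "g003", "g003"),
                   delta = c(0.9, 0.9, -0.9), stringsAsFactors = FALSE)
  cfg <- synth_config(n_genes = 20, n_pathways = 2, pathway_size = 5,
                      n_samples_per_arm = 10, de_pathway = NULL,
                      coexpr_blocks = list(), dysreg_pairs = dp,
                      ppi = list(n_crossing = 0L), protein = NULL, seed = 1)
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$study$exprs), c(20L, 40L))

  # delta stacked on a co-expression block exceeds |rho| = 1
  dp2 <- data.frame(gene_a = "g001", gene_b = "g002", delta = 0.5,
                    stringsAsFactors = FALSE)
  cfg2 <- synth_config(n_genes = 20, n_pathways = 2, pathway_size = 5,
                       n_samples_per_arm = 10, de_pathway = NULL,
                       coexpr_blocks = list(P01 = 0.8), dysreg_pairs = dp2,
                       ppi = list(n_crossing = 0L), protein = NULL, seed = 1)
  expect_error(simulate_expression(cfg2), "g001-g002")
})

test_that("ground truth records every planted signal", {
  cfg <- tiny_config(seed = 6)
  truth <- simulate_expression(cfg)$truth
  expect_equal(truth$de_pathway, "P01")
  expect_length(truth$de_effects, 10L)
  expect_equal(nrow(truth$crossing_edges), 4L)
  expect_equal(truth$gwas_genes,
               cfg$sets$P01[seq_len(ceiling(0.75 * 10))])
  expect_true(all(unlist(truth$dysreg_pairs[, 1:2]) %in% cfg$genes))
  expect_equal(truth$seed, 6L)
})
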