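test_that("hypergeometric p matches exact tail enumeration", {
  u <- paste0("g", 1:10)
  r <- hypergeometric_enrichment(paste0("g", 1:4),
                                 list(s = paste0("g", 1:5)), u)
  expect_equal(r$k, 4L)
  expect_equal(r$p_hyper, 5 / 210, tolerance = 1e-12)

  # brute-force enumeration oracle on random instances, N <= 30
  set.seed(31)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    univ <- paste0("g", seq_len(N))
    set <- sample(univ, K)
    sig <- sample(univ, n)
    k <- length(intersect(set, sig))
    p_enum <- sum(vapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j), 0)) / choose(N, n)
    r <- hypergeometric_enrichment(sig, list(s = set), univ)
    expect_equal(r$p_hyper, p_enum, tolerance = 1e-10)
  }
})

test_that("odds ratios behave at the no-association and depletion limits", {
  u <- paste0("g", 1:40)
  # balanced table (10, 10, 10, 10)
  r <- hypergeometric_enrichment(u[1:20], list(s = u[c(1:10, 21:30)]), u)
  expect_equal(r$odds_ratio, 1)
  # zero overlap: corrected OR < 1 and p ~ 1
  r0 <- hypergeometric_enrichment(u[1:10], list(s = u[11:20]), u)
  expect_lt(r0$odds_ratio, 1)
  expect_equal(r0$p_hyper, 1, tolerance = 1e-12)
})

test_that("GSEA running sum reproduces hand-computed scores", {
  s10 <- stats::setNames(10:1, letters[1:10])
  r <- gsea_enrichment(s10, list(top = letters[1:3]), n_perm = 50,
                       weight = 0)
  expect_equal(r$es, 1)
  s4 <- stats::setNames(4:1, c("a", "b", "c", "d"))
  r2 <- gsea_enrichment(s4, list(odd = c("a", "c")), n_perm = 50,
                        weight = 0)
  expect_equal(r2$es, 0.5)
  expect_warning(
    gsea_enrichment(s4, list(none = c("x", "y")), n_perm = 10), "skipped")
})

test_that("reversing the ranking negates the unweighted enrichment score", {
  set.seed(7)
  scores <- stats::setNames(rnorm(40), paste0("g", 1:40))
  set <- sample(names(scores), 8)
  es_f <- gsea_enrichment(scores, list(s = set), n_perm = 10, weight = 0)$es
  es_r <- gsea_enrichment(-scores, list(s = set), n_perm = 10, weight = 0)$es
  expect_equal(es_r, -es_f, tolerance = 1e-10)
})

test_that("weighted enrichment score matches the fgsea implementation", {
  set.seed(8)
  scores <- sort(rnorm(60), decreasing = TRUE)
  names(scores) <- paste0("g", 1:60)
  idx <- sort(sample(60, 10))
  es_ref <- fgsea::calcGseaStat(scores, selectedStats = idx, gseaParam = 1)
  es <- gsea_enrichment(scores, list(s = names(scores)[idx]),
                        n_perm = 10, weight = 1)$es
  expect_equal(es, es_ref, tolerance = 1e-10)
})

test_that("BH q-values reproduce hand step-ups and ignore input order", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bh_qvalues(0.3), 0.3)
  set.seed(5)
  p <- runif(50)
  ord <- sample(50)
  expect_equal(bh_qvalues(p)[ord], bh_qvalues(p[ord]))
})

test_that("consensus filter is an inclusive conjunction", {
  rec <- data.frame(set = c("a", "b", "c"),
                    q_hyper = c(0.01, 0.05, 0.2),
                    q_gsea = c(0.30, 0.05, 0.01))
  expect_equal(consensus_enriched(rec, 0.05)$set, "b")
  expect_equal(nrow(consensus_enriched(rec[0, ], 0.05)), 0L)
})

test_that("Jaccard overlap map keeps only positive-overlap edges", {
  sets <- list(A = c("a", "b"), B = c("b", "c"), C = c("x", "y"),
               D = c("a", "b"))
  g <- jaccard_overlap_map(sets, min_jaccard = 0)
  ed <- igraph::as_data_frame(g)
  expect_equal(nrow(ed), 3L)  # A-B, A-D, B-D; C disjoint from all
  expect_equal(sort(ed$jaccard), c(1 / 3, 1 / 3, 1), tolerance = 1e-12)
  g2 <- jaccard_overlap_map(sets, min_jaccard = 0.5)
  expect_equal(nrow(igraph::as_data_frame(g2)), 1L)
})

test_that("Mantel-Haenszel pooling matches hand computation", {
  t1 <- c(20, 10, 10, 10)  # single-table OR 2
  expect_equal(mh_meta_or(list(t1, t1))$or,
               (20 * 10) / (10 * 10), tolerance = 1e-10)
  # OR 2 and OR 1/2 at equal size pool to exactly 1
  a <- c(20, 10, 10, 10)   # OR 2
  b <- c(10, 20, 10, 10)   # OR 1/2
  fit <- mh_meta_or(list(a, b))
  # hand MH: sum(ai di / ni) / sum(bi ci / ni) = (4 + 2) / (2 + 4) = 1
  expect_equal(fit$or, 1, tolerance = 1e-10)
  expect_true(fit$het_p >= 0 && fit$het_p <= 1)
  expect_equal(fit$heterogeneous, fit$het_p <= 0.2)
  expect_error(mh_meta_or(list(t1)), "two")
  expect_warning(res <- mh_meta_or(list(a, b, c(0, 0, 5, 5))), "margin")
  expect_equal(res$k, 2L)
})

test_that("a planted pathway dominates expression enrichment", {
  sim <- simulate_expression(tiny_config(seed = 13))
  de <- differential_expression(sim$study, "case_allergen-vs-case_diluent")
  set.seed(1)
  rec <- enrich_expression(de, tiny_config(seed = 13)$sets, n_perm = 200)
  expect_equal(rec$set[which.min(rec$q_hyper)], "P01")
  expect_true(rec$consensus[rec$set == "P01"])
})
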