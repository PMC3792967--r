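mk_graph <- function(a, b, type = "direct", nodes = NULL) {
  interaction_graph(data.frame(node_a = a, node_b = b, type = type,
                               evidence = "test",
                               stringsAsFactors = FALSE), nodes = nodes)
}

test_that("network extraction keeps only crossing direct edges", {
  A <- c("a1", "a2"); B <- c("b1", "b2")
  g <- mk_graph("a1", "b1")
  net <- extract_inpar_network(g, A, B)
  expect_setequal(net$members, c("a1", "b1"))
  expect_equal(nrow(net$edges), 1L)

  # the same edge flagged indirect yields an empty network
  g2 <- mk_graph("a1", "b1", type = "indirect")
  expect_length(extract_inpar_network(g2, A, B)$members, 0L)

  # within-pathway edges alone yield an empty network
  g3 <- mk_graph(c("a1", "b1"), c("a2", "b2"))
  expect_length(extract_inpar_network(g3, A, B)$members, 0L)
})

test_that("extraction is symmetric and ignores within-pathway edges", {
  A <- c("a1", "a2", "a3"); B <- c("b1", "b2")
  g <- mk_graph(c("a1", "a2", "a1"), c("b1", "b2", "a2"))
  n1 <- extract_inpar_network(g, A, B)
  n2 <- extract_inpar_network(g, B, A)
  expect_setequal(n1$members, n2$members)
  expect_equal(nrow(n1$edges), nrow(n2$edges))
  # adding another within-pathway edge never changes membership
  g2 <- mk_graph(c("a1", "a2", "a1", "a2"), c("b1", "b2", "a2", "a3"))
  expect_setequal(extract_inpar_network(g2, A, B)$members, n1$members)
  # the a1-a2 edge is reported separately, not as a crossing edge
  expect_equal(nrow(n1$within_edges), 1L)
})

test_that("shared genes between pathways get the overlap label", {
  A <- c("x", "a1"); B <- c("x", "b1")
  g <- mk_graph(c("a1", "a1"), c("x", "b1"))
  net <- extract_inpar_network(g, A, B)
  expect_equal(unname(net$labels["x"]), "both")
  expect_true(all(c("a1", "b1", "x") %in% net$members))
})

test_that("planted crossing edges are recovered exactly from synthetic data", {
  dat <- simulate_all(tiny_config(seed = 8))
  net <- extract_inpar_network(dat$graph, dat$sets$P01, dat$sets$P02)
  truth <- dat$truth$crossing_edges
  expect_setequal(net$members, unique(unlist(truth)))
  expect_equal(nrow(net$edges), nrow(truth))
})

test_that("a planted clique attains the permutation floor", {
  set.seed(42)
  bg <- igraph::sample_gnp(500, 0.005)
  el <- igraph::as_edgelist(bg)
  clique <- inparkit:::all_pairs(paste0("n", 1:6))
  edges <- data.frame(
    node_a = c(paste0("n", el[, 1]), clique[, 1]),
    node_b = c(paste0("n", el[, 2]), clique[, 2]),
    type = "direct", evidence = "test", stringsAsFactors = FALSE)
  g <- interaction_graph(edges, nodes = paste0("n", 1:500))
  set.seed(1)
  ct <- connectivity_enrichment(paste0("n", 1:6), g, n_perm = 999)
  expect_equal(ct$direct_stat, choose(6, 2))
  expect_equal(ct$p_direct, 1 / 1000, tolerance = 1e-12)
  expect_true(all(ct$node_p <= 0.05))
})

test_that("degenerate member sets and absent genes are handled", {
  g <- mk_graph(c("a", "b"), c("b", "c"))
  set.seed(2)
  ct <- connectivity_enrichment("a", g, n_perm = 100)
  expect_equal(ct$direct_stat, 0)
  expect_equal(ct$p_direct, 1)
  expect_error(connectivity_enrichment(c("a", "zz"), g, n_perm = 100), "zz")
})

test_that("permutation p-values are calibrated for random member sets", {
  dat <- simulate_all(tiny_config(seed = 30, ppi = list(density = 0.05,
                                                        n_crossing = 0L)))
  set.seed(5)
  ps <- replicate(15, {
    members <- sample(dat$graph$nodes, 8)
    connectivity_enrichment(members, dat$graph, n_perm = 199)$p_direct
  })
  expect_true(all(ps >= 1 / 200 & ps <= 1))
  expect_gt(mean(ps), 0.2)  # not systematically anti-conservative
})

test_that("drug bipartite view reports degree, consensus and orphans", {
  members <- c("FYN", "LCK", "SRC", "STAT4")
  tab <- data.frame(
    drug = c("dasatinib", "dasatinib", "dasatinib", "other", "other",
             "other2"),
    gene = c("FYN", "LCK", "SRC", "SRC", "ELSEWHERE", "FYN"),
    effect = c("immunosuppressant", "immunosuppressant", "antineoplastic",
               "antineoplastic", "antineoplastic", "immunosuppressant"),
    stringsAsFactors = FALSE)
  bp <- drug_bipartite(members, tab)
  d <- bp$drugs[bp$drugs$drug == "dasatinib", ]
  expect_equal(d$n_targets, 3L)
  expect_equal(d$consensus_effect, "immunosuppressant")
  expect_equal(bp$untargeted, "STAT4")
  expect_false("ELSEWHERE" %in% bp$edges$gene)
  # a 1:1 effect split is ambiguous
  tab2 <- tab[1:2, ]; tab2$effect <- c("x", "y")
  expect_equal(drug_bipartite(members, tab2)$drugs$consensus_effect,
               "ambiguous")
})
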