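#' Run the full integrative pipeline on a synthetic configuration
#'
#' Chains every stage on data from [simulate_all()]: differential
#' expression (case-allergen vs case-diluent), expression-side
#' enrichment (hypergeometric + GSEA consensus), GWAS gene scoring and
#' MAGENTA-style enrichment, pathway co-enrichment with Pareto
#' selection, inter-pathway network extraction with connectivity
#' testing, case/control coordination analysis of the network genes
#' under both challenges, and predictive regression of the protein
#' response on the network gene expression.
#'
#' @param config A [synth_config()].
#' @param gsea_perms,magenta_perms,conn_perms,q2_perms Permutation
#'   counts per stage (`conn_perms = 0` skips the connectivity test).
#' @param alpha Significance bound used for Pareto efficiency and the
#'   per-pair coordination level.
#' @return List of class `inpar_pipeline` with elements `data`, `de`,
#'   `expr_enrich`, `gene_scores`, `gwas_enrich`, `coenrich`, `network`,
#'   `connectivity`, `coordination` (full-network and cross-pathway
#'   strata per challenge), `protein_fit` (univariate Q2 regression)
#'   and `panel_fit` (multivariate Wilks-lambda regression of the
#'   response panel).
#' @export
run_pipeline <- function(config, gsea_perms = 500L, magenta_perms = 1000L,
                         conn_perms = 0L, q2_perms = 200L, alpha = 0.05) {
  stopifnot(inherits(config, "synth_config"))
  dat <- simulate_all(config)
  de <- differential_expression(dat$study, "case_allergen-vs-case_diluent")
  expr_enrich <- enrich_expression(de, dat$sets, n_perm = gsea_perms)
  scores <- map_genes_to_best_snp(dat$gwas, dat$coords,
                                  window = config$gwas$window)
  gwas_enrich <- magenta_enrichment(scores, dat$sets,
                                    n_perm = magenta_perms)
  coen <- co_enrichment(expr_enrich, gwas_enrich, alpha = alpha)

  network <- extract_inpar_network(dat$graph,
                                   dat$sets[[config$ppi$pathway_a]],
                                   dat$sets[[config$ppi$pathway_b]])
  connectivity <- NULL
  if (conn_perms > 0L && length(network$members) > 1L)
    connectivity <- connectivity_enrichment(network$members, dat$graph,
                                            n_perm = conn_perms)

  coordination <- NULL
  if (length(network$members) >= 2L) {
    cross <- inter_pathway_pairs(network)
    coordination <- list(
      allergen = coordination_analysis(dat$study, network$members,
                                       "allergen", alpha = alpha),
      diluent = coordination_analysis(dat$study, network$members,
                                      "diluent", alpha = alpha),
      allergen_cross = coordination_analysis(dat$study, challenge = "allergen",
                                             pairs = cross, alpha = alpha),
      diluent_cross = coordination_analysis(dat$study, challenge = "diluent",
                                            pairs = cross, alpha = alpha))
  }

  protein_fit <- panel_fit <- NULL
  if (!is.null(dat$protein) && length(network$members) >= 2L) {
    X <- t(dat$study$exprs[network$members, , drop = FALSE])
    protein_fit <- crossval_q2_regression(X, dat$protein,
                                          n_perm = q2_perms)
    if (!is.null(dat$panel))
      panel_fit <- multivariate_wilks(X, dat$panel, n_perm = q2_perms)
  }

  structure(list(data = dat, de = de, expr_enrich = expr_enrich,
                 gene_scores = scores, gwas_enrich = gwas_enrich,
                 coenrich = coen, network = network,
                 connectivity = connectivity,
                 coordination = coordination,
                 protein_fit = protein_fit, panel_fit = panel_fit),
            class = "inpar_pipeline")
}

#' @export
print.inpar_pipeline <- function(x, ...) {
  cat("Integrative pathway pipeline\n")
  sel <- x$coenrich$set[x$coenrich$selected]
  cat("  selected pathway:", if (length(sel)) sel else "(none)", "\n")
  cat("  inter-pathway network:", length(x$network$members), "genes\n")
  if (!is.null(x$coordination)) {
    s <- x$coordination$allergen$summary
    cat(sprintf("  coordination (allergen): %d observed vs %d expected, p = %s\n",
                s$observed, s$expected, format(s$p_binom, digits = 2)))
  }
  if (!is.null(x$protein_fit))
    cat(sprintf("  protein response Q2 = %.2f (p = %s)\n",
                x$protein_fit$q2_y, format.pval(x$protein_fit$q2_p)))
  if (!is.null(x$panel_fit))
    cat(sprintf("  response panel out-of-sample 1 - lambda = %.2f\n",
                x$panel_fit$q2_y))
  invisible(x)
}
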