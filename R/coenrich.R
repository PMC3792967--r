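#' Combine p-values under a global null
#'
#' A global null for a conjunction of experiments: all component nulls
#' must be rejected to call the joint finding.  Two forms are provided:
#' assuming independence, `1 - prod(1 - p_k)` (the chance of any false
#' positive); and the conservative Sidak-corrected maximum,
#' `1 - (1 - max(p_k))^K`, which drops the independence assumption.
#'
#' @param p_values Numeric vector of component p-values (length K >= 1).
#' @param method `"sidak_max"` (default) or `"independence"`.
#' @return The combined p-value.
#' @export
combine_global_p <- function(p_values,
                             method = c("sidak_max", "independence")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) stop("empty p-value list")
  stop_if_not_prob(p_values, "p_values")
  switch(method,
         independence = 1 - prod(1 - p_values),
         sidak_max = 1 - (1 - max(p_values))^length(p_values))
}

#' Pareto-efficiency flags in (p_expr, p_gwas) objective space
#'
#' A point is Pareto-efficient (non-dominated, minimisation in both
#' coordinates) when no other point is less than or equal in both
#' coordinates and strictly less in at least one.  Duplicate points do
#' not dominate each other.  With `bound` given, efficiency additionally
#' requires both coordinates at or below the bound.
#'
#' @param p_expr,p_gwas Numeric vectors of equal length, values in
#'   [0, 1].
#' @param bound Optional nominal significance bound applied to both
#'   coordinates.
#' @return Logical vector of efficiency flags.
#' @export
pareto_front <- function(p_expr, p_gwas, bound = NULL) {
  stopifnot(length(p_expr) == length(p_gwas))
  stop_if_not_prob(p_expr, "p_expr")
  stop_if_not_prob(p_gwas, "p_gwas")
  n <- length(p_expr)
  if (n == 0L) return(logical(0))
  # sweep in increasing p_expr; within ties, increasing p_gwas.  A point
  # is dominated iff some strictly better-or-equal predecessor beats it.
  ord <- order(p_expr, p_gwas)
  eff <- logical(n)
  best_gwas <- Inf         # smallest p_gwas among strictly smaller p_expr
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && p_expr[ord[j + 1L]] == p_expr[ord[i]]) j <- j + 1L
    block <- ord[i:j]
    min_block_gwas <- min(p_gwas[block])
    for (b in block) {
      dominated <- p_gwas[b] >= best_gwas ||
        (p_gwas[b] > min_block_gwas)
      eff[b] <- !dominated
    }
    best_gwas <- min(best_gwas, min_block_gwas)
    i <- j + 1L
  }
  if (!is.null(bound)) eff <- eff & p_expr <= bound & p_gwas <= bound
  eff
}

#' Pathway co-enrichment records
#'
#' Joins expression-side and GWAS-side enrichment tables on set name and
#' builds the objective space of the Pareto analysis: the expression
#' coordinate is the maximum of the GSEA and hypergeometric p-values,
#' the GWAS coordinate is the permutation enrichment p.  The global
#' co-enrichment p combines the two under [combine_global_p()], and
#' Pareto-efficiency is assessed within the nominal bound.
#'
#' @param expr_records Expression enrichment table from
#'   [enrich_expression()] (needs set, p_hyper, p_gsea, odds_ratio).
#' @param gwas_records GWAS enrichment table from
#'   [magenta_enrichment()] (needs set, p).
#' @param alpha Nominal significance bound for Pareto efficiency.
#' @param method Global-p form, see [combine_global_p()].
#' @return data.frame of class `coenrichment`: set, p_expr, p_gwas,
#'   p_global, or_expr, pareto, selected; ranked by [prioritize_pathways()].
#' @export
co_enrichment <- function(expr_records, gwas_records, alpha = 0.05,
                          method = c("sidak_max", "independence")) {
  method <- match.arg(method)
  stopifnot(all(c("set", "p_hyper", "p_gsea", "odds_ratio") %in%
                  names(expr_records)),
            all(c("set", "p") %in% names(gwas_records)))
  rec <- merge(expr_records[, c("set", "p_hyper", "p_gsea", "odds_ratio")],
               gwas_records[, c("set", "p")], by = "set")
  names(rec)[names(rec) == "p"] <- "p_gwas"
  rec$p_expr <- pmax(rec$p_hyper, rec$p_gsea)
  rec$p_global <- vapply(seq_len(nrow(rec)), function(i)
    combine_global_p(c(rec$p_expr[i], rec$p_gwas[i]), method = method), 0)
  names(rec)[names(rec) == "odds_ratio"] <- "or_expr"
  rec$pareto <- pareto_front(rec$p_expr, rec$p_gwas, bound = alpha)
  out <- prioritize_pathways(rec)
  class(out) <- c("coenrichment", "data.frame")
  out
}

#' Rank Pareto-efficient pathways for prioritisation
#'
#' Restricts to Pareto-efficient records, sorts by global co-enrichment
#' p ascending with ties broken by expression odds ratio descending, and
#' marks the top record as `selected`.  Dominated records follow,
#' unselected, in the same order.  An empty efficient set yields
#' `attr(, "status") = "no efficient pathway within bound"`.
#'
#' @param records data.frame with p_global, or_expr and pareto columns.
#' @return The reordered records with a `rank` (efficient records only)
#'   and `selected` column.
#' @export
prioritize_pathways <- function(records) {
  stopifnot(all(c("p_global", "or_expr", "pareto") %in% names(records)))
  ord <- order(!records$pareto, records$p_global, -records$or_expr)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- ifelse(out$pareto, cumsum(out$pareto), NA_integer_)
  out$selected <- !is.na(out$rank) & out$rank == 1L
  if (!any(out$pareto)) attr(out, "status") <- "no efficient pathway within bound"
  out
}

#' @export
print.coenrichment <- function(x, ...) {
  cat("Pathway co-enrichment (", nrow(x), " sets, ",
      sum(x$pareto), " Pareto-efficient)\n", sep = "")
  print.data.frame(utils::head(
    x[, c("set", "p_expr", "p_gwas", "p_global", "or_expr", "pareto",
          "selected")], 10L), digits = 3)
  if (!is.null(attr(x, "status"))) cat(attr(x, "status"), "\n")
  invisible(x)
}
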