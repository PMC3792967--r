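#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, delegated to [stats::p.adjust()]; exported so
#' every module shares one definition.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p) {
  stop_if_not_prob(p)
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided upper-tail hypergeometric test of the overlap between a
#' significant-gene list and each gene set, inside a measured-gene
#' universe, plus the 2x2-table odds ratio (Haldane-Anscombe 0.5 added
#' to every cell when any cell is zero).
#'
#' @param significant Character vector of significant genes (intersected
#'   with the universe).
#' @param sets Named list of gene sets.
#' @param universe Character vector of measured genes.
#' @return data.frame: set, k (overlap), K (set size in universe),
#'   n (significant genes), N (universe size), odds_ratio, p_hyper.
#' @export
hypergeometric_enrichment <- function(significant, sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  significant <- intersect(unique(as.character(significant)), universe)
  if (!is.list(sets)) sets <- list(set = sets)
  N <- length(universe)
  n <- length(significant)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, significant))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    cells <- c(k, K - k, n - k, N - K - n + k)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    data.frame(set = nm, k = k, K = K, n = n, N = N, odds_ratio = or,
               p_hyper = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Running-sum enrichment score of one gene set in a ranked list.
# scores: named vector sorted by decreasing score; hit increments are
# |score|^weight normalised over in-set scores, misses retreat 1/(N-K).
gsea_running_score <- function(hit, scores, weight) {
  N <- length(hit)
  K <- sum(hit)
  w <- abs(scores)^weight
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - K)
  cs <- cumsum(inc)
  cs[which.max(abs(cs))]
}

#' GSEA enrichment score with gene-label permutation p-values
#'
#' Classic weighted Kolmogorov-Smirnov-like running sum: walking down
#' the ranked gene list, set members advance the sum by their
#' `|score|^weight` (normalised over in-set scores) and non-members
#' retreat it by `1/(N - K)`; the enrichment score is the signed maximum
#' deviation.  Significance comes from `n_perm` random draws of K gene
#' labels, one-sided in the direction of the observed score, with
#' add-one correction.
#'
#' @param scores Named numeric vector of per-gene ranking scores
#'   (e.g. t statistics); need not be sorted.
#' @param sets Named list of gene sets; sets with no overlap with the
#'   scored genes are skipped with a warning.
#' @param n_perm Number of gene-label permutations.
#' @param weight Weighting exponent (1 classic weighted, 0 unweighted).
#' @return data.frame: set, size (overlap K), es, p_gsea.
#' @export
gsea_enrichment <- function(scores, sets, n_perm = 1000L, weight = 1) {
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  N <- length(scores)
  if (!is.list(sets)) sets <- list(set = sets)
  rows <- lapply(names(sets), function(nm) {
    members <- names(scores) %in% sets[[nm]]
    K <- sum(members)
    if (K == 0L || K == N) {
      warning("set '", nm, "' skipped: overlap with ranked list is ",
              K, call. = FALSE)
      return(NULL)
    }
    es <- gsea_running_score(members, scores, weight)
    null_es <- vapply(seq_len(n_perm), function(b) {
      hit <- logical(N)
      hit[sample.int(N, K)] <- TRUE
      gsea_running_score(hit, scores, weight)
    }, 0)
    # one-sided in the direction of the observed score, against the
    # same-sign side of the null (the standard GSEA convention, which
    # keeps the null p uniform)
    side <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    b <- if (es >= 0) sum(side >= es) else sum(side <= es)
    data.frame(set = nm, size = K, es = es,
               p_gsea = perm_pvalue(b, length(side)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression-side enrichment records (hypergeometric + GSEA consensus)
#'
#' Combines both enrichment routes on differential-expression output:
#' the hypergeometric test on genes passing the significance and effect
#' thresholds, and GSEA on genes ranked by the t statistic.  BH q-values
#' are computed per route across sets and the consensus flag marks sets
#' significant under both at `fdr`.
#'
#' @param de A `de_result` from [differential_expression()].
#' @param sets Named list of gene sets.
#' @param q_cut,lfc_cut Significant-gene thresholds: BH q-value and
#'   absolute log2 ratio.
#' @param fdr Consensus FDR level applied to both q columns.
#' @param n_perm,weight GSEA settings, see [gsea_enrichment()].
#' @return data.frame of enrichment records: set, k, K, n, N,
#'   odds_ratio, p_hyper, es, p_gsea, q_hyper, q_gsea, consensus.
#' @export
enrich_expression <- function(de, sets, q_cut = 0.05, lfc_cut = 1,
                              fdr = 0.05, n_perm = 1000L, weight = 1) {
  stopifnot(all(c("gene", "log2_ratio", "stat", "q") %in% names(de)))
  significant <- de$gene[de$q < q_cut & abs(de$log2_ratio) > lfc_cut]
  hyper <- hypergeometric_enrichment(significant, sets, de$gene)
  scores <- stats::setNames(de$stat, de$gene)
  gsea <- gsea_enrichment(scores, sets, n_perm = n_perm, weight = weight)
  rec <- merge(hyper, gsea[, c("set", "es", "p_gsea")], by = "set",
               all.x = TRUE)
  rec$q_hyper <- bh_qvalues(rec$p_hyper)
  rec$q_gsea <- ifelse(is.na(rec$p_gsea), NA_real_, bh_qvalues(rec$p_gsea))
  rec$consensus <- !is.na(rec$q_gsea) & rec$q_hyper <= fdr & rec$q_gsea <= fdr
  rec[order(rec$p_hyper), , drop = FALSE]
}

#' Consensus-enriched subset
#'
#' Sets simultaneously significant under the hypergeometric test and
#' GSEA after BH correction (inclusive comparisons).
#'
#' @param records data.frame with q_hyper and q_gsea columns.
#' @param fdr FDR level.
#' @return Subset of `records`.
#' @export
consensus_enriched <- function(records, fdr = 0.05) {
  stopifnot(all(c("q_hyper", "q_gsea") %in% names(records)))
  records[!is.na(records$q_gsea) & records$q_hyper <= fdr &
            records$q_gsea <= fdr, , drop = FALSE]
}

#' Jaccard overlap map of a gene-set collection
#'
#' Weighted undirected graph over set names with an edge wherever the
#' Jaccard index |A n B| / |A u B| reaches `min_jaccard`; zero-overlap
#' pairs never form edges.
#'
#' @param sets Named list of gene sets.
#' @param min_jaccard Minimum Jaccard index for an edge.
#' @return An igraph object with edge attribute `jaccard`.
#' @export
jaccard_overlap_map <- function(sets, min_jaccard = 0.25) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  nms <- names(sets)
  edges <- list()
  if (length(sets) >= 2L) {
    idx <- utils::combn(length(sets), 2L)
    for (e in seq_len(ncol(idx))) {
      a <- sets[[idx[1, e]]]; b <- sets[[idx[2, e]]]
      j <- length(intersect(a, b)) / length(union(a, b))
      if (j > 0 && j >= min_jaccard) {
        edges[[length(edges) + 1L]] <-
          data.frame(from = nms[idx[1, e]], to = nms[idx[2, e]], jaccard = j,
                     stringsAsFactors = FALSE)
      }
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), jaccard = numeric(0))
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = nms))
}

#' Mantel-Haenszel meta-analysis of enrichment odds ratios
#'
#' Pools 2x2 enrichment tables across studies with the Mantel-Haenszel
#' fixed-effect estimator (via metafor) and tests heterogeneity with
#' Woolf's test on the per-table log odds ratios (0.5 added to every
#' cell).  Tables are flagged heterogeneous when the Woolf p-value is
#' at or below 0.2.
#'
#' @param tables List of at least two 2x2 tables, each a matrix or a
#'   length-4 vector `(a, b, c, d)` = (significant-in-set,
#'   not-significant-in-set, significant-outside, not-significant-
#'   outside).  Tables with an all-zero margin are excluded with a
#'   warning.
#' @return List: or (pooled), p (two-sided), het_p (Woolf),
#'   heterogeneous flag, k (tables used).
#' @export
mh_meta_or <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("Mantel-Haenszel meta-analysis needs at least two 2x2 tables")
  cells <- t(vapply(tables, function(tb) {
    tb <- as.numeric(tb)
    if (length(tb) != 4L || any(tb < 0) || any(tb != round(tb)))
      stop("each table must hold 4 non-negative integer cells")
    tb
  }, numeric(4)))
  colnames(cells) <- c("a", "b", "c", "d")
  margin_zero <- (cells[, 1] + cells[, 2] == 0) |
    (cells[, 3] + cells[, 4] == 0) |
    (cells[, 1] + cells[, 3] == 0) | (cells[, 2] + cells[, 4] == 0)
  if (any(margin_zero)) {
    warning(sum(margin_zero), " table(s) with an all-zero margin excluded")
    cells <- cells[!margin_zero, , drop = FALSE]
  }
  if (nrow(cells) < 2L)
    stop("fewer than two usable tables after exclusions")
  fit <- metafor::rma.mh(ai = cells[, 1], bi = cells[, 2],
                         ci = cells[, 3], di = cells[, 4],
                         measure = "OR", correct = FALSE)
  # Woolf heterogeneity on continuity-corrected log odds ratios
  cc <- cells + 0.5
  lor <- log(cc[, 1] * cc[, 4] / (cc[, 2] * cc[, 3]))
  w <- 1 / rowSums(1 / cc)
  lbar <- sum(w * lor) / sum(w)
  Q <- sum(w * (lor - lbar)^2)
  het_p <- stats::pchisq(Q, df = nrow(cells) - 1L, lower.tail = FALSE)
  list(or = exp(as.numeric(fit$beta)), p = fit$pval, het_p = het_p,
       heterogeneous = het_p <= 0.2, k = nrow(cells))
}
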