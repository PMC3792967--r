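#' Gene-set correlation enrichment
#'
#' Tests whether a gene set shows larger absolute Spearman correlations
#' than background genes.  For `target = "self"` the in-group values are
#' |rho| over all within-set gene pairs and the null group is |rho| over
#' set-by-remainder pairs; for a response-vector target the in-group is
#' |rho| of each set gene against the response and the null group is
#' |rho| of every remaining gene against the response.  Reported are the
#' two group means, a Welch t-test p, a permutation p (set membership
#' resampled `n_perm` times, one-sided for enrichment, add-one
#' corrected), and the ROC AUC (probability that a random in-group |rho|
#' exceeds a random null |rho|, rank-sum form) with a rank-sum p and a
#' Hanley-McNeil normal-approximation 95% CI.
#'
#' @param study An [expression_study()] or a genes-by-samples matrix.
#' @param set Character vector of set genes (>= 2 for `target = "self"`).
#' @param target `"self"` or a numeric response vector named by (or
#'   aligned with) the study samples.
#' @param n_perm Membership permutations.
#' @param arm Optional arm label restricting the samples used.
#' @return data.frame of class `correlation_enrichment`: target,
#'   n_set, mean_abs_rho_set, mean_abs_rho_null, p_t, p_perm, auc,
#'   auc_p, auc_ci_low, auc_ci_high.
#' @export
correlation_enrichment <- function(study, set, target = "self",
                                   n_perm = 1000L, arm = NULL) {
  exprs <- if (inherits(study, "expression_study")) {
    if (is.null(arm)) study$exprs else study_arm(study, arm)
  } else as.matrix(study)
  if (ncol(exprs) < 3L) stop("need at least 3 samples")
  keep <- apply(exprs, 1L, stats::sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant gene(s) dropped")
    exprs <- exprs[keep, , drop = FALSE]
  }
  genes <- rownames(exprs)
  set <- intersect(unique(set), genes)
  is_self <- identical(target, "self")
  if (is_self && length(set) < 2L)
    stop("self-target enrichment needs a set of >= 2 measured genes")
  if (length(set) < 1L) stop("no set genes measured")

  rk <- t(apply(exprs, 1L, rank))  # Spearman = Pearson on ranks
  in_set <- genes %in% set

  if (is_self) {
    rho <- stats::cor(t(rk))
    in_group_of <- function(sel) abs(rho[sel, sel][upper.tri(rho[sel, sel])])
    null_group_of <- function(sel) abs(as.vector(rho[sel, !sel]))
    target_name <- "self"
  } else {
    y <- align_response(target, colnames(exprs))
    ry <- rank(y)
    rho_y <- as.vector(stats::cor(t(rk), ry))
    names(rho_y) <- genes
    in_group_of <- function(sel) abs(rho_y[sel])
    null_group_of <- function(sel) abs(rho_y[!sel])
    target_name <- attr(target, "label") %||% "response"
  }

  in_group <- in_group_of(in_set)
  null_group <- null_group_of(in_set)
  stat_obs <- mean(in_group) - mean(null_group)
  p_t <- stats::t.test(in_group, null_group)$p.value

  k <- sum(in_set)
  b <- 0L
  for (i in seq_len(n_perm)) {
    sel <- logical(length(genes))
    sel[sample.int(length(genes), k)] <- TRUE
    b <- b + ((mean(in_group_of(sel)) - mean(null_group_of(sel))) >= stat_obs)
  }
  p_perm <- perm_pvalue(b, n_perm)

  roc <- rank_sum_auc(in_group, null_group)
  out <- data.frame(target = target_name, n_set = k,
                    mean_abs_rho_set = mean(in_group),
                    mean_abs_rho_null = mean(null_group),
                    p_t = p_t, p_perm = p_perm,
                    auc = roc$auc, auc_p = roc$p,
                    auc_ci_low = roc$ci[1], auc_ci_high = roc$ci[2],
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_enrichment", "data.frame")
  out
}

align_response <- function(y, samples) {
  if (!is.null(names(y))) {
    missing <- setdiff(samples, names(y))
    if (length(missing)) stop("response lacks sample(s): ",
                              paste(missing, collapse = ", "))
    y <- y[samples]
  } else if (length(y) != length(samples)) {
    stop("unnamed response must have one value per sample")
  }
  as.numeric(y)
}

# AUC by the rank-sum (Mann-Whitney) identity, with the Wilcoxon
# rank-sum p (one-sided, enrichment direction) and a Hanley-McNeil
# normal-approximation 95% CI truncated to [0, 1].
rank_sum_auc <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  p <- suppressWarnings(
    stats::wilcox.test(pos, neg, alternative = "greater", exact = FALSE)
  )$p.value
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))
  list(auc = auc, p = p, ci = ci)
}

#' Per-pair correlation differences between two sample arms
#'
#' For each gene pair, computes the Spearman correlation in each arm and
#' a two-sided p-value for their difference from Fisher's z transform:
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#' Correlations at exactly |rho| = 1 are clipped to 1 - 1e-10 with a
#' warning; pairs whose correlation is undefined (a constant gene) are
#' skipped with a warning.
#'
#' @param exprs_a,exprs_b Genes-by-samples matrices for the two arms
#'   (each >= 4 samples).
#' @param pairs Two-column matrix or data.frame of gene ids; defaults to
#'   all pairs of the common genes.
#' @return data.frame: gene_a, gene_b, rho_a, rho_b, z, p.
#' @export
correlation_difference_table <- function(exprs_a, exprs_b,
                                         pairs = NULL) {
  n1 <- ncol(exprs_a); n2 <- ncol(exprs_b)
  if (n1 < 4L || n2 < 4L)
    stop("Fisher's z needs at least 4 samples per arm")
  genes <- intersect(rownames(exprs_a), rownames(exprs_b))
  if (is.null(pairs)) pairs <- all_pairs(genes)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  missing <- setdiff(unique(as.vector(pairs)), genes)
  if (length(missing))
    stop("pair gene(s) not measured in both arms: ",
         paste(missing, collapse = ", "))

  rk_a <- t(apply(exprs_a[genes, , drop = FALSE], 1L, rank))
  rk_b <- t(apply(exprs_b[genes, , drop = FALSE], 1L, rank))
  rho_pair <- function(rk, pairs) {
    vapply(seq_len(nrow(pairs)), function(i)
      suppressWarnings(stats::cor(rk[pairs[i, 1], ], rk[pairs[i, 2], ])), 0)
  }
  rho_a <- rho_pair(rk_a, pairs)
  rho_b <- rho_pair(rk_b, pairs)
  defined <- !is.na(rho_a) & !is.na(rho_b)
  if (any(!defined)) {
    warning(sum(!defined), " pair(s) with undefined correlation skipped")
    pairs <- pairs[defined, , drop = FALSE]
    rho_a <- rho_a[defined]; rho_b <- rho_b[defined]
  }
  ft <- fisher_z_test(rho_a, rho_b, n1, n2)
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
             rho_a = rho_a, rho_b = rho_b, z = ft$z, p = ft$p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher z test for the difference of two correlations
#'
#' Two-sided test of `rho_a = rho_b` from independent samples of sizes
#' `n_a` and `n_b`:
#' `z = (atanh(rho_a) - atanh(rho_b)) / sqrt(1/(n_a-3) + 1/(n_b-3))`.
#' Correlations at exactly |rho| = 1 are clipped to `1 - 1e-10` with a
#' warning.  Vectorised over the correlations.
#'
#' @param rho_a,rho_b Correlations in [-1, 1].
#' @param n_a,n_b Sample sizes (> 3).
#' @return data.frame with columns z and p.
#' @export
fisher_z_test <- function(rho_a, rho_b, n_a, n_b) {
  stopifnot(n_a > 3, n_b > 3,
            all(abs(rho_a) <= 1), all(abs(rho_b) <= 1))
  clip <- 1 - 1e-10
  if (any(abs(c(rho_a, rho_b)) >= 1))
    warning("correlation(s) at |rho| = 1 clipped for the z transform")
  z <- (atanh(pmin(clip, pmax(-clip, rho_a))) -
          atanh(pmin(clip, pmax(-clip, rho_b)))) /
    sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  data.frame(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Exact binomial test of excess correlation differences
#'
#' Summarises a list of per-pair correlation-difference p-values: the
#' observed count of nominally significant differences (`p < alpha`),
#' the expected count `N * alpha` rounded half-up for reporting, and a
#' two-sided exact binomial p-value (minimum-likelihood two-sided
#' definition, computed from the raw counts, never the rounded
#' expectation).
#'
#' @param pair_pvalues Numeric vector of per-pair p-values (N >= 1).
#' @param alpha Nominal level (success probability of the binomial).
#' @return data.frame: n, observed, expected, p_binom.
#' @export
dysregulation_summary <- function(pair_pvalues, alpha = 0.05) {
  stopifnot(length(pair_pvalues) >= 1L)
  stop_if_not_prob(pair_pvalues, "pair_pvalues")
  dysregulation_test(sum(pair_pvalues < alpha), length(pair_pvalues), alpha)
}

#' @rdname dysregulation_summary
#' @param observed,n Observed significant count and number of pairs
#'   tested, when the per-pair p-values themselves are not at hand.
#' @export
dysregulation_test <- function(observed, n, alpha = 0.05) {
  stopifnot(observed >= 0, observed <= n, n >= 1)
  data.frame(n = as.integer(n), observed = as.integer(observed),
             expected = round_half_up(n * alpha),
             p_binom = stats::binom.test(observed, n, alpha)$p.value)
}

#' One-sided sign test of paired superiority
#'
#' Counts how often `value_a > value_b` over paired comparisons and
#' returns the one-sided binomial tail `P(X >= successes)` at success
#' probability 0.5.  Exact ties are dropped with a warning.
#'
#' @param value_a,value_b Numeric vectors of paired values.
#' @return List: successes, n, p.
#' @export
sign_test_superiority <- function(value_a, value_b) {
  stopifnot(length(value_a) == length(value_b))
  ties <- value_a == value_b
  if (any(ties)) {
    warning(sum(ties), " tie(s) dropped")
    value_a <- value_a[!ties]; value_b <- value_b[!ties]
  }
  n <- length(value_a)
  if (n == 0L) stop("no comparisons left after tie removal")
  s <- sum(value_a > value_b)
  list(successes = s, n = n,
       p = stats::pbinom(s - 1, n, 0.5, lower.tail = FALSE))
}

#' Case/control coordination analysis of a gene set
#'
#' Convenience wrapper reproducing the dysregulated-coordination layout:
#' for a given challenge, compares the case and control arms over all
#' within-set pairs (or the supplied pairs) and returns the observed /
#' expected / binomial-p summary together with the per-pair detail
#' table.
#'
#' @param study An [expression_study()] with case and control samples.
#' @param set Character vector of genes, or `NULL` when `pairs` given.
#' @param challenge `"allergen"` or `"diluent"`.
#' @param pairs Optional explicit gene pairs (2 columns).
#' @param alpha Nominal per-pair level.
#' @return List of class `coordination_result`: summary (data.frame),
#'   detail (per-pair table), set_size, challenge.
#' @export
coordination_analysis <- function(study, set = NULL,
                                  challenge = c("allergen", "diluent"),
                                  pairs = NULL, alpha = 0.05) {
  challenge <- match.arg(challenge)
  stopifnot(inherits(study, "expression_study"))
  cases <- study_arm(study, paste0("case_", challenge))
  controls <- study_arm(study, paste0("control_", challenge))
  if (is.null(pairs)) {
    stopifnot(!is.null(set))
    pairs <- all_pairs(intersect(set, rownames(study$exprs)))
  }
  detail <- correlation_difference_table(cases, controls, pairs)
  summary <- dysregulation_summary(detail$p, alpha)
  structure(list(summary = summary, detail = detail,
                 set_size = length(unique(c(detail$gene_a, detail$gene_b))),
                 challenge = challenge),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat("Coordination dysregulation (", x$challenge, " challenge, ",
      x$set_size, " genes, N = ", x$summary$n, " pairs)\n", sep = "")
  cat("  observed ", x$summary$observed, " vs expected ",
      x$summary$expected, " significant differences;  exact binomial p = ",
      format(x$summary$p_binom, digits = 2), "\n", sep = "")
  invisible(x)
}
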