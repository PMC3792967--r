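#' Per-gene differential expression between two study arms
#'
#' Computes, for every gene, the log2 ratio of arm means with its
#' delta-method standard error, a Welch (unequal-variance) t-test
#' p-value, an optional label-permutation p-value, and
#' Benjamini-Hochberg q-values across genes.
#'
#' With `log2_scale = TRUE` (the default; microarray matrices are
#' conventionally on the log2 scale) the log2 ratio of means is the
#' difference of arm means and the usual Welch machinery applies
#' directly.  With `log2_scale = FALSE` intensities are linear:
#' `log2_ratio = log2(mean(arm1)) - log2(mean(arm2))`, the SE follows
#' from the delta method on the per-arm means, and the Welch
#' Satterthwaite degrees of freedom are computed on the transformed
#' variances.
#'
#' @param study An [expression_study()].
#' @param contrast Either a string `"arm1-vs-arm2"` using arm labels
#'   (e.g. `"case_allergen-vs-case_diluent"`) or a character vector of
#'   length 2 of arm labels; arm1 is the numerator.
#' @param n_perm Number of label permutations for the permutation
#'   p-value (0 to skip).  The permutation shuffles arm labels and
#'   recomputes the Welch t statistic; p is add-one corrected.
#' @param log2_scale Are intensities already log2-transformed?
#' @return data.frame of class `de_result`: gene, log2_ratio, se, stat,
#'   df, p, p_perm (NA when `n_perm = 0`), q.
#' @export
differential_expression <- function(study, contrast, n_perm = 0L,
                                    log2_scale = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  arms <- parse_contrast(contrast)
  x1 <- study_arm(study, arms[1])
  x2 <- study_arm(study, arms[2])
  if (ncol(x1) < 2L || ncol(x2) < 2L)
    stop("each contrast arm needs at least 2 samples")
  res <- welch_log2ratio(x1, x2, log2_scale)

  p_perm <- rep(NA_real_, nrow(res))
  if (n_perm > 0L) {
    pooled <- cbind(x1, x2)
    n1 <- ncol(x1)
    exceed <- integer(nrow(res))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(ncol(pooled))
      rb <- welch_log2ratio(pooled[, idx[seq_len(n1)], drop = FALSE],
                            pooled[, idx[-seq_len(n1)], drop = FALSE],
                            log2_scale)
      exceed <- exceed + (abs(rb$stat) >= abs(res$stat))
    }
    p_perm <- perm_pvalue(exceed, n_perm)
  }
  out <- data.frame(gene = rownames(x1), res, p_perm = p_perm,
                    q = bh_qvalues(res$p), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

parse_contrast <- function(contrast) {
  if (length(contrast) == 1L && grepl("-vs-", contrast, fixed = TRUE))
    contrast <- strsplit(contrast, "-vs-", fixed = TRUE)[[1]]
  if (length(contrast) != 2L)
    stop("contrast must name two arms, e.g. \"case_allergen-vs-case_diluent\"")
  contrast
}

welch_log2ratio <- function(x1, x2, log2_scale) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  if (log2_scale) {
    est <- m1 - m2
    c1 <- v1 / n1; c2 <- v2 / n2
  } else {
    if (any(m1 <= 0) || any(m2 <= 0)) {
      bad <- rownames(x1)[m1 <= 0 | m2 <= 0]
      stop("non-positive arm mean on the linear scale for gene(s): ",
           paste(bad, collapse = ", "))
    }
    est <- log2(m1) - log2(m2)
    # delta method: var(log2 m) = var(m) / (m ln 2)^2
    c1 <- v1 / (n1 * (m1 * log(2))^2)
    c2 <- v2 / (n2 * (m2 * log(2))^2)
  }
  se <- sqrt(c1 + c2)
  df <- (c1 + c2)^2 / (c1^2 / (n1 - 1) + c2^2 / (n2 - 1))
  stat <- est / se
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  data.frame(log2_ratio = est, se = se, stat = stat, df = df, p = p)
}

#' Fixed-effect meta-analysis of per-gene log2 ratios
#'
#' Inverse-variance pooling across two or more studies, matched by gene
#' id (inner join); genes present in only one study are dropped with a
#' message.  Pooled SE is `(sum of weights)^(-1/2)` with weights
#' `1/se^2`; the p-value is two-sided normal.
#'
#' @param results_by_study List of two or more `de_result` data.frames
#'   (needs columns gene, log2_ratio, se).
#' @return data.frame: gene, log2_ratio (pooled), se, z, p, q.
#' @export
meta_analyze_logratios <- function(results_by_study) {
  if (length(results_by_study) < 2L)
    stop("meta-analysis needs at least two studies")
  genes <- Reduce(intersect, lapply(results_by_study, `[[`, "gene"))
  dropped <- setdiff(unique(unlist(lapply(results_by_study, `[[`, "gene"))),
                     genes)
  if (length(dropped))
    message(length(dropped), " gene(s) absent from some study excluded ",
            "from meta-analysis")
  est <- do.call(cbind, lapply(results_by_study,
                               function(d) d$log2_ratio[match(genes, d$gene)]))
  se <- do.call(cbind, lapply(results_by_study,
                              function(d) d$se[match(genes, d$gene)]))
  w <- 1 / se^2
  pooled <- rowSums(est * w) / rowSums(w)
  pooled_se <- 1 / sqrt(rowSums(w))
  z <- pooled / pooled_se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(gene = genes, log2_ratio = pooled, se = pooled_se, z = z,
             p = p, q = bh_qvalues(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Reproducibility decision rule for meta-analysed genes
#'
#' A gene is reproducibly differentially expressed when its
#' meta-analysis p-value is smaller (strictly) than both the discovery
#' p-value and the Bonferroni-corrected family level
#' `alpha / n_tests`.
#'
#' @param meta_p,discovery_p P-values (vectorised).
#' @param n_tests Number of tests in the family (e.g. probes on the
#'   array).
#' @param alpha Family-wise level.
#' @return Logical vector.
#' @seealso [bonferroni_threshold()]
#' @export
is_reproducible <- function(meta_p, discovery_p, n_tests, alpha = 0.05) {
  stop_if_not_prob(meta_p, "meta_p")
  stop_if_not_prob(discovery_p, "discovery_p")
  stopifnot(n_tests >= 1)
  meta_p < discovery_p & meta_p < bonferroni_threshold(alpha, n_tests)
}

#' Bonferroni-corrected significance threshold
#' @inheritParams is_reproducible
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1) alpha / n_tests
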