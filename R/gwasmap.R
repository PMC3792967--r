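#' Map genes to their best SNP within a window
#'
#' MAGENTA-style gene scoring: each gene is assigned the smallest SNP
#' association p-value among SNPs falling within `window` bp upstream or
#' downstream of the gene span.  Coordinates come in BED convention
#' (0-based half-open) and are converted internally to 1-based inclusive,
#' so a SNP is eligible when
#' `start + 1 - window <= pos <= end + window` (both bounds inclusive).
#' Genes without any eligible SNP are absent from the output.
#'
#' @param gwas data.frame of summary statistics: snp, chrom, pos
#'   (1-based), p.
#' @param coords Gene coordinate table: chrom, start, end, gene
#'   (0-based half-open).
#' @param window Window size in bp on each side (default 50 kb).
#' @return data.frame: gene, best_snp, best_p, n_snps (SNPs in window).
#' @export
map_genes_to_best_snp <- function(gwas, coords, window = 50000L) {
  stopifnot(window >= 0)
  coords <- validate_gene_coords(coords)
  gwas <- validate_gwas(gwas)
  empty <- data.frame(gene = character(0), best_snp = character(0),
                      best_p = numeric(0), n_snps = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(gwas) == 0L || nrow(coords) == 0L) return(empty)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = coords$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, coords$start + 1L - window),
                              end = coords$end + window))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = gwas$chrom,
    ranges = IRanges::IRanges(start = gwas$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gene_gr, snp_gr)
  if (length(hits) == 0L) return(empty)
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  best <- vapply(split(si, gi), function(idx) idx[which.min(gwas$p[idx])], 0L)
  gsel <- as.integer(names(best))
  data.frame(gene = coords$gene[gsel],
             best_snp = gwas$snp[best],
             best_p = gwas$p[best],
             n_snps = as.integer(lengths(split(si, gi))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' MAGENTA-style pathway enrichment of GWAS gene scores
#'
#' Counts, per gene set, how many member genes score above the
#' `cutoff_quantile` of `-log10(best p)` over all scored genes, and
#' compares that count with `n_perm` random draws of equally many scored
#' genes (add-one corrected, observed-or-more).  BH FDR is computed
#' across sets; `significant` flags sets at `p <= 0.05` and
#' `FDR <= 0.25`.  Only scored genes enter both the observed counts and
#' the null draws.
#'
#' @param scores Gene score table from [map_genes_to_best_snp()].
#' @param sets Named list of gene sets; sets with fewer than 3 scored
#'   genes are skipped with a warning.
#' @param cutoff_quantile Quantile of the -log10 best-p distribution
#'   defining "high-scoring" (default 0.95).
#' @param n_perm Number of random gene draws.
#' @return data.frame: set, size (scored genes), observed, expected
#'   (null mean), p, fdr, significant.
#' @export
magenta_enrichment <- function(scores, sets, cutoff_quantile = 0.95,
                               n_perm = 1000L) {
  stopifnot(nrow(scores) > 0L, all(c("gene", "best_p") %in% names(scores)))
  if (!is.list(sets)) sets <- list(set = sets)
  score <- -log10(scores$best_p)
  names(score) <- scores$gene
  threshold <- stats::quantile(score, cutoff_quantile, names = FALSE)
  high <- score >= threshold
  n_genes <- length(score)
  rows <- lapply(names(sets), function(nm) {
    idx <- which(names(score) %in% sets[[nm]])
    K <- length(idx)
    if (K < 3L) {
      warning("set '", nm, "' skipped: only ", K, " scored gene(s)",
              call. = FALSE)
      return(NULL)
    }
    obs <- sum(high[idx])
    null_counts <- vapply(seq_len(n_perm), function(b)
      sum(high[sample.int(n_genes, K)]), 0L)
    p <- perm_pvalue(sum(null_counts >= obs), n_perm)
    data.frame(set = nm, size = K, observed = obs,
               expected = mean(null_counts), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$fdr <- bh_qvalues(out$p)
  out$significant <- out$p <= 0.05 & out$fdr <= 0.25
  out[order(out$p), , drop = FALSE]
}
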