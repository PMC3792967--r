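# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding; reported
# expected counts such as N * alpha use conventional half-up rounding).
round_half_up <- function(x) floor(x + 0.5)

# Add-one-corrected permutation p-value: b exceedances in n_perm resamples.
perm_pvalue <- function(b, n_perm) (b + 1) / (n_perm + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# All unordered pairs of a character vector, as a 2-column matrix.
all_pairs <- function(genes) {
  genes <- unique(as.character(genes))
  if (length(genes) < 2L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  }
  idx <- utils::combn(length(genes), 2L)
  cbind(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]])
}

stop_if_not_prob <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("'%s' must contain probabilities in [0, 1]", what),
         call. = FALSE)
  }
  invisible(p)
}
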