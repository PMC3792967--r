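# Small configurations and hand-built studies shared across tests.

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 60L, n_pathways = 4L, pathway_size = 10L,
         n_samples_per_arm = 10L,
         ppi = list(n_crossing = 4L),
         gwas = list(n_snps = 800L, chrom_lengths = c(chr1 = 6e6)),
         seed = seed),
    list(...))
  do.call(synth_config, args)
}

tiny_null_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 100L, n_pathways = 5L, pathway_size = 12L,
         n_samples_per_arm = 10L,
         gwas = list(n_snps = 1000L, chrom_lengths = c(chr1 = 1.1e7),
                     planted_fraction = 0),
         seed = seed),
    list(...))
  do.call(null_config, args)
}

# Build an expression_study from a named list of arm matrices
# (names like "case_allergen"); genes taken from the first matrix.
mk_study <- function(arm_mats) {
  stopifnot(length(arm_mats) >= 1, !is.null(names(arm_mats)))
  cols <- list(); ann <- list()
  for (arm in names(arm_mats)) {
    m <- as.matrix(arm_mats[[arm]])
    ids <- sprintf("%s_%02d", arm, seq_len(ncol(m)))
    colnames(m) <- ids
    cols[[arm]] <- m
    ann[[arm]] <- data.frame(sample = ids,
                             group = sub("_.*", "", arm),
                             challenge = sub(".*_", "", arm),
                             pair = ids, stringsAsFactors = FALSE)
  }
  expression_study(do.call(cbind, cols), do.call(rbind, ann))
}

# O(n^2) non-domination oracle (minimisation in both coordinates).
brute_pareto <- function(pe, pg) {
  vapply(seq_along(pe), function(i) {
    !any(pe <= pe[i] & pg <= pg[i] & (pe < pe[i] | pg < pg[i]))
  }, logical(1))
}
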