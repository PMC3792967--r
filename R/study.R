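#' Expression study container
#'
#' Bundles a genes-by-samples expression matrix (log2 scale by
#' convention) with its per-sample annotation: disease group
#' (case/control), culture challenge (allergen/diluent) and pairing id.
#' The design mirrors a 2-group x 2-challenge PBMC culture experiment;
#' paired samples are annotated but analyses treat arms as unpaired.
#'
#' @param exprs Numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns.
#' @param samples data.frame with columns `sample`, `group`
#'   (`case`/`control`), `challenge` (`allergen`/`diluent`) and `pair`;
#'   one row per column of `exprs`.
#' @return An object of class `expression_study` with elements `exprs`
#'   and `samples`; `samples$arm` holds the combined `group_challenge`
#'   label.
#' @export
expression_study <- function(exprs, samples) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || anyNA(rownames(exprs)))
    stop("expression matrix must have complete gene ids as rownames")
  stopifnot(is.data.frame(samples),
            all(c("sample", "group", "challenge", "pair") %in% names(samples)))
  if (!setequal(colnames(exprs), samples$sample) ||
      ncol(exprs) != nrow(samples))
    stop("every expression column must match exactly one annotation row")
  samples <- samples[match(colnames(exprs), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  stopifnot(all(samples$group %in% c("case", "control")),
            all(samples$challenge %in% c("allergen", "diluent")))
  samples$arm <- paste(samples$group, samples$challenge, sep = "_")
  if (any(table(samples$arm) < 2L))
    stop("each present arm needs at least 2 samples")
  structure(list(exprs = exprs, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study:", nrow(x$exprs), "genes x", ncol(x$exprs),
      "samples\n")
  print(table(group = x$samples$group, challenge = x$samples$challenge))
  invisible(x)
}

#' Extract the sub-matrix of one study arm
#'
#' @param study An [expression_study()].
#' @param arm Arm label, e.g. `"case_allergen"`.
#' @return Genes-by-samples matrix of that arm.
#' @export
study_arm <- function(study, arm) {
  stopifnot(inherits(study, "expression_study"))
  keep <- study$samples$arm == arm
  if (!any(keep)) stop("no samples in arm: ", arm)
  study$exprs[, keep, drop = FALSE]
}
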