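#' Read a GMT gene-set file
#'
#' GMT is the standard tab-separated gene-set format: one set per line,
#' fields are set name, description, then member gene ids.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, with the
#'   per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT file")
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a BED-like gene coordinate table
#'
#' Expects at least four columns: chromosome, start, end, name, with BED's
#' 0-based half-open coordinate convention.
#'
#' @param path Path to a BED file (no header).
#' @return data.frame with columns chrom, start, end, gene.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED file needs chrom, start, end, name columns")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "gene")
  validate_gene_coords(df)
}

#' Write a gene coordinate table as BED
#' @param coords data.frame with chrom, start, end, gene (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(coords, path) {
  coords <- validate_gene_coords(coords)
  utils::write.table(coords[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

validate_gene_coords <- function(coords) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(coords)))
  bad <- coords$end <= coords$start
  if (any(bad)) {
    stop("malformed coordinates (end <= start) for gene(s): ",
         paste(coords$gene[bad], collapse = ", "))
  }
  coords
}

#' Read/write GWAS summary statistics
#'
#' Tab-separated with header: snp, chrom, pos (1-based), p.
#' @param path File path.
#' @return data.frame with columns snp, chrom, pos, p.
#' @export
read_gwas <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("snp", "chrom", "pos", "p") %in% names(df)))
  validate_gwas(df)
}

#' @rdname read_gwas
#' @param gwas data.frame as returned by [simulate_gwas()].
#' @export
write_gwas <- function(gwas, path) {
  validate_gwas(gwas)
  utils::write.table(gwas[, c("snp", "chrom", "pos", "p")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

validate_gwas <- function(gwas) {
  if (nrow(gwas) == 0L) return(gwas)
  if (anyDuplicated(gwas$snp)) stop("duplicate SNP ids in GWAS table")
  if (any(gwas$pos < 1L)) stop("GWAS positions must be positive 1-based integers")
  stop_if_not_prob(gwas$p, "gwas$p")
  gwas
}

#' Read/write a protein-interaction edge list
#'
#' Tab-separated with header: node_a, node_b, type (direct/indirect),
#' evidence.
#' @param path File path.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("node_a", "node_b", "type", "evidence") %in% names(df)))
  interaction_graph(df)
}

#' @rdname read_edge_list
#' @param graph An `interaction_graph` or compatible data.frame.
#' @export
write_edge_list <- function(graph, path) {
  edges <- as.data.frame(graph)
  utils::write.table(edges[, c("node_a", "node_b", "type", "evidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write an expression study (matrix + sample annotation)
#'
#' The expression matrix is tab-separated with gene ids in the first
#' column (`gene`) and one column per sample; the annotation table has
#' columns sample, group, challenge, pair.
#'
#' @param expr_path,annot_path File paths.
#' @return An [expression_study()] object.
#' @export
read_study <- function(expr_path, annot_path) {
  em <- utils::read.table(expr_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(em[, -1, drop = FALSE])
  rownames(mat) <- em[[1]]
  ann <- utils::read.table(annot_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expression_study(mat, ann)
}

#' @rdname read_study
#' @param study An [expression_study()] object.
#' @export
write_study <- function(study, expr_path, annot_path) {
  stopifnot(inherits(study, "expression_study"))
  em <- data.frame(gene = rownames(study$exprs), study$exprs,
                   check.names = FALSE)
  utils::write.table(em, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Serialize / restore the planted ground truth of a synthetic dataset
#' @param truth A `synth_truth` list as produced by the generators.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(truth) <- "synth_truth"
  truth
}
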