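#' Configuration for the synthetic study generator
#'
#' Defines a synthetic 2-group x 2-challenge expression study with
#' planted pathway-level differential expression, block co-expression,
#' case-arm correlation disruption, GWAS p-value enrichment near
#' designated genes, a protein-interaction background with planted
#' cross-pathway edges, and a protein response linearly dependent on
#' designated genes.  The defaults emulate the study design the
#' pipeline targets: allergen-challenged CD4+ T cells from cases and
#' controls, a pathway dysregulated in both expression and GWAS data,
#' and an inter-pathway network whose coordination breaks down in the
#' case-allergen arm.
#'
#' Genes are named `g001`, `g002`, ... and partitioned into disjoint
#' pathways `P01`, `P02`, ... of equal size.  Defaults: 250 genes, 20
#' samples per arm, Gaussian noise with sd 0.5 on the log2 scale,
#' log2 effect magnitudes spanning 0.3-2.7 on pathway `P01`
#' (case-allergen arm), a 0.8 co-expression block on `P03`, 12 planted
#' crossing edges `P01` x `P02` whose gene pairs gain correlation 0.9 in
#' the case-allergen arm (a 24-gene inter-pathway network, 276 gene
#' pairs), a Beta(0.1, 1) GWAS alternative on half of `P01`'s genes, and
#' a protein response driven by 5 network genes.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_arm Samples in each of the four arms.
#' @param n_pathways,pathway_size Disjoint pathway layout
#'   (`n_pathways * pathway_size <= n_genes`).
#' @param de_pathway Pathway receiving planted log2 shifts in the
#'   case-allergen arm, or `NULL` for none.
#' @param de_effects Per-gene log2 effect sizes for `de_pathway`
#'   (recycled/truncated to the pathway size).
#' @param coexpr_blocks Named list: pathway name -> within-block
#'   correlation in [0, 1).
#' @param dysreg_pairs data.frame (`gene_a`, `gene_b`, `delta`) of gene
#'   pairs whose correlation is shifted by `delta` in `dysreg_arm`;
#'   `NULL` for none.
#' @param dysreg_arm Arm carrying the correlation disruption.
#' @param baseline_mean,noise_sd Mean and sd of log2 intensities.
#' @param gwas List: `n_snps`, `chrom_lengths` (named), `pathway` (or
#'   `NULL`), `planted_fraction`, `beta_a` (Beta(a, 1) alternative,
#'   a < 1), `window` (bp).
#' @param ppi List: `density` (background Erdos-Renyi edge density),
#'   `pathway_a`, `pathway_b`, `n_crossing` planted crossing edges
#'   (0 for none).
#' @param protein List: `targets` (gene ids), `coefficients`,
#'   `noise_sd_scale` (response noise sd as a fraction of the signal
#'   sd), or `NULL` for none.
#' @param seed Integer seed; all generators derive their streams from
#'   it.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(n_genes = 250L,
                         n_samples_per_arm = 20L,
                         n_pathways = 10L,
                         pathway_size = 20L,
                         de_pathway = "P01",
                         de_effects = NULL,
                         coexpr_blocks = list(P03 = 0.8),
                         dysreg_pairs = NULL,
                         dysreg_arm = "case_allergen",
                         baseline_mean = 8,
                         noise_sd = 0.5,
                         gwas = list(),
                         ppi = list(),
                         protein = NULL,
                         seed = 1L) {
  stopifnot(n_genes >= 1L, n_samples_per_arm >= 2L, n_pathways >= 1L,
            pathway_size >= 1L, n_pathways * pathway_size <= n_genes,
            noise_sd > 0)
  genes <- sprintf("g%03d", seq_len(n_genes))
  sets <- split(genes[seq_len(n_pathways * pathway_size)],
                rep(seq_len(n_pathways), each = pathway_size))
  names(sets) <- sprintf("P%02d", seq_len(n_pathways))

  gwas <- utils::modifyList(list(n_snps = 4000L,
                                 chrom_lengths = c(chr1 = 2.6e7),
                                 pathway = "P01",
                                 planted_fraction = 0.75,
                                 beta_a = 0.1,
                                 window = 50000L), gwas)
  ppi <- utils::modifyList(list(density = 0.01,
                                pathway_a = "P01",
                                pathway_b = "P02",
                                n_crossing = 12L), ppi)
  if (gwas$beta_a >= 1 || gwas$beta_a <= 0)
    stop("gwas$beta_a must lie in (0, 1) for a low-p alternative")

  if (!is.null(de_pathway)) {
    if (!de_pathway %in% names(sets)) stop("unknown de_pathway: ", de_pathway)
    if (is.null(de_effects)) {
      # coherent down-regulation of the planted pathway, magnitudes
      # spanning the typical microarray range
      k <- length(sets[[de_pathway]])
      de_effects <- -seq(0.3, 2.7, length.out = k)
    }
    de_effects <- rep_len(de_effects, length(sets[[de_pathway]]))
    names(de_effects) <- sets[[de_pathway]]
  }

  if (is.null(dysreg_pairs) && ppi$n_crossing > 0) {
    # Default disruption sits on the planted crossing pairs, so the
    # inter-pathway network is also the dysregulated module.
    a <- sets[[ppi$pathway_a]][seq_len(ppi$n_crossing)]
    b <- sets[[ppi$pathway_b]][seq_len(ppi$n_crossing)]
    dysreg_pairs <- data.frame(gene_a = a, gene_b = b, delta = 0.9,
                               stringsAsFactors = FALSE)
  }
  if (!is.null(dysreg_pairs)) {
    stopifnot(all(c("gene_a", "gene_b", "delta") %in% names(dysreg_pairs)))
    if (any(abs(dysreg_pairs$delta) >= 1))
      stop("dysreg deltas must lie in (-1, 1)")
    missing <- setdiff(c(dysreg_pairs$gene_a, dysreg_pairs$gene_b), genes)
    if (length(missing))
      stop("dysreg pair genes absent from gene universe: ",
           paste(missing, collapse = ", "))
  }

  for (bl in names(coexpr_blocks)) {
    r <- coexpr_blocks[[bl]]
    if (r < 0 || r >= 1) stop("block correlation must lie in [0, 1)")
    if (!bl %in% names(sets)) stop("unknown co-expression block: ", bl)
  }

  if (is.null(protein) && ppi$n_crossing > 0) {
    a <- sets[[ppi$pathway_a]]; b <- sets[[ppi$pathway_b]]
    protein <- list(targets = c(a[1], b[1], a[3], b[3], a[5]),
                    coefficients = c(1.2, -1.0, 0.8, -0.8, 0.6),
                    noise_sd_scale = 0.5)
  }
  if (!is.null(protein)) {
    stopifnot(length(protein$targets) == length(protein$coefficients),
              all(protein$targets %in% genes))
    protein$noise_sd_scale <- protein$noise_sd_scale %||% 0.5
    # weights of the multivariate response panel (cytokine-panel
    # analogue): one column per response, signs emulating the mixed
    # up-/down-regulation patterns of a differentiation panel
    protein$panel_weights <- protein$panel_weights %||%
      c(1, 0.8, 0.6, -0.7, -0.9)
  }

  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_arm = as.integer(n_samples_per_arm),
                 genes = genes, sets = sets,
                 de_pathway = de_pathway, de_effects = de_effects,
                 coexpr_blocks = coexpr_blocks,
                 dysreg_pairs = dysreg_pairs, dysreg_arm = dysreg_arm,
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 gwas = gwas, ppi = ppi, protein = protein,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Null configuration: nothing planted
#'
#' Convenience wrapper used for calibration runs: no differential
#' expression, no co-expression blocks, no correlation disruption, no
#' GWAS alternative, no crossing edges, no protein response.
#'
#' @param ... Passed on to [synth_config()].
#' @export
null_config <- function(...) {
  args <- utils::modifyList(
    list(de_pathway = NULL, coexpr_blocks = list(),
         dysreg_pairs = NULL, gwas = list(planted_fraction = 0),
         ppi = list(n_crossing = 0L), protein = NULL),
    list(...))
  # NULL cannot switch the GWAS planting off through modifyList (it
  # deletes the entry and the planted default would resurface), hence
  # the planted_fraction = 0 convention.
  do.call(synth_config, args)
}

# Target correlation matrix for one arm: co-expression blocks plus, in
# the disrupted arm, the planted pair deltas.  Repaired to the nearest
# correlation matrix by eigenvalue clipping (Matrix::nearPD) when the
# deltas break positive semi-definiteness.
arm_correlation <- function(config, arm) {
  R <- diag(config$n_genes)
  dimnames(R) <- list(config$genes, config$genes)
  for (bl in names(config$coexpr_blocks)) {
    g <- config$sets[[bl]]
    R[g, g] <- config$coexpr_blocks[[bl]]
    R[cbind(g, g)] <- 1
  }
  if (!is.null(config$dysreg_pairs) && identical(arm, config$dysreg_arm)) {
    dp <- config$dysreg_pairs
    new_r <- R[cbind(dp$gene_a, dp$gene_b)] + dp$delta
    if (any(abs(new_r) >= 1))
      stop("dysreg delta pushes correlation outside (-1, 1) for pair(s): ",
           paste(dp$gene_a, dp$gene_b, sep = "-", collapse = ", "))
    R[cbind(dp$gene_a, dp$gene_b)] <- new_r
    R[cbind(dp$gene_b, dp$gene_a)] <- new_r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    rep <- tryCatch(
      as.matrix(Matrix::nearPD(R, corr = TRUE)$mat),
      error = function(e) NULL)
    if (is.null(rep)) {
      dp <- config$dysreg_pairs
      stop("target correlation matrix is not positive semi-definite and ",
           "could not be repaired; offending pairs: ",
           paste(dp$gene_a, dp$gene_b, sep = "-", collapse = ", "))
    }
    dimnames(rep) <- dimnames(R)
    R <- rep
  }
  R
}

#' Generate a synthetic expression study
#'
#' Draws each arm from a multivariate normal on the log2 scale:
#' mean = baseline (+ planted log2 shifts on the DE pathway in the
#' case-allergen arm), covariance = `noise_sd^2` times the arm's target
#' correlation matrix (co-expression blocks everywhere; planted pair
#' deltas in the disrupted arm only).  A protein response, when
#' configured, is a linear combination of target-gene expression plus
#' Gaussian noise with sd equal to `noise_sd_scale` times the signal sd.
#'
#' @param config A [synth_config()].
#' @return List with `study` (an [expression_study()]), `protein`
#'   (named numeric response per sample, or `NULL`), `panel` (samples x
#'   responses matrix, the multivariate response panel, or `NULL`) and
#'   `truth` (`synth_truth`: every planted signal plus the seed).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  arms <- c("case_allergen", "case_diluent",
            "control_allergen", "control_diluent")
  n <- config$n_samples_per_arm
  R_base <- arm_correlation(config, arm = NA_character_)
  cols <- list()
  ann <- list()
  for (arm in arms) {
    R <- if (!is.null(config$dysreg_pairs) &&
             identical(arm, config$dysreg_arm))
      arm_correlation(config, arm) else R_base
    mu <- rep(config$baseline_mean, config$n_genes)
    names(mu) <- config$genes
    if (!is.null(config$de_pathway) && arm == "case_allergen")
      mu[names(config$de_effects)] <- mu[names(config$de_effects)] +
        config$de_effects
    X <- MASS::mvrnorm(n, mu = mu, Sigma = config$noise_sd^2 * R)
    grp <- sub("_.*", "", arm)
    chl <- sub(".*_", "", arm)
    ids <- sprintf("%s_%02d", arm, seq_len(n))
    cols[[arm]] <- t(X)
    colnames(cols[[arm]]) <- ids
    ann[[arm]] <- data.frame(sample = ids, group = grp, challenge = chl,
                             pair = sprintf("%s_subj_%02d", grp, seq_len(n)),
                             stringsAsFactors = FALSE)
  }
  exprs <- do.call(cbind, cols)
  rownames(exprs) <- config$genes
  study <- expression_study(exprs, do.call(rbind, ann))

  protein <- NULL
  panel <- NULL
  if (!is.null(config$protein)) {
    pr <- config$protein
    signal <- drop(crossprod(exprs[pr$targets, , drop = FALSE],
                             pr$coefficients))
    protein <- signal + stats::rnorm(length(signal),
                                     sd = pr$noise_sd_scale * stats::sd(signal))
    names(protein) <- colnames(exprs)
    # multivariate response panel: each column scales the same target
    # signal by its panel weight, with independent noise
    panel <- sapply(pr$panel_weights, function(w) {
      y <- w * signal
      y + stats::rnorm(length(y), sd = pr$noise_sd_scale * stats::sd(y))
    })
    dimnames(panel) <- list(colnames(exprs),
                            sprintf("R%d", seq_along(pr$panel_weights)))
  }

  planted_gwas <- planted_gwas_genes(config)
  truth <- structure(list(
    de_pathway = config$de_pathway,
    de_effects = config$de_effects,
    gwas_pathway = if (length(planted_gwas)) config$gwas$pathway,
    gwas_genes = planted_gwas,
    dysreg_pairs = config$dysreg_pairs,
    dysreg_arm = config$dysreg_arm,
    coexpr_blocks = config$coexpr_blocks,
    crossing_edges = planted_crossing_edges(config),
    protein_targets = config$protein$targets,
    protein_coefficients = config$protein$coefficients,
    panel_weights = config$protein$panel_weights,
    seed = config$seed), class = "synth_truth")

  list(study = study, protein = protein, panel = panel, truth = truth)
}

planted_gwas_genes <- function(config) {
  g <- config$gwas
  if (is.null(g$pathway) || g$planted_fraction <= 0) return(character(0))
  members <- config$sets[[g$pathway]]
  members[seq_len(ceiling(g$planted_fraction * length(members)))]
}

planted_crossing_edges <- function(config) {
  p <- config$ppi
  if (p$n_crossing == 0L) {
    return(data.frame(node_a = character(0), node_b = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(node_a = config$sets[[p$pathway_a]][seq_len(p$n_crossing)],
             node_b = config$sets[[p$pathway_b]][seq_len(p$n_crossing)],
             stringsAsFactors = FALSE)
}

#' Deterministic gene coordinate table for a configuration
#'
#' Genes are laid out evenly along the configured chromosomes (allocated
#' proportionally to length), each spanning 2 kb, in BED convention
#' (0-based half-open).
#'
#' @param config A [synth_config()].
#' @return data.frame with chrom, start, end, gene.
#' @export
gene_coordinates <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lens <- config$gwas$chrom_lengths
  n_per <- pmax(1L, round_half_up(config$n_genes * lens / sum(lens)))
  # fix rounding so the total matches
  while (sum(n_per) != config$n_genes) {
    i <- if (sum(n_per) > config$n_genes) which.max(n_per) else which.min(n_per)
    n_per[i] <- n_per[i] + sign(config$n_genes - sum(n_per))
  }
  out <- lapply(seq_along(lens), function(ci) {
    k <- n_per[ci]
    spacing <- floor(lens[ci] / k)
    start <- (seq_len(k) - 1L) * spacing
    data.frame(chrom = names(lens)[ci], start = start,
               end = start + 2000L, gene = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$gene <- config$genes
  rownames(out) <- NULL
  validate_gene_coords(out)
}

#' Generate synthetic GWAS summary statistics
#'
#' Null SNPs carry i.i.d. Uniform(0, 1) p-values at uniform random
#' 1-based positions.  For each planted gene (the configured fraction of
#' the GWAS pathway), one SNP inside the gene's +/- `window` region is
#' given a p-value from the Beta(a, 1) low-p alternative; when no
#' background SNP falls in the window an extra SNP is placed at the gene
#' midpoint.
#'
#' @param config A [synth_config()].
#' @param coords Gene coordinate table covering the planted genes
#'   (default [gene_coordinates()]).
#' @return data.frame with columns snp, chrom, pos, p.
#' @export
simulate_gwas <- function(config, coords = gene_coordinates(config)) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  g <- config$gwas
  if (g$n_snps == 0L) {
    return(data.frame(snp = character(0), chrom = character(0),
                      pos = integer(0), p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  lens <- g$chrom_lengths
  n_per <- stats::rmultinom(1, g$n_snps, lens / sum(lens))[, 1]
  tab <- do.call(rbind, lapply(seq_along(lens), function(ci) {
    data.frame(chrom = names(lens)[ci],
               pos = sort(sample.int(lens[ci], n_per[ci], replace = FALSE)),
               stringsAsFactors = FALSE)
  }))
  tab$snp <- sprintf("rs%06d", seq_len(nrow(tab)))
  tab$p <- stats::runif(nrow(tab))

  planted <- planted_gwas_genes(config)
  if (length(planted)) {
    missing <- setdiff(planted, coords$gene)
    if (length(missing))
      stop("planted GWAS gene(s) without coordinates: ",
           paste(missing, collapse = ", "))
    for (gene in planted) {
      co <- coords[coords$gene == gene, ][1, ]
      lo <- max(1L, co$start + 1L - g$window)
      hi <- co$end + g$window
      in_win <- which(tab$chrom == co$chrom & tab$pos >= lo & tab$pos <= hi)
      p_alt <- stats::rbeta(1, g$beta_a, 1)
      if (length(in_win)) {
        hit <- in_win[which.min(tab$p[in_win])]
        tab$p[hit] <- min(tab$p[hit], p_alt)
      } else {
        mid <- as.integer((co$start + 1L + co$end) / 2)
        if (mid < lo || mid > hi)
          stop("no SNP placeable in window of planted gene: ", gene)
        tab <- rbind(tab, data.frame(chrom = co$chrom, pos = mid,
                                     snp = paste0("rs_planted_", gene),
                                     p = p_alt, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(tab) <- NULL
  validate_gwas(tab[, c("snp", "chrom", "pos", "p")])
}

#' Generate a synthetic protein-interaction graph
#'
#' Background edges are Erdos-Renyi at the configured density over all
#' gene pairs except the cross-pathway cell holding the planted crossing
#' edges, so the planted edges are exactly the direct interactions
#' linking the two designated pathways.  All edges are flagged `direct`.
#'
#' @param config A [synth_config()].
#' @return An [interaction_graph()].
#' @export
simulate_interactions <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  genes <- config$genes
  n <- length(genes)
  p <- config$ppi
  bg <- igraph::sample_gnp(n, p$density, directed = FALSE)
  el <- igraph::as_edgelist(bg, names = FALSE)
  edges <- data.frame(node_a = genes[el[, 1]], node_b = genes[el[, 2]],
                      stringsAsFactors = FALSE)
  planted <- planted_crossing_edges(config)
  if (nrow(planted)) {
    missing <- setdiff(c(planted$node_a, planted$node_b), genes)
    if (length(missing))
      stop("planted crossing edge endpoint(s) absent from gene universe: ",
           paste(missing, collapse = ", "))
    a <- config$sets[[p$pathway_a]]
    b <- config$sets[[p$pathway_b]]
    crossing_cell <- (edges$node_a %in% a & edges$node_b %in% b) |
      (edges$node_a %in% b & edges$node_b %in% a)
    edges <- edges[!crossing_cell, , drop = FALSE]
    edges <- rbind(edges, planted)
  }
  edges$type <- "direct"
  edges$evidence <- "synthetic"
  interaction_graph(edges, nodes = genes)
}

#' Simulate every input of the pipeline at once
#'
#' @param config A [synth_config()].
#' @return List with `study`, `protein`, `gwas`, `coords`, `sets`
#'   (pathway collection), `graph` and `truth`.
#' @export
simulate_all <- function(config) {
  expr <- simulate_expression(config)
  coords <- gene_coordinates(config)
  list(study = expr$study,
       protein = expr$protein,
       panel = expr$panel,
       gwas = simulate_gwas(config, coords),
       coords = coords,
       sets = config$sets,
       graph = simulate_interactions(config),
       truth = expr$truth)
}
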