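#' Protein-interaction graph container
#'
#' An undirected edge list of molecular interactions with a
#' direct/indirect flag and an evidence tag.  Self-loops are rejected
#' and duplicate undirected edges collapse to one.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `type`
#'   (`direct`/`indirect`) and `evidence`; `type`/`evidence` are filled
#'   with `"direct"`/`"na"` when absent.
#' @param nodes Optional character vector of the full node universe
#'   (defaults to the union of edge endpoints).
#' @return An object of class `interaction_graph`.
#' @export
interaction_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b") %in% names(edges)))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (!"type" %in% names(edges)) edges$type <- "direct"
  if (!"evidence" %in% names(edges)) edges$evidence <- "na"
  if (!all(edges$type %in% c("direct", "indirect")))
    stop("edge type must be 'direct' or 'indirect'")
  if (any(edges$node_a == edges$node_b)) stop("self-loops are not allowed")
  # canonical endpoint order so undirected duplicates collapse
  flip <- edges$node_a > edges$node_b
  tmp <- edges$node_a[flip]
  edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  edges <- edges[!duplicated(edges[, c("node_a", "node_b")]), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- union(nodes %||% character(0),
                 union(edges$node_a, edges$node_b))
  structure(list(edges = edges, nodes = nodes),
            class = "interaction_graph")
}

#' @export
as.data.frame.interaction_graph <- function(x, ...) x$edges

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Interaction graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (",
      sum(x$edges$type == "direct"), "direct )\n")
  invisible(x)
}

as_igraph <- function(graph, type = c("any", "direct")) {
  type <- match.arg(type)
  ed <- graph$edges
  if (type == "direct") ed <- ed[ed$type == "direct", , drop = FALSE]
  igraph::graph_from_data_frame(ed[, c("node_a", "node_b")],
                                directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Extract the inter-pathway interactions network between two pathways
#'
#' The network's members are the genes of either pathway incident to at
#' least one *direct* edge whose endpoints lie one in each pathway; the
#' retained edges are exactly those crossing direct edges.  Genes
#' belonging to both pathways may satisfy the crossing condition with
#' either endpoint role and are labelled `"both"`.  Indirect edges never
#' qualify.  An empty network is a valid result.
#'
#' @param graph An [interaction_graph()].
#' @param pathway_a,pathway_b Character vectors of gene ids (overlap
#'   allowed).
#' @return Object of class `inpar_network`: `members` (character),
#'   `edges` (crossing direct edges), `labels` (named pathway label per
#'   member: `"a"`, `"b"` or `"both"`), `within_edges` (direct edges
#'   among members inside one pathway, reported separately).
#' @export
extract_inpar_network <- function(graph, pathway_a, pathway_b) {
  stopifnot(inherits(graph, "interaction_graph"),
            length(pathway_a) > 0L, length(pathway_b) > 0L)
  ed <- graph$edges[graph$edges$type == "direct", , drop = FALSE]
  a_first <- ed$node_a %in% pathway_a & ed$node_b %in% pathway_b
  b_first <- ed$node_a %in% pathway_b & ed$node_b %in% pathway_a
  crossing <- ed[(a_first | b_first) & ed$node_a != ed$node_b, ,
                 drop = FALSE]
  members <- sort(unique(c(crossing$node_a, crossing$node_b)))
  labels <- ifelse(members %in% pathway_a & members %in% pathway_b, "both",
                   ifelse(members %in% pathway_a, "a", "b"))
  names(labels) <- members
  within <- ed[ed$node_a %in% members & ed$node_b %in% members, ,
               drop = FALSE]
  within <- within[!(paste(within$node_a, within$node_b) %in%
                       paste(crossing$node_a, crossing$node_b)), ,
                   drop = FALSE]
  structure(list(members = members, edges = crossing, labels = labels,
                 within_edges = within,
                 pathway_a = pathway_a, pathway_b = pathway_b),
            class = "inpar_network")
}

#' Cross-pathway gene pairs of an inter-pathway network
#'
#' All pairs of network members with one gene on each pathway side
#' (overlap-labelled genes count on both sides; self-pairs and
#' duplicates are removed).  This is the pair stratum in which planted
#' or biological cross-pathway coordination lives, reported separately
#' from the all-pairs analysis of the full network.
#'
#' @param network An [extract_inpar_network()] result.
#' @return Two-column character matrix of gene pairs.
#' @export
inter_pathway_pairs <- function(network) {
  stopifnot(inherits(network, "inpar_network"))
  lab <- network$labels
  a <- names(lab)[lab %in% c("a", "both")]
  b <- names(lab)[lab %in% c("b", "both")]
  if (!length(a) || !length(b))
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  grid <- expand.grid(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
  key <- ifelse(grid$gene_a < grid$gene_b,
                paste(grid$gene_a, grid$gene_b),
                paste(grid$gene_b, grid$gene_a))
  as.matrix(grid[!duplicated(key), , drop = FALSE])
}

#' @export
print.inpar_network <- function(x, ...) {
  cat("Inter-pathway network:", length(x$members), "genes,",
      nrow(x$edges), "crossing direct edges\n")
  if (length(x$members)) {
    tab <- table(factor(x$labels, levels = c("a", "b", "both")))
    cat("  pathway A:", tab[["a"]], " pathway B:", tab[["b"]],
        " overlap:", tab[["both"]], "\n")
  }
  invisible(x)
}

# log2-spaced degree bins over the background degree distribution,
# merged upward until every bin holds at least min_size candidates.
degree_bins <- function(deg, min_size = 5L) {
  breaks <- unique(c(-0.5, 0.5, 2^seq(1, ceiling(log2(max(deg, 1))))))
  if (max(breaks) < max(deg)) breaks <- c(breaks, max(deg))
  bin <- cut(deg, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  repeat {
    counts <- table(bin)
    small <- names(counts)[counts < min_size]
    if (!length(small) || length(counts) == 1L) break
    b <- as.integer(small[1])
    bins_present <- sort(unique(bin))
    neighbor <- if (b == max(bins_present))
      max(bins_present[bins_present < b]) else
        min(bins_present[bins_present > b])
    bin[bin == b] <- neighbor
  }
  bin
}

#' Connectivity enrichment of a gene set in an interaction network
#'
#' Tests whether a member set is more connected than expected by
#' chance, controlling for node degree: the direct statistic is the
#' number of edges among members; the indirect statistic is the number
#' of member pairs sharing at least one non-member neighbour.  The null
#' resamples node sets of the same size within log2-spaced degree bins
#' (bins with fewer than 5 candidates are merged, and the merge is
#' recorded in the result).  P-values are add-one corrected,
#' observed-or-greater.  Per-node p-values compare each member's
#' within-member degree with the within-sample degree of its stand-in
#' across permutations.
#'
#' @param members Character vector of member genes (must all be
#'   background nodes).
#' @param graph An [interaction_graph()] serving as background.
#' @param n_perm Number of null draws (>= 100).
#' @return List of class `connectivity_test`: direct_stat,
#'   indirect_stat, p_direct, p_indirect, node_p (named), n_perm,
#'   bins_merged.
#' @export
connectivity_enrichment <- function(members, graph, n_perm = 1000L) {
  stopifnot(inherits(graph, "interaction_graph"), n_perm >= 100L)
  members <- unique(as.character(members))
  absent <- setdiff(members, graph$nodes)
  if (length(absent))
    stop("member(s) absent from background graph: ",
         paste(absent, collapse = ", "))
  g <- as_igraph(graph)
  nodes <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  names(deg) <- nodes
  m <- length(members)

  stats_of <- function(idx) {
    Asub <- A[idx, idx, drop = FALSE]
    direct <- sum(Asub) / 2
    Aout <- A[idx, -idx, drop = FALSE]
    shared <- Matrix::tcrossprod(Aout)
    indirect <- (sum(shared > 0) - sum(Matrix::diag(shared) > 0)) / 2
    node_deg <- Matrix::rowSums(Asub)
    list(direct = direct, indirect = indirect, node_deg = node_deg)
  }
  midx <- match(members, nodes)
  obs <- stats_of(midx)
  if (m < 2L) {
    node_p <- stats::setNames(rep(1, m), members)
    return(structure(list(direct_stat = 0, indirect_stat = 0,
                          p_direct = 1, p_indirect = 1, node_p = node_p,
                          n_perm = n_perm, bins_merged = FALSE),
                     class = "connectivity_test"))
  }

  bin <- degree_bins(deg)
  bins_merged <- length(unique(bin)) <
    length(unique(cut(deg, breaks = unique(c(-0.5, 0.5,
                                             2^seq(1, max(1, ceiling(log2(max(deg, 1))))),
                                             max(deg, 1))),
                      labels = FALSE, include.lowest = TRUE)))
  candidates <- split(seq_along(nodes), bin[seq_along(nodes)])
  member_bins <- bin[midx]

  b_direct <- 0L; b_indirect <- 0L
  node_exceed <- numeric(m)
  for (b in seq_len(n_perm)) {
    draw <- integer(m)
    for (bb in unique(member_bins)) {
      slots <- which(member_bins == bb)
      pool <- candidates[[as.character(bb)]]
      draw[slots] <- if (length(pool) == 1L) pool else
        sample(pool, length(slots), replace = length(pool) < length(slots))
    }
    ns <- stats_of(draw)
    b_direct <- b_direct + (ns$direct >= obs$direct)
    b_indirect <- b_indirect + (ns$indirect >= obs$indirect)
    node_exceed <- node_exceed + (ns$node_deg >= obs$node_deg)
  }
  structure(list(direct_stat = obs$direct, indirect_stat = obs$indirect,
                 p_direct = perm_pvalue(b_direct, n_perm),
                 p_indirect = perm_pvalue(b_indirect, n_perm),
                 node_p = stats::setNames(perm_pvalue(node_exceed, n_perm),
                                          members),
                 n_perm = n_perm, bins_merged = bins_merged),
            class = "connectivity_test")
}

#' @export
print.connectivity_test <- function(x, ...) {
  cat("Connectivity permutation test (", x$n_perm, " degree-binned draws)\n",
      sep = "")
  cat("  direct edges among members:  ", x$direct_stat,
      "  p =", format.pval(x$p_direct), "\n")
  cat("  pairs with shared neighbour: ", x$indirect_stat,
      "  p =", format.pval(x$p_indirect), "\n")
  invisible(x)
}

#' Drug-target bipartite view of a gene set
#'
#' Restricts a drug-target table to the member genes, builds the
#' bipartite drug/gene edge list, and reports each drug's consensus
#' physiological effect (the modal effect tag; ties are reported as
#' `"ambiguous"`).  Members with no targeting drug are listed
#' separately.
#'
#' @param members Character vector of gene ids.
#' @param drug_targets data.frame with columns `drug`, `gene`, `effect`.
#' @return List: `edges` (drug, gene), `drugs` (drug, n_targets,
#'   consensus_effect), `untargeted` (member genes without a drug).
#' @export
drug_bipartite <- function(members, drug_targets) {
  stopifnot(all(c("drug", "gene", "effect") %in% names(drug_targets)))
  edges <- drug_targets[drug_targets$gene %in% members, , drop = FALSE]
  rownames(edges) <- NULL
  drugs <- if (nrow(edges)) {
    do.call(rbind, lapply(split(edges, edges$drug), function(d) {
      tab <- sort(table(d$effect), decreasing = TRUE)
      consensus <- if (length(tab) > 1L && tab[1] == tab[2]) "ambiguous"
      else names(tab)[1]
      data.frame(drug = d$drug[1], n_targets = length(unique(d$gene)),
                 consensus_effect = consensus, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(drug = character(0), n_targets = integer(0),
               consensus_effect = character(0), stringsAsFactors = FALSE)
  }
  rownames(drugs) <- NULL
  list(edges = edges[, c("drug", "gene", "effect")], drugs = drugs,
       untargeted = setdiff(members, edges$gene))
}
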