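#' Call activated genes for a cell-type context
#'
#' Repeatedly subsamples cells, ranks genes by a one-sided Wilcoxon rank-sum
#' statistic comparing expression in the context's cells against all other
#' cells, and keeps the `top_k` genes of each iteration. Genes appearing in
#' at least `freq_threshold` of the iterations are returned, ordered by mean
#' rank across iterations (ties broken by gene symbol).
#'
#' @param expr Expression data: a list with `counts` (gene x cell matrix,
#'   dense or sparse, with dimnames) and `cell_meta` (data frame with
#'   `cell_id` and `cell_type`), as produced by [synth_expression()] or
#'   [read_expression()].
#' @param context Cell-type label to test.
#' @param top_k Genes kept per iteration (clamped to the number of genes,
#'   with a warning).
#' @param n_iter Number of subsampling iterations.
#' @param freq_threshold Minimum fraction of iterations a gene must appear in.
#' @param subsample_fraction Fraction of cells drawn (without replacement)
#'   per iteration.
#' @param seed Integer seed.
#' @return Character vector of activated genes, most activated first.
#' @export
call_activated_genes <- function(expr, context, top_k = 4000, n_iter = 10,
                                 freq_threshold = 0.9, subsample_fraction = 0.8,
                                 seed = 1) {
  stopifnot(freq_threshold > 0, freq_threshold <= 1,
            subsample_fraction > 0, subsample_fraction <= 1, n_iter >= 1)
  counts <- expr$counts
  meta <- expr$cell_meta
  stopifnot(!is.null(counts), !is.null(meta),
            ncol(counts) == nrow(meta))
  if (!(context %in% meta$cell_type)) stop("context not present: ", context)
  if (sum(meta$cell_type == context) < 2) {
    stop("context has fewer than 2 cells: ", context)
  }
  n_genes <- nrow(counts)
  if (top_k > n_genes) {
    warning("top_k exceeds the number of genes; clamping to ", n_genes)
    top_k <- n_genes
  }
  genes <- rownames(counts)
  # work on a stable cell ordering so results do not depend on column order
  ord <- order(meta$cell_id)
  counts <- as.matrix(counts)[, ord, drop = FALSE]
  is_ctx <- meta$cell_type[ord] == context
  n_cells <- ncol(counts)
  n_sub <- max(2L, floor(subsample_fraction * n_cells))

  set.seed(seed)
  hits <- integer(n_genes)
  rank_sum <- numeric(n_genes)
  for (it in seq_len(n_iter)) {
    sub <- sort(sample.int(n_cells, n_sub))
    in_ctx <- is_ctx[sub]
    if (sum(in_ctx) < 1 || sum(!in_ctx) < 1) next
    x <- counts[, sub, drop = FALSE]
    rk <- t(apply(x, 1, rank))               # ties get average ranks
    n1 <- sum(in_ctx)
    w <- rowSums(rk[, in_ctx, drop = FALSE]) - n1 * (n1 + 1) / 2
    pos <- order(-w, genes)                  # one-sided: larger in context first
    gene_rank <- integer(n_genes)
    gene_rank[pos] <- seq_len(n_genes)
    hits[pos[seq_len(top_k)]] <- hits[pos[seq_len(top_k)]] + 1L
    rank_sum <- rank_sum + gene_rank
  }
  keep <- hits / n_iter >= freq_threshold
  mean_rank <- rank_sum[keep] / n_iter
  genes[keep][order(mean_rank, genes[keep])]
}

#' Build a cell-type-specific protein interaction network
#'
#' Induces the reference network on the given genes and keeps the largest
#' connected component. The network is rejected if the component has fewer
#' than `min_size` proteins, or if none of the genes map into the reference.
#'
#' @param genes Character vector of activated genes.
#' @param ref Reference network: data frame with columns `protein_a`,
#'   `protein_b` (undirected, no self-loops).
#' @param min_size Minimum component size to accept (1000 at atlas scale;
#'   much smaller values are appropriate for synthetic data).
#' @param context_id Optional label stored on the result.
#' @return An object of class `"context_network"` (fields `context_id`,
#'   `nodes`, `edges`), or of class `"context_rejection"` with a `reason`.
#' @export
build_context_network <- function(genes, ref, min_size = 1000, context_id = NA_character_) {
  stopifnot(length(genes) > 0)
  ref_nodes <- unique(c(ref$protein_a, ref$protein_b))
  present <- intersect(genes, ref_nodes)
  if (length(present) == 0) {
    return(structure(list(context_id = context_id, reason = "no overlap"),
                     class = "context_rejection"))
  }
  keep <- ref$protein_a %in% present & ref$protein_b %in% present
  ed <- ref[keep, c("protein_a", "protein_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = present)
  comp <- igraph::components(g)
  nodes <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  if (length(nodes) < min_size) {
    return(structure(list(context_id = context_id,
                          reason = sprintf("largest component has %d proteins (< %d)",
                                           length(nodes), min_size)),
                     class = "context_rejection"))
  }
  sub <- igraph::induced_subgraph(g, nodes)
  ee <- igraph::as_data_frame(sub, what = "edges")
  structure(list(context_id = context_id, nodes = sort(nodes),
                 edges = data.frame(protein_a = ee$from, protein_b = ee$to,
                                    stringsAsFactors = FALSE)),
            class = "context_network")
}

#' Build the cell-type/tissue metagraph
#'
#' Cell-cell edges connect cell-type pairs for which at least one
#' ligand-receptor row is significant at `p_cutoff`; cell-tissue edges attach
#' each cell type to the tissue(s) its cells were sampled from; the tissue
#' set is closed under ancestry up to the ontology root, and tissue-tissue
#' edges are the parent-child links among retained tissues.
#'
#' @param lr_table Data frame (`cell_type_a`, `cell_type_b`, `p_value`).
#' @param cell_meta Data frame with `cell_type` and `tissue` columns (one row
#'   per cell or per type; duplicates are fine).
#' @param ontology_edges Data frame (`child`, `parent`) forming a rooted tree
#'   or DAG over tissues.
#' @param p_cutoff Significance cutoff on the ligand-receptor p-value.
#' @return An object of class `"metagraph"` with fields `cell_types`,
#'   `tissues`, `cc_edges`, `ct_edges`, `tt_edges`, `root`.
#' @export
build_metagraph <- function(lr_table, cell_meta, ontology_edges, p_cutoff = 0.001) {
  stopifnot(all(c("cell_type", "tissue") %in% names(cell_meta)))
  onto_nodes <- unique(c(ontology_edges$child, ontology_edges$parent))
  g <- igraph::graph_from_data_frame(ontology_edges[, c("child", "parent")],
                                     directed = TRUE, vertices = onto_nodes)
  if (!igraph::is_dag(g)) stop("cycle in tissue ontology")
  parent_of <- split(ontology_edges$parent, ontology_edges$child)

  cell_types <- sort(unique(cell_meta$cell_type))
  ct_pairs <- unique(cell_meta[, c("cell_type", "tissue")])
  unknown <- setdiff(ct_pairs$tissue, onto_nodes)
  if (length(unknown) > 0) {
    stop("cell type with unknown tissue: ", paste(unknown, collapse = ", "))
  }

  # ancestor closure of the sampled tissues
  tissues <- unique(ct_pairs$tissue)
  frontier <- tissues
  while (length(frontier) > 0) {
    par <- unique(unlist(parent_of[frontier], use.names = FALSE))
    par <- setdiff(par, tissues)
    tissues <- c(tissues, par)
    frontier <- par
  }
  tissues <- sort(tissues)
  tt_keep <- ontology_edges$child %in% tissues & ontology_edges$parent %in% tissues
  tt_edges <- ontology_edges[tt_keep, c("child", "parent"), drop = FALSE]
  rownames(tt_edges) <- NULL
  roots <- setdiff(tissues, tt_edges$child)

  cc <- lr_table[lr_table$p_value < p_cutoff &
                   lr_table$cell_type_a %in% cell_types &
                   lr_table$cell_type_b %in% cell_types, , drop = FALSE]
  cc_edges <- unique(data.frame(
    cell_type_a = pmin(cc$cell_type_a, cc$cell_type_b),
    cell_type_b = pmax(cc$cell_type_a, cc$cell_type_b),
    stringsAsFactors = FALSE))
  cc_edges <- cc_edges[cc_edges$cell_type_a != cc_edges$cell_type_b, , drop = FALSE]
  rownames(cc_edges) <- NULL

  ct_edges <- unique(ct_pairs)
  names(ct_edges) <- c("cell_type", "tissue")
  rownames(ct_edges) <- NULL

  structure(list(cell_types = cell_types, tissues = tissues,
                 cc_edges = cc_edges, ct_edges = ct_edges, tt_edges = tt_edges,
                 root = roots),
            class = "metagraph")
}
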