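#' Specification of a synthetic single-cell atlas with planted markers
#'
#' Describes a gene-by-cell count matrix in which each cell type has a planted
#' set of activated genes: negative-binomial counts with mean
#' `baseline_mean * activation_fold` inside the type and `baseline_mean`
#' elsewhere. Overdispersed counts (rather than Poisson) are used so that the
#' rank-based activation calling downstream faces realistic noise.
#'
#' @param n_cell_types Number of cell types.
#' @param cells_per_type Cells sampled per type.
#' @param n_genes Total number of genes.
#' @param activated_genes_per_type Planted activated genes per type
#'   (disjoint across types).
#' @param baseline_mean Expected count of a non-activated gene.
#' @param activation_fold Mean multiplier for activated genes (> 1).
#' @param dispersion Negative-binomial shape parameter (`size` in
#'   [stats::rnbinom()]); smaller is more overdispersed.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `"atlas_spec"`.
#' @export
atlas_spec <- function(n_cell_types = 5, cells_per_type = 100, n_genes = 500,
                       activated_genes_per_type = 50, baseline_mean = 2,
                       activation_fold = 5, dispersion = 2, seed = 1) {
  stopifnot(n_cell_types >= 1, cells_per_type >= 1, n_genes >= 1,
            activated_genes_per_type >= 1, baseline_mean >= 0,
            activation_fold > 1, dispersion > 0)
  if (activated_genes_per_type * n_cell_types > n_genes) {
    stop("infeasible planting: activated_genes_per_type * n_cell_types > n_genes")
  }
  structure(list(n_cell_types = n_cell_types, cells_per_type = cells_per_type,
                 n_genes = n_genes,
                 activated_genes_per_type = activated_genes_per_type,
                 baseline_mean = baseline_mean, activation_fold = activation_fold,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "atlas_spec")
}

#' Generate a synthetic expression atlas with planted activated genes
#'
#' @param spec An [atlas_spec()].
#' @return A list with `counts` (sparse gene x cell `dgCMatrix`), `genes`,
#'   `cell_meta` (data frame with `cell_id`, `cell_type`, `tissue`) and
#'   `planted` (named list: cell type -> character vector of planted genes).
#' @export
synth_expression <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  types <- sprintf("celltype_%d", seq_len(spec$n_cell_types))
  n_cells <- spec$n_cell_types * spec$cells_per_type
  cell_type <- rep(types, each = spec$cells_per_type)
  cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  # two cell types per tissue keeps the type -> tissue map many-to-one
  tissue <- sprintf("tissue_%d", ceiling(match(cell_type, types) / 2))

  planted_idx <- split(seq_len(spec$activated_genes_per_type * spec$n_cell_types),
                       rep(seq_len(spec$n_cell_types), each = spec$activated_genes_per_type))
  planted <- lapply(planted_idx, function(i) genes[i])
  names(planted) <- types

  mu <- matrix(spec$baseline_mean, nrow = spec$n_genes, ncol = n_cells)
  for (k in seq_len(spec$n_cell_types)) {
    mu[planted_idx[[k]], cell_type == types[k]] <-
      spec$baseline_mean * spec$activation_fold
  }
  counts <- matrix(stats::rnbinom(length(mu), size = spec$dispersion, mu = mu),
                   nrow = spec$n_genes,
                   dimnames = list(genes, cell_id))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       genes = genes,
       cell_meta = data.frame(cell_id = cell_id, cell_type = cell_type,
                              tissue = tissue, stringsAsFactors = FALSE),
       planted = planted)
}

#' Specification of synthetic multi-scale networks
#'
#' Each cell-type context is a stochastic block model on named proteins; a
#' `shared_fraction` of protein identities recurs in every context (with the
#' same planted block, so cross-context similarity structure is well
#' defined). The tissue part of the metagraph is a random rooted tree of the
#' requested depth; each context attaches to one leaf, and cell-cell
#' communication edges connect contexts whose leaves are siblings.
#'
#' @param n_contexts Number of cell-type contexts.
#' @param proteins_per_context Proteins per context before largest-component
#'   extraction.
#' @param shared_fraction Fraction of each context's proteins drawn from a
#'   shared pool present in all contexts.
#' @param within_block_p,between_block_p Stochastic-block-model edge
#'   probabilities (`within_block_p > between_block_p`).
#' @param n_blocks Planted blocks per context.
#' @param tissue_tree_depth Depth of the random tissue tree.
#' @param n_tissues Total tissue nodes (default `4 * n_contexts`).
#' @param seed Integer seed.
#' @return An object of class `"graph_spec"`.
#' @export
graph_spec <- function(n_contexts = 3, proteins_per_context = 200,
                       shared_fraction = 0.5, within_block_p = 0.15,
                       between_block_p = 0.02, n_blocks = 4,
                       tissue_tree_depth = 3, n_tissues = 4 * n_contexts,
                       seed = 1) {
  stopifnot(n_contexts >= 1, proteins_per_context >= n_blocks,
            shared_fraction >= 0, shared_fraction <= 1,
            within_block_p > between_block_p, between_block_p >= 0,
            within_block_p <= 1, n_blocks >= 1, tissue_tree_depth >= 1,
            n_tissues >= tissue_tree_depth + 1)
  structure(list(n_contexts = n_contexts,
                 proteins_per_context = proteins_per_context,
                 shared_fraction = shared_fraction,
                 within_block_p = within_block_p,
                 between_block_p = between_block_p, n_blocks = n_blocks,
                 tissue_tree_depth = tissue_tree_depth,
                 n_tissues = n_tissues, seed = as.integer(seed)),
            class = "graph_spec")
}

# Sample SBM edges among `nodes` with block labels `blocks`.
.sbm_edges <- function(nodes, blocks, p_in, p_out) {
  n <- length(nodes)
  if (n < 2) return(data.frame(protein_a = character(0), protein_b = character(0)))
  pr <- utils::combn(n, 2)
  same <- blocks[pr[1, ]] == blocks[pr[2, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pr)) < p
  data.frame(protein_a = nodes[pr[1, keep]], protein_b = nodes[pr[2, keep]],
             stringsAsFactors = FALSE)
}

#' Generate synthetic context networks, tissue tree and metagraph inputs
#'
#' @param spec A [graph_spec()].
#' @return A list with:
#'   * `contexts`: named list of context networks (each with `nodes`, `edges`);
#'   * `planted`: named list mapping each context to a named integer vector of
#'     planted block labels on the retained nodes;
#'   * `ontology`: data frame (`child`, `parent`) for the tissue tree;
#'   * `context_tissue`: data frame (`cell_type`, `tissue`) attaching each
#'     context to its leaf tissue;
#'   * `lr_table`: data frame (`cell_type_a`, `cell_type_b`, `p_value`), with
#'     sub-threshold p-values exactly for sibling-leaf context pairs;
#'   * `metagraph`: the assembled [metagraph] over these inputs.
#' @export
synth_multiscale_graph <- function(spec) {
  stopifnot(inherits(spec, "graph_spec"))
  set.seed(spec$seed)
  ctx <- sprintf("celltype_%d", seq_len(spec$n_contexts))

  n_shared <- round(spec$shared_fraction * spec$proteins_per_context)
  shared <- if (n_shared > 0) sprintf("P%05d", seq_len(n_shared)) else character(0)
  shared_block <- if (n_shared > 0)
    stats::setNames(rep_len(seq_len(spec$n_blocks), n_shared)[sample.int(n_shared)], shared)
  else stats::setNames(integer(0), character(0))

  next_id <- n_shared
  contexts <- list()
  planted <- list()
  for (ci in ctx) {
    n_uniq <- spec$proteins_per_context - n_shared
    uniq <- if (n_uniq > 0) sprintf("P%05d", next_id + seq_len(n_uniq)) else character(0)
    next_id <- next_id + n_uniq
    nodes <- c(shared, uniq)
    blocks <- c(shared_block,
                stats::setNames(rep_len(seq_len(spec$n_blocks), n_uniq)[sample.int(max(n_uniq, 1L))][seq_len(n_uniq)], uniq))
    ed <- .sbm_edges(nodes, blocks[nodes], spec$within_block_p, spec$between_block_p)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
    comp <- igraph::components(g)
    keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    sub <- igraph::induced_subgraph(g, keep)
    ee <- igraph::as_data_frame(sub, what = "edges")
    contexts[[ci]] <- list(context_id = ci, nodes = sort(keep),
                           edges = data.frame(protein_a = ee$from, protein_b = ee$to,
                                              stringsAsFactors = FALSE))
    planted[[ci]] <- blocks[sort(keep)]
  }

  tree <- .synth_tissue_tree(spec$n_tissues, spec$tissue_tree_depth, spec$n_contexts)
  context_tissue <- data.frame(cell_type = ctx, tissue = tree$context_leaves,
                               stringsAsFactors = FALSE)

  # cell-cell communication: significant LR p-value iff the two contexts'
  # leaves are siblings in the tissue tree (share a parent)
  parent_of <- stats::setNames(tree$ontology$parent, tree$ontology$child)
  lr <- NULL
  if (spec$n_contexts >= 2) {
    pr <- utils::combn(spec$n_contexts, 2)
    sib <- parent_of[tree$context_leaves[pr[1, ]]] == parent_of[tree$context_leaves[pr[2, ]]]
    p_value <- ifelse(sib, stats::runif(ncol(pr), 0, 5e-4),
                      stats::runif(ncol(pr), 0.01, 1))
    lr <- data.frame(cell_type_a = ctx[pr[1, ]], cell_type_b = ctx[pr[2, ]],
                     p_value = p_value, stringsAsFactors = FALSE)
  } else {
    lr <- data.frame(cell_type_a = character(0), cell_type_b = character(0),
                     p_value = numeric(0))
  }

  cell_meta <- data.frame(cell_id = ctx, cell_type = ctx,
                          tissue = context_tissue$tissue, stringsAsFactors = FALSE)
  mg <- build_metagraph(lr, cell_meta, tree$ontology, p_cutoff = 0.001)

  list(contexts = contexts, planted = planted, ontology = tree$ontology,
       context_tissue = context_tissue, lr_table = lr, metagraph = mg)
}

# Random rooted tree: a backbone path fixes the depth, remaining interior
# nodes attach to random parents above the bottom level, and the last
# n_contexts nodes are dedicated context leaves grouped under few parents so
# that sibling pairs (hence cell-cell edges) exist.
.synth_tissue_tree <- function(n_tissues, depth, n_contexts) {
  lab <- sprintf("tissue_%02d", seq_len(n_tissues))
  level <- integer(n_tissues); level[1] <- 0L
  parent <- rep(NA_character_, n_tissues)
  n_backbone <- min(depth, n_tissues - 1L)
  for (i in seq_len(n_backbone)) {
    parent[i + 1L] <- lab[i]; level[i + 1L] <- i
  }
  n_leaf <- min(n_contexts, max(0L, n_tissues - n_backbone - 1L))
  n_interior <- n_tissues - n_backbone - 1L - n_leaf
  at <- n_backbone + 1L
  for (i in seq_len(n_interior)) {
    cand <- which(level[seq_len(at)] < depth)
    pk <- cand[sample.int(length(cand), 1L)]
    at <- at + 1L
    parent[at] <- lab[pk]; level[at] <- level[pk] + 1L
  }
  # context leaves: grouped under at most ceil(n_contexts / 2) parents
  leaf_parents <- character(0)
  if (n_leaf > 0) {
    cand <- which(level[seq_len(at)] < depth)
    k <- min(length(cand), max(1L, ceiling(n_contexts / 2)))
    pool <- cand[sample.int(length(cand), k)]
    leaf_parents <- lab[pool[rep_len(seq_len(k), n_leaf)]]
    for (i in seq_len(n_leaf)) {
      at <- at + 1L
      parent[at] <- leaf_parents[i]
      level[at] <- level[match(leaf_parents[i], lab)] + 1L
    }
  }
  is_child <- !is.na(parent)
  ontology <- data.frame(child = lab[is_child], parent = parent[is_child],
                         stringsAsFactors = FALSE)
  # attach contexts to the dedicated leaves (recycled if very few tissues)
  leaves <- if (n_leaf > 0) lab[(n_tissues - n_leaf + 1L):n_tissues] else lab[n_tissues]
  context_leaves <- rep_len(leaves, n_contexts)
  list(ontology = ontology, context_leaves = context_leaves)
}

#' Generate planted therapeutic-target labels
#'
#' Positives are drawn preferentially (with probability `pref`) from one
#' planted block within the given contexts, so that context-specific
#' embeddings carry signal for the fine-tuning stage; negatives are drawn
#' uniformly from the remaining proteins.
#'
#' @param graph Output of [synth_multiscale_graph()].
#' @param planted_contexts Character vector of context ids holding the signal.
#' @param n_pos,n_neg Numbers of positive and negative labels.
#' @param seed Integer seed.
#' @param community Planted block index carrying the positives (default 1).
#' @param pref Probability that a positive is drawn from the planted block.
#' @return A list with `labels` (data frame `protein`, `label`),
#'   `planted_contexts` and `community`.
#' @export
synth_target_labels <- function(graph, planted_contexts, n_pos, n_neg, seed = 1,
                                community = 1L, pref = 0.9) {
  stopifnot(length(planted_contexts) >= 1,
            all(planted_contexts %in% names(graph$contexts)))
  set.seed(seed)
  all_prot <- sort(unique(unlist(lapply(graph$contexts, `[[`, "nodes"))))
  if (n_pos + n_neg > length(all_prot)) {
    stop("n_pos + n_neg exceeds the number of available proteins")
  }
  in_comm <- sort(unique(unlist(lapply(graph$planted[planted_contexts], function(b) {
    names(b)[b == community]
  }))))
  pos <- character(0)
  if (n_pos > 0) {
    n_from_comm <- min(length(in_comm), sum(stats::runif(n_pos) < pref))
    pos <- sample(in_comm, n_from_comm)
    if (n_pos > n_from_comm) {
      pos <- c(pos, sample(setdiff(all_prot, pos), n_pos - n_from_comm))
    }
  }
  neg <- if (n_neg > 0) sample(setdiff(all_prot, pos), n_neg) else character(0)
  labels <- data.frame(protein = c(pos, neg),
                       label = rep(c(1L, 0L), c(length(pos), length(neg))),
                       stringsAsFactors = FALSE)
  list(labels = labels, planted_contexts = planted_contexts, community = community)
}
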