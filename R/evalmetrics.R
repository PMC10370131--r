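# Quantitative evaluation procedures: ranking metrics, embedding-similarity
# analyses, tissue-hierarchy retrieval, permutation tests, neighborhood
# enrichment, and contextualization of external (structure-based) protein
# vectors.

#' Average Precision and Recall at K
#'
#' `(1/r) * sum_{k<=K} Precision@k * rel(k)`, where `r` is the number of
#' relevant items in the top K; defined as 0 when `r = 0`.
#'
#' @param relevance Binary vector, ranked best-first.
#' @param K Cutoff (`1 <= K <= length(relevance)`).
#' @return A value in `[0, 1]`.
#' @export
apr_at_k <- function(relevance, K) {
  if (K < 1 || K > length(relevance)) stop("K out of range")
  rel <- as.numeric(relevance[seq_len(K)])
  r <- sum(rel)
  if (r == 0) return(0)
  prec <- cumsum(rel) / seq_len(K)
  sum(prec * rel) / r
}

# Row-normalized matrix for cosine computations; zero rows map to zero
# vectors (their cosine with anything is reported as 0) with a warning.
.row_normalize <- function(X) {
  nrm <- sqrt(rowSums(X * X))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " zero vector(s); cosine with them reported as 0")
    nrm[zero] <- 1
  }
  X / nrm
}

#' Within- versus cross-context embedding similarity
#'
#' Cosine similarities over all pairs of protein embeddings in the same
#' context and over all pairs in different contexts (pairs of the same
#' protein identity are excluded from the cross-context set), with a
#' two-sample Kolmogorov-Smirnov comparison of the two distributions.
#'
#' @param embeddings Numeric matrix, one row per (protein, context) node.
#' @param context Context label per row.
#' @param protein Optional protein identity per row (enables the
#'   same-protein exclusion).
#' @return List with `within`, `cross` (similarity vectors),
#'   `median_within`, `median_cross`, `gap`, `ks_stat`, `ks_p`.
#' @export
similarity_gap <- function(embeddings, context, protein = NULL) {
  stopifnot(length(unique(context)) >= 2)
  Xn <- .row_normalize(as.matrix(embeddings))
  S <- Xn %*% t(Xn)
  n <- nrow(S)
  same_ctx <- outer(context, context, "==")
  up <- upper.tri(S)
  singleton <- names(table(context))[table(context) < 2]
  keep_within <- up & same_ctx
  if (length(singleton)) {
    keep_within <- keep_within & !(context[row(S)] %in% singleton)
  }
  keep_cross <- up & !same_ctx
  if (!is.null(protein)) {
    keep_cross <- keep_cross & outer(protein, protein, "!=")
  }
  within <- S[keep_within]
  cross <- S[keep_cross]
  ks <- suppressWarnings(stats::ks.test(within, cross))
  list(within = within, cross = cross,
       median_within = stats::median(within), median_cross = stats::median(cross),
       gap = stats::median(within) - stats::median(cross),
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Correlation between context multiplicity and cross-context self-similarity
#'
#' For each protein present in at least two contexts: the mean pairwise
#' cosine similarity among its own context-specific vectors, Spearman
#' correlated against its number of contexts.
#'
#' @param embeddings Numeric matrix, one row per (protein, context) node.
#' @param protein Protein identity per row.
#' @return List with `rho`, `n_proteins`, `table` (per-protein multiplicity
#'   and mean self-similarity), and `tied` (TRUE when ranks were fully
#'   degenerate and `rho` is reported as 0).
#' @export
multiplicity_correlation <- function(embeddings, protein) {
  Xn <- .row_normalize(as.matrix(embeddings))
  rows <- split(seq_along(protein), protein)
  rows <- rows[vapply(rows, length, integer(1)) >= 2]
  if (length(rows) < 3) stop("need at least 3 proteins in >= 2 contexts")
  tab <- do.call(rbind, lapply(names(rows), function(p) {
    ii <- rows[[p]]
    S <- Xn[ii, , drop = FALSE] %*% t(Xn[ii, , drop = FALSE])
    data.frame(protein = p, n_contexts = length(ii),
               mean_self_similarity = mean(S[upper.tri(S)]))
  }))
  tied <- stats::sd(tab$n_contexts) == 0 || stats::sd(tab$mean_self_similarity) == 0
  rho <- if (tied) 0 else
    suppressWarnings(stats::cor(tab$n_contexts, tab$mean_self_similarity,
                                method = "spearman"))
  list(rho = rho, n_proteins = nrow(tab), table = tab, tied = tied)
}

#' Ontology tree utilities
#'
#' `ontology_tree()` validates a child-parent edge table into a rooted tree;
#' `tissue_ontology_distance()` returns the sum of the two nodes' shortest
#' path lengths to their lowest common ancestor.
#'
#' @param edges Data frame with `child` and `parent`.
#' @return `ontology_tree`: an object of class `"ontology_tree"`.
#' @export
ontology_tree <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  if (anyDuplicated(edges$child)) stop("a child has two parents; not a tree")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  if (!igraph::is_dag(g)) stop("ontology edges contain a cycle")
  root <- setdiff(nodes, edges$child)
  if (length(root) != 1) stop("expected exactly one root, found ", length(root))
  structure(list(nodes = nodes,
                 parent = stats::setNames(edges$parent, edges$child),
                 root = root),
            class = "ontology_tree")
}

.ancestor_path <- function(tree, t) {
  path <- t; depth <- 0
  while (t != tree$root) {
    t <- tree$parent[[t]]
    path <- c(path, t)
  }
  path
}

#' @param t1,t2 Tissue labels present in the tree.
#' @param tree An [ontology_tree()].
#' @rdname ontology_tree
#' @export
tissue_ontology_distance <- function(t1, t2, tree) {
  if (!(t1 %in% tree$nodes) || !(t2 %in% tree$nodes)) {
    stop("unknown tissue: ", paste(setdiff(c(t1, t2), tree$nodes), collapse = ", "))
  }
  p1 <- .ancestor_path(tree, t1)
  p2 <- .ancestor_path(tree, t2)
  lca <- p1[p1 %in% p2][1]
  (match(lca, p1) - 1L) + (match(lca, p2) - 1L)
}

#' Zero-shot retrieval of the tissue hierarchy from embeddings
#'
#' Correlates pairwise cosine distances between tissue embeddings with
#' pairwise ontology distances (Spearman), compares the embedding distances
#' against those of standard-normal random vectors of equal count and
#' dimension (two-sample Kolmogorov-Smirnov), and builds a null Spearman
#' distribution by shuffling the tissue identities of the tree.
#'
#' @param tissue_embeddings Matrix with tissue rownames.
#' @param tree An [ontology_tree()] over (at least) those tissues.
#' @param n_shuffles Shuffled-tree null replicates (default 10).
#' @param seed Integer seed for the random vectors and shuffles.
#' @return List with `rho`, `rho_p`, `ks_stat`, `ks_p`, `null_rho`.
#' @export
hierarchy_retrieval <- function(tissue_embeddings, tree, n_shuffles = 10, seed = 1) {
  tiss <- rownames(tissue_embeddings)
  stopifnot(length(tiss) >= 4, all(tiss %in% tree$nodes))
  set.seed(seed)
  Xn <- .row_normalize(as.matrix(tissue_embeddings))
  S <- Xn %*% t(Xn)
  up <- upper.tri(S)
  emb_dist <- (1 - S)[up]
  onto <- outer(tiss, tiss, Vectorize(function(a, b) tissue_ontology_distance(a, b, tree)))
  onto_dist <- onto[up]
  ct <- suppressWarnings(stats::cor.test(emb_dist, onto_dist, method = "spearman"))
  R <- matrix(stats::rnorm(length(tissue_embeddings)), nrow(tissue_embeddings))
  Rn <- .row_normalize(R)
  rand_dist <- (1 - Rn %*% t(Rn))[up]
  ks <- suppressWarnings(stats::ks.test(emb_dist, rand_dist))
  null_rho <- vapply(seq_len(n_shuffles), function(i) {
    perm <- sample(tiss)
    onto_perm <- onto[match(perm, tiss), match(perm, tiss)]
    suppressWarnings(stats::cor(emb_dist, onto_perm[up], method = "spearman"))
  }, numeric(1))
  list(rho = unname(ct$estimate), rho_p = ct$p.value,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value, null_rho = null_rho)
}

#' One-sided permutation test for a binding-score gap
#'
#' The observed gap is `mean(binding) - mean(nonbinding)`; scores are pooled
#' and repeatedly re-partitioned at the original sizes, and the p-value is
#' the fraction of iterations whose permuted gap is at least the observed
#' one.
#'
#' @param binding,nonbinding Numeric score vectors.
#' @param n_iter Permutation iterations (default 100000).
#' @param seed Integer seed.
#' @param plus_one Use the (b+1)/(n+1) estimator instead of the raw
#'   fraction.
#' @return List with `gap`, `p`, `n_iter`.
#' @export
score_gap_permutation_test <- function(binding, nonbinding, n_iter = 1e5,
                                       seed = 1, plus_one = FALSE) {
  stopifnot(length(binding) >= 1, length(nonbinding) >= 1)
  set.seed(seed)
  pool <- c(binding, nonbinding)
  n <- length(binding); m <- length(nonbinding)
  gap <- mean(binding) - mean(nonbinding)
  tot <- sum(pool)
  hits <- 0L
  for (i in seq_len(n_iter)) {
    ii <- sample.int(n + m, n)
    g <- sum(pool[ii]) / n - (tot - sum(pool[ii])) / m
    if (g >= gap - 1e-12) hits <- hits + 1L
  }
  p <- if (plus_one) (hits + 1) / (n_iter + 1) else hits / n_iter
  list(gap = gap, p = p, n_iter = n_iter)
}

#' Neighborhood enrichment on the embedding-similarity graph
#'
#' Builds an unweighted graph by thresholding pairwise cosine similarity,
#' keeps the largest connected component, defines each node's neighborhood
#' as the nodes within a graph-distance radius (a quantile of the pairwise
#' shortest-path distance distribution), and tests each neighborhood for
#' over-representation of the binary label with the hypergeometric test,
#' Benjamini-Hochberg corrected.
#'
#' @param embeddings Numeric matrix (one row per node).
#' @param labels Binary vector (1 = labeled).
#' @param sim_threshold Cosine similarity threshold (default 0.3).
#' @param radius Distance quantile defining the neighborhood (default 0.15).
#' @param alpha Significance cutoff on the adjusted p-value (default 0.05).
#' @return List of class `"enrichment_result"`: `table` (per retained node:
#'   neighborhood size and label count, `p`, `p_adj`, `nes` =
#'   `-log10(p_adj)`, `significant`), `n_enriched`, `kept` (indices of the
#'   retained component), `radius_used`.
#' @export
spatial_enrichment <- function(embeddings, labels, sim_threshold = 0.3,
                               radius = 0.15, alpha = 0.05) {
  stopifnot(length(labels) == nrow(embeddings), any(labels == 1))
  Xn <- .row_normalize(as.matrix(embeddings))
  S <- Xn %*% t(Xn)
  A <- S >= sim_threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  kept <- which(comp$membership == which.max(comp$csize))
  if (length(kept) < 2) stop("similarity graph has an empty largest component")
  sub <- igraph::induced_subgraph(g, kept)
  D <- igraph::distances(sub)
  r <- stats::quantile(D[upper.tri(D)][is.finite(D[upper.tri(D)])], radius)
  lab <- labels[kept]
  N <- length(kept); K <- sum(lab == 1)
  pvals <- vapply(seq_len(N), function(i) {
    nb <- which(D[i, ] <= r)
    k <- sum(lab[nb] == 1)
    stats::phyper(k - 1, K, N - K, length(nb), lower.tail = FALSE)
  }, numeric(1))
  nb_size <- vapply(seq_len(N), function(i) sum(D[i, ] <= r), integer(1))
  nb_lab <- vapply(seq_len(N), function(i) sum(lab[D[i, ] <= r] == 1), integer(1))
  p_adj <- stats::p.adjust(pvals, method = "BH")
  tab <- data.frame(node = kept, neighborhood_size = nb_size,
                    n_labeled = nb_lab, p = pvals, p_adj = p_adj,
                    nes = -log10(pmax(p_adj, .Machine$double.xmin)),
                    significant = p_adj < alpha)
  structure(list(table = tab, n_enriched = sum(tab$significant),
                 kept = kept, radius_used = unname(r), alpha = alpha),
            class = "enrichment_result")
}

#' Contextualize an external protein representation
#'
#' Concatenates an external (e.g. structure-based) protein vector with the
#' model's cell-type-specific representation of the protein, per context;
#' the context-free counterpart concatenates it with the elementwise mean
#' of the protein's representations across all of its contexts.
#'
#' @param external Numeric vector (the external representation).
#' @param fit A fitted [contextppi] model or its `embeddings` list.
#' @param protein Protein identity.
#' @return List with `per_context` (named list of combined vectors) and
#'   `context_free` (one combined vector).
#' @export
contextualize_external <- function(external, fit, protein) {
  emb <- if (inherits(fit, "contextppi")) fit$embeddings else fit
  idx <- emb$index
  rows <- idx[idx$protein == protein, , drop = FALSE]
  if (!nrow(rows)) stop("unknown protein: ", protein)
  vecs <- lapply(seq_len(nrow(rows)), function(i) {
    c(external, emb$protein[rows$node_id[i], ])
  })
  names(vecs) <- rows$context
  list(per_context = vecs,
       context_free = c(external, colMeans(emb$protein[rows$node_id, , drop = FALSE])))
}

#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity (0 for zero vectors, with a warning).
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("cosine of a zero vector reported as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Median-pool a patch matrix into a fixed-length vector
#'
#' Keeps the `k_select` rows with the highest site scores and takes the
#' median across the columns of each kept row, yielding a vector of length
#' `k_select` (200 for the structure-surface patch matrices this mirrors).
#'
#' @param patches Numeric matrix (patches x features).
#' @param site_scores Per-row score ranking the patches.
#' @param k_select Number of rows to keep.
#' @return Numeric vector of length `k_select`.
#' @export
median_pool_patches <- function(patches, site_scores, k_select = 200) {
  patches <- as.matrix(patches)
  stopifnot(length(site_scores) == nrow(patches))
  if (nrow(patches) < k_select) stop("fewer patch rows than k_select")
  keep <- order(-site_scores)[seq_len(k_select)]
  apply(patches[keep, , drop = FALSE], 1, stats::median)
}
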