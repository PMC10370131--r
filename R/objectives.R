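#' Bilinear edge decoder
#'
#' Scores an edge of type i between embeddings `z_u` and `z_v` as the
#' diagonal bilinear form `sum_k z_u[k] * r_i[k] * z_v[k]`, mapped to a
#' probability through the logistic function. The decoder is symmetric in
#' its two node arguments.
#'
#' @param z_u,z_v Numeric vectors (or matrices with one row per edge).
#' @param r_i Relation embedding vector of the same dimension.
#' @return Probability (vector when matrices are supplied).
#' @export
decode_edge <- function(z_u, r_i, z_v) {
  if (is.null(dim(z_u))) z_u <- matrix(z_u, nrow = 1)
  if (is.null(dim(z_v))) z_v <- matrix(z_v, nrow = 1)
  r_i <- as.numeric(r_i)
  if (ncol(z_u) != length(r_i) || ncol(z_v) != length(r_i)) {
    stop("dimension mismatch between node and relation embeddings")
  }
  score <- rowSums(z_u * matrix(r_i, nrow(z_u), length(r_i), byrow = TRUE) * z_v)
  stats::plogis(score)
}

#' Binary cross-entropy over predicted edge probabilities
#'
#' Mean binary cross-entropy; probabilities are clipped away from 0 and 1 by
#' `eps` for numerical safety.
#'
#' @param probabilities Numeric vector in (0, 1).
#' @param labels 0/1 vector of the same length.
#' @param eps Clipping constant.
#' @return Nonnegative scalar.
#' @export
link_loss <- function(probabilities, labels, eps = 1e-12) {
  stopifnot(length(probabilities) == length(labels))
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Center loss over contextualized protein embeddings
#'
#' Mean squared Euclidean distance between each (protein, context) embedding
#' and its cell type's center, normalized by the number of embeddings.
#'
#' @param z Matrix of embeddings (rows = protein-context pairs).
#' @param context Character or integer vector assigning each row to a cell
#'   type.
#' @param centers Matrix of centers with rownames (or rows indexed by the
#'   integer contexts).
#' @return Nonnegative scalar.
#' @export
center_loss <- function(z, context, centers) {
  ci <- if (is.character(context)) match(context, rownames(centers)) else as.integer(context)
  if (anyNA(ci) || any(ci < 1) || any(ci > nrow(centers))) {
    stop("missing center for some context")
  }
  d <- z - centers[ci, , drop = FALSE]
  sum(d * d) / nrow(z)
}

#' Composite training loss
#'
#' `theta * ppi + lambda * cellid + (1 - theta) * celltype + tissue`, where
#' the cell-type term is the sum of the cell-cell and cell-tissue link
#' losses and the tissue term the sum of the tissue-tissue and tissue-cell
#' link losses.
#'
#' @param ppi,cellid,celltype,tissue Nonnegative component losses.
#' @param theta,lambda Weights in `[0, 1]`.
#' @return Scalar.
#' @export
total_loss <- function(ppi, cellid, celltype, tissue, theta = 0.5, lambda = 0.1) {
  stopifnot(theta >= 0, theta <= 1, lambda >= 0, lambda <= 1,
            ppi >= 0, cellid >= 0, celltype >= 0, tissue >= 0)
  theta * ppi + lambda * cellid + (1 - theta) * celltype + tissue
}

# ---- tape-side loss construction (used by the trainer) ----

# BCE in logit form: softplus(-s) + (1 - y) * s; numerically stable, equal
# to -[y log p + (1-y) log(1-p)] at p = plogis(s). The training objective
# uses the summed form of the printed equations by default; the mean form
# is available for size-balanced contexts.
.ad_bce_logits <- function(tp, scores, labels, reduction = "sum") {
  y <- ad_leaf(tp, matrix(1 - labels, ncol = 1))
  terms <- ad_add(tp, ad_softplus(tp, ad_scale(tp, scores, -1)),
                  ad_mul(tp, scores, y))
  if (reduction == "mean") ad_mean(tp, terms) else ad_sum(tp, terms)
}

# Bilinear scores for node-id pairs within one embedding matrix (or across
# two, for cell-tissue edges).
.ad_edge_scores <- function(tp, Zl, Zr, pairs, rel) {
  zi <- ad_rows(tp, Zl, pairs[, 1])
  zj <- ad_rows(tp, Zr, pairs[, 2])
  ad_mm(tp, ad_mul(tp, zi, zj), rel)
}

# Assemble every loss component on the tape. Returns nodes plus the scalar
# component values for logging.
.ad_total_loss <- function(tp, fw, graph, params, config, split, P,
                           neg_seed_offset = 0L) {
  ctx_names <- names(graph$contexts)
  nC <- length(ctx_names)
  mg <- graph$metagraph

  # protein-protein link prediction on the train split, negatives resampled
  pos_all <- list(); neg_all <- list()
  for (ci in ctx_names) {
    pos <- split[[ci]]$train
    if (nrow(pos) == 0) next
    neg <- sample_negatives(graph, pos, ci)
    pos_all[[ci]] <- pos; neg_all[[ci]] <- neg
  }
  pairs <- do.call(rbind, c(pos_all, neg_all))
  labels <- c(rep(1, sum(vapply(pos_all, nrow, integer(1)))),
              rep(0, sum(vapply(neg_all, nrow, integer(1)))))
  red <- if (is.null(config$loss_reduction)) "sum" else config$loss_reduction
  l_ppi <- .ad_bce_logits(tp, .ad_edge_scores(tp, fw$Zp, fw$Zp, pairs, P("rel_pp")),
                          labels, red)

  # cell-type identity: center loss on proteins incident to train edges
  train_nodes <- sort(unique(unlist(lapply(pos_all, as.integer))))
  ctr_idx <- fw$ctx_of_node[train_nodes]
  zd <- ad_sub(tp, ad_rows(tp, fw$Zp, train_nodes), ad_rows(tp, P("centers"), ctr_idx))
  l_cid <- ad_sum(tp, ad_mul(tp, zd, zd))
  if (red == "mean") l_cid <- ad_scale(tp, l_cid, 1 / length(train_nodes))

  # metagraph link prediction, 1:1 negatives within each node-type pair
  meta_bce <- function(Zl, Zr, pos_pairs, n_left, n_right, rel, bipartite) {
    if (nrow(pos_pairs) == 0) return(NULL)
    neg <- .meta_negatives(pos_pairs, n_left, n_right, bipartite)
    pp <- rbind(pos_pairs, neg)
    yy <- rep(c(1, 0), c(nrow(pos_pairs), nrow(neg)))
    .ad_bce_logits(tp, .ad_edge_scores(tp, Zl, Zr, pp, rel), yy, red)
  }
  zero <- function() ad_leaf(tp, matrix(0, 1, 1))
  l_cc <- l_ct <- l_tt <- l_tc <- NULL
  if (config$use_metagraph) {
    cc_pairs <- cbind(fw$cell_ids[mg$cc_edges$cell_type_a],
                      fw$cell_ids[mg$cc_edges$cell_type_b])
    ct_pairs <- cbind(fw$cell_ids[mg$ct_edges$cell_type],
                      fw$tissue_ids[mg$ct_edges$tissue])
    tt_pairs <- cbind(fw$tissue_ids[mg$tt_edges$child],
                      fw$tissue_ids[mg$tt_edges$parent])
    l_cc <- meta_bce(fw$Zc, fw$Zc, cc_pairs, nC, nC, P("rel_cc"), FALSE)
    l_ct <- meta_bce(fw$Zc, fw$Zt, ct_pairs, nC, length(mg$tissues), P("rel_ct"), TRUE)
    l_tt <- meta_bce(fw$Zt, fw$Zt, tt_pairs, length(mg$tissues), length(mg$tissues),
                     P("rel_tt"), FALSE)
    # the tissue-cell term shares the cell-tissue pairs, decoded with its
    # own relation vector from the tissue side
    l_tc <- meta_bce(fw$Zt, fw$Zc, ct_pairs[, c(2, 1), drop = FALSE],
                     length(mg$tissues), nC, P("rel_tc"), TRUE)
  }
  if (is.null(l_cc)) l_cc <- zero()
  if (is.null(l_ct)) l_ct <- zero()
  if (is.null(l_tt)) l_tt <- zero()
  if (is.null(l_tc)) l_tc <- zero()

  l_celltype <- ad_add(tp, l_cc, l_ct)
  l_tissue <- ad_add(tp, l_tt, l_tc)
  total <- ad_add(tp, ad_add(tp, ad_scale(tp, l_ppi, config$theta),
                             ad_scale(tp, l_cid, config$lambda)),
                  ad_add(tp, ad_scale(tp, l_celltype, 1 - config$theta), l_tissue))
  list(total = total,
       parts = c(l_ppi = l_ppi$value[1], l_cellid = l_cid$value[1],
                 l_cc = l_cc$value[1], l_ct = l_ct$value[1],
                 l_tt = l_tt$value[1], l_tc = l_tc$value[1],
                 total = total$value[1]))
}

# 1:1 negatives among (left, right) index pairs that are not positives; one
# corrupted right endpoint per positive. Positives whose left endpoint has
# no non-positive partner (tiny metagraphs) contribute no negative.
.meta_negatives <- function(pos_pairs, n_left, n_right, bipartite) {
  key <- paste(pos_pairs[, 1], pos_pairs[, 2])
  if (!bipartite) key <- c(key, paste(pos_pairs[, 2], pos_pairs[, 1]))
  rows <- list()
  for (k in seq_len(nrow(pos_pairs))) {
    a <- pos_pairs[k, 1]
    cand <- seq_len(n_right)
    if (!bipartite) cand <- cand[cand != a]
    cand <- cand[!(paste(a, cand) %in% key)]
    if (length(cand) == 0) next
    rows[[length(rows) + 1L]] <- c(a, cand[sample.int(length(cand), 1L)])
  }
  if (length(rows) == 0) return(matrix(0L, 0, 2))
  do.call(rbind, rows)
}
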