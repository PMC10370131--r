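# The multi-scale attention model.
#
# Per layer: (i) GATv2-style attention inside every cell-type-specific
# protein network; (ii) an attention bridge that pools protein embeddings
# into their cell type with learned importances gamma; (iii) GATv2 attention
# on the metagraph per edge type (cc, ct, tc, tt) combined by a semantic
# attention beta shared across edge types; (iv) a write-back of gamma-scaled
# cell-type embeddings onto the proteins. Two layers; layer normalization
# after the first, batch normalization after the second; dropout between
# layers during training.

#' Training configuration
#'
#' Defaults follow the published pretraining hyperparameters: input feature
#' dimension 1024, output dimension 16, 8 attention heads, dropout 0.6,
#' weight decay 1e-5, link-prediction learning rate 0.01, center-loss
#' learning rate 0.1, lambda 0.1, 250 epochs. `theta` (the weight trading
#' protein-level link prediction against metagraph link prediction) has no
#' published default and is set to 0.5. `head_dim` is the per-head hidden
#' width of the first layer (heads are concatenated there and averaged at
#' the output layer, so the output dimension stays `d_out`).
#'
#' @param d_in Input feature dimension.
#' @param d_out Output embedding dimension.
#' @param n_heads Attention heads.
#' @param head_dim Hidden width per head on the first layer.
#' @param sem_dim Width of the shared semantic-attention projection.
#' @param epochs Training epochs.
#' @param dropout Dropout rate applied after each attention layer.
#' @param weight_decay L2 penalty on weights (not on normalization or
#'   relation parameters).
#' @param lr_link Learning rate for the model parameters.
#' @param lr_center Learning rate for the cell-type center parameters.
#' @param theta,lambda Loss weights in `[0, 1]` (see [total_loss()]).
#' @param lrelu_slope Negative slope of the attention leaky ReLU.
#' @param loss_reduction `"sum"` (the printed form of the objective) or
#'   `"mean"` per term.
#' @param use_metagraph,use_bridge Ablation switches; with both FALSE the
#'   model reduces to independent per-context graph attention.
#' @param eval_every Validation cadence in epochs.
#' @param seed Integer seed controlling initialization, dropout and
#'   negative resampling.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(d_in = 1024, d_out = 16, n_heads = 8, head_dim = 8,
                         sem_dim = 16, epochs = 250, dropout = 0.6,
                         weight_decay = 1e-5, lr_link = 0.01, lr_center = 0.1,
                         theta = 0.5, lambda = 0.1, lrelu_slope = 0.2,
                         loss_reduction = c("sum", "mean"),
                         use_metagraph = TRUE, use_bridge = TRUE,
                         eval_every = 5, seed = 1) {
  loss_reduction <- match.arg(loss_reduction)
  stopifnot(epochs >= 1, dropout >= 0, dropout < 1,
            theta >= 0, theta <= 1, lambda >= 0, lambda <= 1,
            d_in >= 1, d_out >= 1, n_heads >= 1, head_dim >= 1)
  structure(list(d_in = d_in, d_out = d_out, n_heads = n_heads,
                 head_dim = head_dim, sem_dim = sem_dim, epochs = epochs,
                 dropout = dropout, weight_decay = weight_decay,
                 lr_link = lr_link, lr_center = lr_center, theta = theta,
                 lambda = lambda, lrelu_slope = lrelu_slope,
                 loss_reduction = loss_reduction,
                 use_metagraph = use_metagraph, use_bridge = use_bridge,
                 eval_every = eval_every, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration for synthetic benchmarks
#'
#' The published defaults target atlas-scale networks (thousands of proteins
#' per context). For the synthetic benchmarks shipped with the package
#' (hundreds of proteins per context) this configuration shrinks the input
#' feature dimension and the dropout rate in proportion to the much smaller
#' parameter count, and keeps everything else at the published values.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `"train_config"`.
#' @export
synthetic_train_config <- function(...) {
  defaults <- list(d_in = 64, dropout = 0.2, epochs = 100)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

# Glorot-style initializer.
.glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# Block mask restricting attention vector columns to their own head.
.head_mask <- function(n_heads, head_dim) {
  m <- matrix(0, n_heads * head_dim, n_heads)
  for (k in seq_len(n_heads)) m[(k - 1) * head_dim + seq_len(head_dim), k] <- 1
  m
}

#' Initialize model parameters
#'
#' @param graph An [multiscale_graph()] with initialized features.
#' @param config A [train_config()].
#' @return Named list of parameter matrices (class `"ms_params"`).
#' @export
init_model_params <- function(graph, config) {
  stopifnot(inherits(graph, "ms_graph"), !is.null(graph$features))
  set.seed(config$seed)
  K <- config$n_heads
  H1 <- K * config$head_dim
  d_in <- config$d_in
  d_out <- config$d_out
  dims <- list(`1` = c(d_in, H1, config$head_dim),
               `2` = c(H1, K * d_out, d_out))
  p <- list()
  for (l in 1:2) {
    dd <- dims[[as.character(l)]]
    for (ci in names(graph$contexts)) {
      p[[sprintf("pp_Wl_%d_%s", l, ci)]] <- .glorot(dd[1], dd[2])
      p[[sprintf("pp_Wr_%d_%s", l, ci)]] <- .glorot(dd[1], dd[2])
      p[[sprintf("pp_a_%d_%s", l, ci)]] <- .glorot(dd[2], K)
    }
    for (r in c("cc", "ct", "tc", "tt")) {
      p[[sprintf("mg_Wl_%d_%s", l, r)]] <- .glorot(dd[1], dd[2])
      p[[sprintf("mg_Wr_%d_%s", l, r)]] <- .glorot(dd[1], dd[2])
      p[[sprintf("mg_a_%d_%s", l, r)]] <- .glorot(dd[2], K)
    }
    Hl <- if (l == 1) H1 else d_out
    p[[sprintf("sem_M_%d", l)]] <- .glorot(config$sem_dim, Hl)
    p[[sprintf("sem_b_%d", l)]] <- matrix(0, 1, config$sem_dim)
    p[[sprintf("sem_s_%d", l)]] <- .glorot(config$sem_dim, 1)
    p[[sprintf("br_q_%d", l)]] <- .glorot(dd[1], 1)
    p[[sprintf("pn_g_%d", l)]] <- matrix(1, 1, Hl)
    p[[sprintf("pn_b_%d", l)]] <- matrix(0, 1, Hl)
    p[[sprintf("mn_g_%d", l)]] <- matrix(1, 1, Hl)
    p[[sprintf("mn_b_%d", l)]] <- matrix(0, 1, Hl)
  }
  for (r in c("pp", "cc", "ct", "tc", "tt")) {
    p[[paste0("rel_", r)]] <- matrix(stats::rnorm(d_out, sd = 0.5), d_out, 1)
  }
  p$centers <- matrix(0, length(graph$contexts), d_out)
  p$feat <- graph$features[, seq_len(d_in), drop = FALSE]
  if (ncol(graph$features) != d_in) {
    stop("feature dimension mismatch: graph features have ", ncol(graph$features),
         " columns, config$d_in is ", d_in)
  }
  structure(p, class = "ms_params")
}

# One GATv2 attention pass for a (possibly bipartite) arc set.
# Hsrc/Hdst: tape nodes; src/dst integer arcs; returns list(out, alpha, dst).
.gat_pass <- function(tp, Hsrc, Hdst, src, dst, n_dst, Wl, Wr, a, mask,
                      n_heads, head_dim, concat, slope) {
  Xl <- ad_mm(tp, Hsrc, Wl)
  Xr <- ad_mm(tp, Hdst, Wr)
  Su <- ad_rows(tp, Xl, src)
  Sv <- ad_rows(tp, Xr, dst)
  E <- ad_lrelu(tp, ad_add(tp, Su, Sv), slope)
  a_eff <- ad_mul(tp, a, mask)
  scores <- ad_mm(tp, E, a_eff)                       # arcs x heads
  alpha <- ad_softmax_by(tp, scores, dst, n_dst)
  alpha_exp <- ad_cols(tp, alpha, rep(seq_len(n_heads), each = head_dim))
  agg <- ad_rowsum_by(tp, ad_mul(tp, alpha_exp, Su), dst, n_dst)
  out <- ad_relu(tp, agg)
  if (!concat) {
    # average heads so the output width is head-independent
    A <- matrix(0, n_heads * head_dim, head_dim)
    for (k in seq_len(n_heads)) {
      A[(k - 1) * head_dim + seq_len(head_dim), ] <- diag(head_dim) / n_heads
    }
    out <- ad_mm(tp, out, ad_leaf(tp, A))
  }
  list(out = out, alpha = alpha$value, dst = dst)
}

# Arcs (both directions) plus self-loops from an undirected edge matrix,
# in LOCAL indices 1..n.
.arcs_with_loops <- function(edge_idx, n) {
  src <- c(edge_idx[, 1], edge_idx[, 2], seq_len(n))
  dst <- c(edge_idx[, 2], edge_idx[, 1], seq_len(n))
  cbind(src, dst)
}

# Semantic attention over edge types: m_r = sum_u s' tanh(M h_u^r + b).
.semantic_scores <- function(tp, H_list, M, b, s) {
  lapply(H_list, function(H) {
    proj <- ad_tanh(tp, ad_add(tp, ad_mm(tp, H, ad_node(tp, t(M$value), list(M), function(g) list(t(g)))), b))
    ad_sum(tp, ad_mm(tp, proj, s))
  })
}

# Tissue initialization: mean of already-initialized neighbors, processed
# bottom-up so that every tissue with any metagraph neighbor gets a value.
.init_tissue_embeddings <- function(tp, mg, HC, cell_ids, tissue_ids, d) {
  nT <- length(tissue_ids)
  depth <- .tissue_depths(mg)
  ord <- order(-depth[names(tissue_ids)])        # deepest first
  rows <- vector("list", nT)
  # repeated sweeps: a tissue initializes from any already-initialized
  # neighbor (attached cell types, child or parent tissues); a connected
  # tree with at least one cell-attached tissue fills completely
  repeat {
    progressed <- FALSE
    for (t in names(tissue_ids)[ord]) {
      if (!is.null(rows[[tissue_ids[t]]])) next
      cts <- mg$ct_edges$cell_type[mg$ct_edges$tissue == t]
      kids <- mg$tt_edges$child[mg$tt_edges$parent == t]
      pars <- mg$tt_edges$parent[mg$tt_edges$child == t]
      nb <- list()
      if (length(cts)) nb <- c(nb, list(ad_rows(tp, HC, cell_ids[cts])))
      for (k in c(kids, pars)) {
        if (!is.null(rows[[tissue_ids[k]]])) nb <- c(nb, list(rows[[tissue_ids[k]]]))
      }
      if (length(nb) > 0) {
        stacked <- ad_rbind(tp, nb)
        ones <- ad_leaf(tp, matrix(1 / nrow(stacked$value), 1, nrow(stacked$value)))
        rows[[tissue_ids[t]]] <- ad_mm(tp, ones, stacked)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  for (t in names(tissue_ids)) {
    if (is.null(rows[[tissue_ids[t]]])) {
      warning("tissue without metagraph neighbors: ", t, "; using zeros")
      rows[[tissue_ids[t]]] <- ad_leaf(tp, matrix(0, 1, d))
    }
  }
  ad_rbind(tp, rows)
}

.tissue_depths <- function(mg) {
  depth <- stats::setNames(rep(NA_real_, length(mg$tissues)), mg$tissues)
  depth[mg$root] <- 0
  parent_of <- stats::setNames(mg$tt_edges$parent, mg$tt_edges$child)
  repeat {
    todo <- names(depth)[is.na(depth)]
    if (!length(todo)) break
    progressed <- FALSE
    for (t in todo) {
      p <- parent_of[[t]]
      if (!is.null(p) && !is.na(depth[p])) {
        depth[t] <- depth[p] + 1
        progressed <- TRUE
      }
    }
    if (!progressed) { depth[is.na(depth)] <- 0; break }
  }
  depth
}

#' Run the multi-scale forward pass
#'
#' @param graph An [multiscale_graph()].
#' @param params An [init_model_params()] parameter list.
#' @param config A [train_config()].
#' @param train_edges Named list (per context) of 2-column node-id matrices
#'   used as message-passing adjacency; defaults to all context edges.
#'   During training this must be the train split only, so that held-out
#'   edges stay invisible to message passing.
#' @param training Logical; enables dropout.
#' @param tape Optionally, an existing tape to build on (used by the
#'   trainer); a fresh one is created otherwise.
#' @return A list with tape nodes `Zp` (all protein nodes, stacked in
#'   node-id order), `Zc` (cell types), `Zt` (tissues), the tape, and
#'   diagnostic attention values (`alpha` per context and layer, `beta` per
#'   layer, `gamma` per layer).
#' @export
forward_multiscale <- function(graph, params, config, train_edges = NULL,
                               training = FALSE, tape = NULL) {
  stopifnot(inherits(graph, "ms_graph"))
  tp <- if (is.null(tape)) tape_new() else tape
  leaf_env <- new.env(parent = emptyenv())
  K <- config$n_heads
  mg <- graph$metagraph
  ctx_names <- names(graph$contexts)
  nC <- length(ctx_names)
  cell_ids <- stats::setNames(seq_len(nC), ctx_names)
  tissue_ids <- stats::setNames(seq_along(mg$tissues), mg$tissues)
  nT <- length(mg$tissues)

  P <- function(nm) {
    if (is.null(leaf_env[[nm]])) leaf_env[[nm]] <- ad_leaf(tp, params[[nm]], name = nm)
    leaf_env[[nm]]
  }
  mask1 <- ad_leaf(tp, .head_mask(K, config$head_dim))
  mask2 <- ad_leaf(tp, .head_mask(K, config$d_out))

  # per-context node bookkeeping (local indices within the stacked matrix)
  sizes <- vapply(graph$contexts, function(cx) length(cx$nodes), integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offsets) <- ctx_names
  ctx_of_node <- rep(seq_len(nC), sizes)
  id_rows <- match(graph$node_index$protein[order(graph$node_index$node_id)],
                   rownames(params$feat))

  Hp <- ad_rows(tp, P("feat"), id_rows)          # stacked protein features
  HC <- NULL; HT <- NULL
  diag_alpha <- list(); diag_beta <- list(); diag_gamma <- list()

  # metagraph arcs in local indices (fixed across layers)
  cc_arcs <- .arcs_with_loops(
    cbind(cell_ids[mg$cc_edges$cell_type_a], cell_ids[mg$cc_edges$cell_type_b]), nC)
  tt_arcs <- .arcs_with_loops(
    cbind(tissue_ids[mg$tt_edges$child], tissue_ids[mg$tt_edges$parent]), nT)
  ct_src <- tissue_ids[mg$ct_edges$tissue]; ct_dst <- cell_ids[mg$ct_edges$cell_type]
  tc_src <- cell_ids[mg$ct_edges$cell_type]; tc_dst <- tissue_ids[mg$ct_edges$tissue]

  for (l in 1:2) {
    dd_head <- if (l == 1) config$head_dim else config$d_out
    concat <- l == 1
    Hl_width <- if (l == 1) K * config$head_dim else config$d_out

    # gamma: importance of each protein to its cell type, from the
    # embeddings entering this layer
    gam <- NULL
    if (config$use_bridge && config$use_metagraph) {
      gsc <- ad_mm(tp, ad_tanh(tp, Hp), P(sprintf("br_q_%d", l)))
      gam <- ad_softmax_by(tp, gsc, ctx_of_node, nC)
      diag_gamma[[l]] <- list(value = gam$value, group = ctx_of_node)
    }

    # protein attention per context
    outs <- vector("list", nC)
    for (i in seq_len(nC)) {
      ci <- ctx_names[i]
      cx <- graph$contexts[[ci]]
      ei <- if (is.null(train_edges)) cx$edge_idx else train_edges[[ci]]
      local_ei <- ei - offsets[ci]
      arcs <- .arcs_with_loops(local_ei, sizes[i])
      Hc <- ad_rows(tp, Hp, offsets[ci] + seq_len(sizes[i]))
      g <- .gat_pass(tp, Hc, Hc, arcs[, 1], arcs[, 2], sizes[i],
                     P(sprintf("pp_Wl_%d_%s", l, ci)),
                     P(sprintf("pp_Wr_%d_%s", l, ci)),
                     P(sprintf("pp_a_%d_%s", l, ci)),
                     if (l == 1) mask1 else mask2,
                     K, dd_head, concat, config$lrelu_slope)
      outs[[i]] <- g$out
      diag_alpha[[sprintf("layer%d_%s", l, ci)]] <-
        list(value = g$alpha, group = g$dst)
    }
    Hp_new <- ad_rbind(tp, outs)

    if (config$use_metagraph) {
      # metagraph inputs: previous meta embeddings (layer 1: protein means),
      # with the gamma-pooled protein summary added to the cell types
      if (l == 1) {
        cnt <- ad_leaf(tp, matrix(1 / sizes[ctx_of_node], ncol = 1))
        HC_in <- ad_rowsum_by(tp, ad_mul(tp, Hp, cnt), ctx_of_node, nC)
        HT_in <- .init_tissue_embeddings(tp, mg, HC_in, cell_ids, tissue_ids,
                                         ncol(Hp$value))
      } else {
        HC_in <- HC; HT_in <- HT
      }
      if (config$use_bridge) {
        pooled <- ad_rowsum_by(tp, ad_mul(tp, Hp, gam), ctx_of_node, nC)
        HC_in <- ad_add(tp, HC_in, ad_relu(tp, pooled))
      }

      msk <- if (l == 1) mask1 else mask2
      gat_meta <- function(r, Hsrc, Hdst, src, dst, n_dst) {
        .gat_pass(tp, Hsrc, Hdst, src, dst, n_dst,
                  P(sprintf("mg_Wl_%d_%s", l, r)),
                  P(sprintf("mg_Wr_%d_%s", l, r)),
                  P(sprintf("mg_a_%d_%s", l, r)),
                  msk, K, dd_head, concat, config$lrelu_slope)
      }
      HCC <- gat_meta("cc", HC_in, HC_in, cc_arcs[, 1], cc_arcs[, 2], nC)$out
      HCT <- gat_meta("ct", HT_in, HC_in, ct_src, ct_dst, nC)$out
      HTT <- gat_meta("tt", HT_in, HT_in, tt_arcs[, 1], tt_arcs[, 2], nT)$out
      HTC <- gat_meta("tc", HC_in, HT_in, tc_src, tc_dst, nT)$out

      sM <- P(sprintf("sem_M_%d", l)); sb <- P(sprintf("sem_b_%d", l))
      ss <- P(sprintf("sem_s_%d", l))
      mcell <- .semantic_scores(tp, list(cc = HCC, ct = HCT), sM, sb, ss)
      mtis <- .semantic_scores(tp, list(tt = HTT, tc = HTC), sM, sb, ss)
      beta_cell <- ad_softmax_by(tp, ad_rbind(tp, mcell), c(1L, 1L), 1L)
      beta_tis <- ad_softmax_by(tp, ad_rbind(tp, mtis), c(1L, 1L), 1L)
      bC1 <- ad_rows(tp, beta_cell, 1L); bC2 <- ad_rows(tp, beta_cell, 2L)
      bT1 <- ad_rows(tp, beta_tis, 1L); bT2 <- ad_rows(tp, beta_tis, 2L)
      HC_new <- ad_add(tp, ad_mul(tp, HCC, bC1), ad_mul(tp, HCT, bC2))
      HT_new <- ad_add(tp, ad_mul(tp, HTT, bT1), ad_mul(tp, HTC, bT2))
      diag_beta[[l]] <- list(cell = as.numeric(beta_cell$value),
                             tissue = as.numeric(beta_tis$value))

      if (config$use_bridge) {
        # write-back: h_u <- h_u + gamma_u * h_{c(u)}
        HC_per_node <- ad_rows(tp, HC_new, ctx_of_node)
        Hp_new <- ad_add(tp, Hp_new, ad_mul(tp, HC_per_node, gam))
      }
    } else {
      HC_new <- NULL; HT_new <- NULL
    }

    # normalization: layer 1 layer-norm, layer 2 batch-norm
    norm <- function(x, gnm, bnm) {
      if (is.null(x)) return(NULL)
      if (l == 1) ad_layernorm(tp, x, P(gnm), P(bnm))
      else ad_batchnorm(tp, x, P(gnm), P(bnm))
    }
    Hp_new <- norm(Hp_new, sprintf("pn_g_%d", l), sprintf("pn_b_%d", l))
    HC_new <- norm(HC_new, sprintf("mn_g_%d", l), sprintf("mn_b_%d", l))
    HT_new <- norm(HT_new, sprintf("mn_g_%d", l), sprintf("mn_b_%d", l))

    if (training && config$dropout > 0) {
      dr <- function(x) {
        if (is.null(x)) return(NULL)
        keep <- 1 - config$dropout
        m <- matrix(stats::rbinom(length(x$value), 1, keep) / keep,
                    nrow(x$value), ncol(x$value))
        ad_dropout(tp, x, m)
      }
      Hp_new <- dr(Hp_new); HC_new <- dr(HC_new); HT_new <- dr(HT_new)
    }
    Hp <- Hp_new; HC <- HC_new; HT <- HT_new
  }

  list(tape = tp, leaves = leaf_env, Zp = Hp, Zc = HC, Zt = HT,
       cell_ids = cell_ids, tissue_ids = tissue_ids, ctx_of_node = ctx_of_node,
       alpha = diag_alpha, beta = diag_beta, gamma = diag_gamma)
}
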