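# Oracle tests for the attention building blocks: every piece is compared
# against a step-by-step plain-arithmetic evaluation that never touches the
# autodiff tape machinery beyond wrapping inputs.

lrelu <- function(x, s = 0.2) ifelse(x > 0, x, s * x)

test_that("protein attention matches a scalar hand evaluation on a 2-node toy", {
  # one head, width 1: score(u->v) = a * lrelu(wl*h_u + wr*h_v),
  # alpha = softmax over in-neighbors, out_v = relu(sum alpha * wl * h_u)
  h <- matrix(c(0.5, -1.2), 2, 1)
  wl <- 0.7; wr <- -0.3; a <- 1.1
  tp <- contextppi:::tape_new()
  arcs <- contextppi:::.arcs_with_loops(matrix(c(1L, 2L), 1), 2)
  g <- contextppi:::.gat_pass(
    tp,
    contextppi:::ad_leaf(tp, h), contextppi:::ad_leaf(tp, h),
    arcs[, 1], arcs[, 2], 2,
    contextppi:::ad_leaf(tp, matrix(wl, 1, 1)),
    contextppi:::ad_leaf(tp, matrix(wr, 1, 1)),
    contextppi:::ad_leaf(tp, matrix(a, 1, 1)),
    contextppi:::ad_leaf(tp, matrix(1, 1, 1)),
    n_heads = 1, head_dim = 1, concat = TRUE, slope = 0.2)
  # scalar oracle, node by node
  for (v in 1:2) {
    nb <- c(setdiff(1:2, v), v)           # neighbor and self-loop
    sc <- vapply(nb, function(u) a * lrelu(wl * h[u] + wr * h[v]), numeric(1))
    al <- exp(sc - max(sc)); al <- al / sum(al)
    expected <- max(0, sum(al * wl * h[nb]))
    expect_equal(g$out$value[v, 1], expected, tolerance = 1e-12)
  }
})

test_that("attention weights sum to one over each node's in-neighborhood", {
  set.seed(31)
  gs <- graph_spec(n_contexts = 3, proteins_per_context = 40, seed = 3)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  msg <- init_protein_features(msg, 8, seed = 1)
  cfg <- train_config(d_in = 8, n_heads = 2, head_dim = 3, d_out = 4, seed = 1)
  params <- init_model_params(msg, cfg)
  fw <- forward_multiscale(msg, params, cfg)
  for (al in fw$alpha) {
    sums <- rowsum(al$value, al$group)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(al$value >= 0))
  }
  for (b in fw$beta) {
    expect_equal(sum(b$cell), 1, tolerance = 1e-12)
    expect_equal(sum(b$tissue), 1, tolerance = 1e-12)
    expect_true(all(c(b$cell, b$tissue) > 0))
  }
  for (gm in fw$gamma) {
    sums <- rowsum(gm$value, gm$group)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("semantic attention weights match a scalar softmax oracle", {
  set.seed(32)
  tp <- contextppi:::tape_new()
  H1 <- matrix(rnorm(6), 2, 3); H2 <- matrix(rnorm(6), 2, 3)
  M <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(4), 1, 4); s <- matrix(rnorm(4), 4, 1)
  Mn <- contextppi:::ad_leaf(tp, M)
  ms <- contextppi:::.semantic_scores(
    tp, list(contextppi:::ad_leaf(tp, H1), contextppi:::ad_leaf(tp, H2)),
    Mn, contextppi:::ad_leaf(tp, b), contextppi:::ad_leaf(tp, s))
  # oracle: m_r = sum_u s' tanh(M h_u + b)
  oracle_m <- vapply(list(H1, H2), function(H) {
    sum(vapply(seq_len(nrow(H)), function(u) {
      sum(s * tanh(M %*% H[u, ] + as.numeric(b)))
    }, numeric(1)))
  }, numeric(1))
  got_m <- c(ms[[1]]$value[1], ms[[2]]$value[1])
  expect_equal(got_m, oracle_m, tolerance = 1e-10)
  beta <- exp(oracle_m - max(oracle_m)); beta <- beta / sum(beta)
  sm <- contextppi:::ad_softmax_by(tp, contextppi:::ad_rbind(tp, ms), c(1L, 1L), 1L)
  expect_equal(as.numeric(sm$value), beta, tolerance = 1e-10)
  expect_equal(sum(sm$value), 1, tolerance = 1e-12)
})

test_that("a single-protein context gets bridge weight one", {
  ctx <- list(
    solo = list(context_id = "solo", nodes = "P1",
                edges = data.frame(protein_a = character(0), protein_b = character(0))),
    duo = list(context_id = "duo", nodes = c("P1", "P2"),
               edges = data.frame(protein_a = "P1", protein_b = "P2")))
  mg <- build_metagraph(
    data.frame(cell_type_a = "solo", cell_type_b = "duo", p_value = 1e-5),
    data.frame(cell_type = c("solo", "duo"), tissue = c("leaf", "leaf")),
    data.frame(child = "leaf", parent = "root"))
  msg <- multiscale_graph(ctx, mg)
  msg <- init_protein_features(msg, 6, seed = 2)
  cfg <- train_config(d_in = 6, n_heads = 2, head_dim = 2, d_out = 3, seed = 2)
  params <- init_model_params(msg, cfg)
  fw <- forward_multiscale(msg, params, cfg)
  for (gm in fw$gamma) {
    expect_equal(unname(gm$value[gm$group == 1, 1]), 1, tolerance = 1e-12)
  }
})

test_that("initial scale embeddings are neighbor means", {
  # cell-type initialization: mean of its proteins' feature vectors
  gs <- graph_spec(n_contexts = 2, proteins_per_context = 20, seed = 5)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  msg <- init_protein_features(msg, 5, seed = 3)
  tp <- contextppi:::tape_new()
  sizes <- vapply(msg$contexts, function(cx) length(cx$nodes), integer(1))
  ctx_of_node <- rep(seq_along(sizes), sizes)
  id_rows <- match(msg$node_index$protein[order(msg$node_index$node_id)],
                   rownames(msg$features))
  Hp <- contextppi:::ad_leaf(tp, msg$features[id_rows, ])
  cnt <- contextppi:::ad_leaf(tp, matrix(1 / sizes[ctx_of_node], ncol = 1))
  HC <- contextppi:::ad_rowsum_by(tp, contextppi:::ad_mul(tp, Hp, cnt),
                                  ctx_of_node, length(sizes))
  for (i in seq_along(msg$contexts)) {
    direct <- colMeans(msg$features[msg$contexts[[i]]$nodes, , drop = FALSE])
    expect_equal(unname(HC$value[i, ]), unname(direct), tolerance = 1e-12)
  }
  # tissue initialization: mean over already-initialized metagraph neighbors
  cell_ids <- stats::setNames(seq_along(msg$contexts), names(msg$contexts))
  tissue_ids <- stats::setNames(seq_along(msg$metagraph$tissues), msg$metagraph$tissues)
  HT <- contextppi:::.init_tissue_embeddings(tp, msg$metagraph, HC, cell_ids,
                                             tissue_ids, 5)
  leaf <- g$context_tissue$tissue[1]
  cts <- msg$metagraph$ct_edges$cell_type[msg$metagraph$ct_edges$tissue == leaf]
  oracle <- colMeans(HC$value[cell_ids[cts], , drop = FALSE])
  expect_equal(unname(HT$value[tissue_ids[leaf], ]), unname(oracle), tolerance = 1e-12)
})

test_that("forward pass yields finite embeddings at the configured dimension", {
  gs <- graph_spec(n_contexts = 3, proteins_per_context = 30, seed = 6)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  msg <- init_protein_features(msg, 12, seed = 1)
  cfg <- train_config(d_in = 12, n_heads = 4, head_dim = 4, d_out = 16, seed = 1)
  params <- init_model_params(msg, cfg)
  fw <- forward_multiscale(msg, params, cfg)
  expect_equal(ncol(fw$Zp$value), 16)   # default output dimension
  expect_equal(ncol(fw$Zc$value), 16)
  expect_equal(ncol(fw$Zt$value), 16)
  expect_equal(nrow(fw$Zp$value), msg$n_nodes)
  expect_true(all(is.finite(fw$Zp$value)))
  expect_true(all(is.finite(fw$Zc$value)))
  expect_true(all(is.finite(fw$Zt$value)))
})

test_that("with metagraph and bridge disabled the model is a per-context GAT", {
  gs <- graph_spec(n_contexts = 2, proteins_per_context = 25, seed = 7)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  msg <- init_protein_features(msg, 6, seed = 2)
  cfg <- train_config(d_in = 6, n_heads = 2, head_dim = 3, d_out = 4, seed = 2,
                      use_metagraph = FALSE, use_bridge = FALSE)
  params <- init_model_params(msg, cfg)
  fw <- forward_multiscale(msg, params, cfg)

  # independent plain-matrix implementation of the ablated network
  plain_gat <- function(H, ei, Wl, Wr, a, K, dh, concat, slope = 0.2) {
    n <- nrow(H)
    arcs <- contextppi:::.arcs_with_loops(ei, n)
    Xl <- H %*% Wl; Xr <- H %*% Wr
    mask <- contextppi:::.head_mask(K, dh)
    S <- lrelu(Xl[arcs[, 1], , drop = FALSE] + Xr[arcs[, 2], , drop = FALSE], slope)
    sc <- S %*% (a * mask)
    out <- matrix(0, n, K * dh)
    for (v in seq_len(n)) {
      rows <- which(arcs[, 2] == v)
      al <- apply(sc[rows, , drop = FALSE], 2, function(x) {
        e <- exp(x - max(x)); e / sum(e)
      })
      if (!is.matrix(al)) al <- matrix(al, nrow = 1)
      msg_v <- al[, rep(seq_len(K), each = dh), drop = FALSE] *
        Xl[arcs[rows, 1], , drop = FALSE]
      out[v, ] <- colSums(msg_v)
    }
    out <- pmax(out, 0)
    if (!concat) {
      avg <- matrix(0, n, dh)
      for (k in seq_len(K)) avg <- avg + out[, (k - 1) * dh + seq_len(dh)] / K
      out <- avg
    }
    out
  }
  layernorm <- function(X, g, b, eps = 1e-5) {
    mu <- rowMeans(X); xc <- X - mu
    s <- sqrt(rowMeans(xc^2) + eps)
    (xc / s) * matrix(g, nrow(X), ncol(X), byrow = TRUE) +
      matrix(b, nrow(X), ncol(X), byrow = TRUE)
  }
  batchnorm <- function(X, g, b, eps = 1e-5) {
    mu <- colMeans(X); xc <- sweep(X, 2, mu)
    s <- sqrt(colMeans(xc^2) + eps)
    sweep(xc, 2, s, "/") * matrix(g, nrow(X), ncol(X), byrow = TRUE) +
      matrix(b, nrow(X), ncol(X), byrow = TRUE)
  }
  offsets <- c(0, cumsum(vapply(msg$contexts, function(cx) length(cx$nodes),
                                integer(1))))
  # message passing is independent per context; the final batch
  # normalization is a per-feature rescaling over the stacked nodes
  H2_all <- vector("list", length(msg$contexts))
  for (i in seq_along(msg$contexts)) {
    ci <- names(msg$contexts)[i]
    cx <- msg$contexts[[ci]]
    H0 <- msg$features[cx$nodes, , drop = FALSE]
    ei <- cx$edge_idx - offsets[i]
    H1 <- plain_gat(H0, ei, params[[paste0("pp_Wl_1_", ci)]],
                    params[[paste0("pp_Wr_1_", ci)]], params[[paste0("pp_a_1_", ci)]],
                    2, 3, TRUE)
    H1 <- layernorm(H1, params$pn_g_1, params$pn_b_1)
    H2_all[[i]] <- plain_gat(H1, ei, params[[paste0("pp_Wl_2_", ci)]],
                             params[[paste0("pp_Wr_2_", ci)]],
                             params[[paste0("pp_a_2_", ci)]], 2, 4, FALSE)
  }
  H2 <- batchnorm(do.call(rbind, H2_all), params$pn_g_2, params$pn_b_2)
  expect_equal(unname(fw$Zp$value), unname(H2), tolerance = 1e-8)
})

test_that("relabeling proteins permutes the embeddings identically", {
  gs <- graph_spec(n_contexts = 2, proteins_per_context = 20,
                   shared_fraction = 0.5, seed = 8)
  g <- synth_multiscale_graph(gs)
  msg <- multiscale_graph(g$contexts, g$metagraph)
  msg <- init_protein_features(msg, 6, seed = 4)
  cfg <- train_config(d_in = 6, n_heads = 2, head_dim = 2, d_out = 4, seed = 4)
  params <- init_model_params(msg, cfg)
  fw <- forward_multiscale(msg, params, cfg)

  # bijective rename that changes the sort order of the protein names
  all_prot <- sort(unique(unlist(lapply(g$contexts, `[[`, "nodes"))))
  new_names <- stats::setNames(rev(sprintf("Q%05d", seq_along(all_prot))), all_prot)
  ctx2 <- lapply(g$contexts, function(cx) {
    list(context_id = cx$context_id,
         nodes = unname(new_names[cx$nodes]),
         edges = data.frame(protein_a = unname(new_names[cx$edges$protein_a]),
                            protein_b = unname(new_names[cx$edges$protein_b])))
  })
  msg2 <- multiscale_graph(ctx2, g$metagraph)
  feats2 <- msg$features
  rownames(feats2) <- unname(new_names[rownames(msg$features)])
  msg2$features <- feats2[sort(rownames(feats2)), , drop = FALSE]
  params2 <- params
  params2$feat <- msg2$features  # the feature parameter follows the renaming
  fw2 <- forward_multiscale(msg2, params2, cfg)

  idx1 <- msg$node_index
  idx2 <- msg2$node_index
  map <- match(paste(new_names[idx1$protein], idx1$context),
               paste(idx2$protein, idx2$context))
  expect_equal(unname(fw2$Zp$value[idx2$node_id[map], ]),
               unname(fw$Zp$value[idx1$node_id, ]), tolerance = 1e-8)
})
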