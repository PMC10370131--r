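#' Fit contextualized protein embeddings
#'
#' Trains the multi-scale attention model by full-graph gradient descent on
#' the composite objective: binary cross-entropy link prediction within each
#' cell-type-specific protein network (train split only; held-out edges are
#' excluded from message passing), link prediction over the metagraph's
#' cell-cell, cell-tissue, tissue-tissue and tissue-cell edges, and a center
#' loss pulling each protein embedding toward its cell type's center. Two
#' optimizer groups are used: model parameters at `lr_link` and the center
#' parameters at `lr_center`. Validation link AUROC and a Calinski-Harabasz
#' cluster-separation score are computed every `eval_every` epochs and the
#' checkpoint maximizing validation AUROC (ties broken by the cluster score)
#' is returned.
#'
#' @param graph An [multiscale_graph()]; features are initialized with
#'   [init_protein_features()] at `config$d_in` if absent.
#' @param split An [split_edges()] result; computed at the default ratios
#'   with `config$seed` if NULL.
#' @param config A [train_config()].
#' @param verbose Print per-evaluation progress.
#' @return An object of class `"contextppi"` with components `embeddings`
#'   (list `protein` — rows aligned with `graph$node_index` —, `cell_type`,
#'   `tissue`), `params` (best checkpoint), `log` (per-epoch data frame),
#'   `best_epoch`, `config`, `split`, `graph`, and `metrics` (validation and
#'   test AUROC at the selected checkpoint).
#' @export
contextppi <- function(graph, split = NULL, config = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(graph, "ms_graph"), inherits(config, "train_config"))
  set.seed(config$seed)
  if (is.null(graph$features)) {
    graph <- init_protein_features(graph, config$d_in, config$seed)
  }
  if (is.null(split)) split <- split_edges(graph, seed = config$seed)
  params <- init_model_params(graph, config)

  lr <- stats::setNames(rep(config$lr_link, length(params)), names(params))
  lr["centers"] <- config$lr_center
  opt <- adam_new(params, lr)
  decay_skip <- grep("^(pn_|mn_|rel_|centers|sem_b)", names(params), value = TRUE)

  train_edges <- lapply(split, `[[`, "train")
  log_rows <- vector("list", config$epochs)
  best <- list(auroc = -Inf, ch = -Inf, epoch = NA_integer_, params = NULL)

  for (epoch in seq_len(config$epochs)) {
    fw <- forward_multiscale(graph, params, config, train_edges, training = TRUE)
    tp <- fw$tape
    P <- function(nm) {
      if (is.null(fw$leaves[[nm]])) {
        fw$leaves[[nm]] <- ad_leaf(tp, params[[nm]], name = nm)
      }
      fw$leaves[[nm]]
    }
    ls <- .ad_total_loss(tp, fw, graph, params, config, split, P)
    if (!is.finite(ls$total$value[1])) {
      stop("non-finite loss at epoch ", epoch, "; components: ",
           paste(sprintf("%s=%.4g", names(ls$parts), ls$parts), collapse = ", "))
    }
    grads <- ad_backward(tp, ls$total)
    params <- adam_step(opt, params, grads, config$weight_decay, decay_skip)

    row <- c(epoch = epoch, ls$parts, val_auroc = NA_real_, val_ch = NA_real_)
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      ev <- .evaluate_checkpoint(graph, params, config, train_edges, split, "val")
      row["val_auroc"] <- ev$auroc
      row["val_ch"] <- ev$ch
      if (ev$auroc > best$auroc ||
          (ev$auroc == best$auroc && ev$ch > best$ch)) {
        best <- list(auroc = ev$auroc, ch = ev$ch, epoch = epoch, params = params)
      }
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  val AUROC %.3f  CH %.1f",
                        epoch, ls$parts[["total"]], ev$auroc, ev$ch))
      }
    }
    log_rows[[epoch]] <- row
  }
  log <- as.data.frame(do.call(rbind, log_rows))

  fw <- forward_multiscale(graph, best$params, config, train_edges, training = FALSE)
  emb <- .collect_embeddings(fw, graph)
  test_ev <- .evaluate_checkpoint(graph, best$params, config, train_edges, split, "test")
  structure(list(embeddings = emb, params = best$params, log = log,
                 best_epoch = best$epoch, config = config, split = split,
                 graph = graph,
                 metrics = list(val_auroc = best$auroc, val_ch = best$ch,
                                test_auroc = test_ev$auroc)),
            class = "contextppi")
}

.collect_embeddings <- function(fw, graph) {
  prot <- fw$Zp$value
  rownames(prot) <- NULL
  cellm <- NULL; tism <- NULL
  if (!is.null(fw$Zc)) {
    cellm <- fw$Zc$value; rownames(cellm) <- names(fw$cell_ids)
  }
  if (!is.null(fw$Zt)) {
    tism <- fw$Zt$value; rownames(tism) <- names(fw$tissue_ids)
  }
  list(protein = prot, index = graph$node_index,
       cell_type = cellm, tissue = tism)
}

.evaluate_checkpoint <- function(graph, params, config, train_edges, split, which) {
  fw <- forward_multiscale(graph, params, config, train_edges, training = FALSE)
  Z <- fw$Zp$value
  rel <- as.numeric(params$rel_pp)
  scores <- c(); labels <- c()
  for (ci in names(split)) {
    pos <- split[[ci]][[which]]
    neg <- split[[ci]]$negatives[[which]]
    if (nrow(pos) == 0) next
    sc <- function(pr) rowSums(Z[pr[, 1], , drop = FALSE] *
                                 matrix(rel, nrow(pr), length(rel), byrow = TRUE) *
                                 Z[pr[, 2], , drop = FALSE])
    scores <- c(scores, sc(pos), sc(neg))
    labels <- c(labels, rep(1, nrow(pos)), rep(0, nrow(neg)))
  }
  auroc <- if (length(unique(labels)) == 2) .auroc(scores, labels) else NA_real_
  ch <- .calinski_harabasz(Z, fw$ctx_of_node)
  list(auroc = auroc, ch = ch)
}

# Mann-Whitney formulation of the area under the ROC curve.
.auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Between/within-cluster variance ratio with the usual (n-k)/(k-1) scaling.
.calinski_harabasz <- function(X, labels) {
  labels <- as.integer(factor(labels))
  k <- length(unique(labels)); n <- nrow(X)
  if (k < 2 || n <= k) return(NA_real_)
  gm <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    cm <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * sum((cm - gm)^2)
    ssw <- ssw + sum(sweep(Xi, 2, cm)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the best epoch from a training log
#'
#' The epoch with maximal validation AUROC; ties broken by the higher
#' cluster-separation score.
#'
#' @param log Data frame with columns `epoch`, `val_auroc`, `val_ch`.
#' @return The selected epoch id.
#' @export
select_model <- function(log) {
  stopifnot(nrow(log) >= 1)
  cand <- log[!is.na(log$val_auroc), , drop = FALSE]
  if (nrow(cand) == 0) return(log$epoch[nrow(log)])
  cand <- cand[order(-cand$val_auroc, -cand$val_ch, cand$epoch), ]
  cand$epoch[1]
}

#' Export embeddings to TSV files
#'
#' Writes `protein_embeddings.tsv` (columns `protein`, `context`,
#' `v1..v_dout`), `cell_type_embeddings.tsv` and `tissue_embeddings.tsv`.
#'
#' @param object A fitted [contextppi] model (or its `embeddings` list).
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
export_embeddings <- function(object, dir) {
  emb <- if (inherits(object, "contextppi")) object$embeddings else object
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- ncol(emb$protein)
  vn <- paste0("v", seq_len(d))
  pt <- cbind(emb$index[, c("protein", "context")],
              stats::setNames(as.data.frame(emb$protein), vn))
  utils::write.table(pt, file.path(dir, "protein_embeddings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("cell_type", "tissue")) {
    m <- emb[[nm]]
    df <- cbind(data.frame(name = rownames(m)),
                stats::setNames(as.data.frame(m), vn))
    utils::write.table(df, file.path(dir, paste0(nm, "_embeddings.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS archive of the parameter matrices keyed by
#' module path plus a JSON sidecar with the hyperparameters.
#'
#' @param object A fitted [contextppi] model.
#' @param dir Checkpoint directory.
#' @return `save_model`: the directory, invisibly. `load_model`: a list
#'   with `params` and `config`.
#' @export
save_model <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(object$params, file.path(dir, "params.rds"))
  jsonlite::write_json(unclass(object$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  list(params = readRDS(file.path(dir, "params.rds")),
       config = do.call(train_config, cfg[setdiff(names(cfg), character(0))]))
}

# ---- S3 methods ----

#' @export
print.contextppi <- function(x, ...) {
  cat("Contextualized protein embedding model\n")
  cat(sprintf("  contexts: %d  protein nodes: %d  tissues: %d\n",
              length(x$graph$contexts), x$graph$n_nodes,
              length(x$graph$metagraph$tissues)))
  cat(sprintf("  output dimension: %d  heads: %d  epochs trained: %d (best %d)\n",
              x$config$d_out, x$config$n_heads, nrow(x$log), x$best_epoch))
  cat(sprintf("  validation AUROC %.3f  test AUROC %.3f\n",
              x$metrics$val_auroc, x$metrics$test_auroc))
  invisible(x)
}

#' @export
summary.contextppi <- function(object, ...) {
  print(object)
  gap <- similarity_gap(object$embeddings$protein, object$embeddings$index$context)
  cat(sprintf("  median cosine similarity: within-context %.3f, cross-context %.3f\n",
              gap$median_within, gap$median_cross))
  invisible(list(metrics = object$metrics, similarity = gap))
}

#' @export
coef.contextppi <- function(object, ...) object$params

#' Predict link probabilities from a fitted model
#'
#' @param object A fitted [contextppi] model.
#' @param newdata Data frame with columns `protein_a`, `protein_b`,
#'   `context`; defaults to the held-out test edges and their frozen
#'   negatives.
#' @param ... Unused.
#' @return `newdata` with a `probability` column (and `label` for the
#'   default test-edge table).
#' @export
predict.contextppi <- function(object, newdata = NULL, ...) {
  Z <- object$embeddings$protein
  idx <- object$embeddings$index
  rel <- as.numeric(object$params$rel_pp)
  if (is.null(newdata)) {
    rows <- list()
    prot <- idx$protein[order(idx$node_id)]
    for (ci in names(object$split)) {
      for (lb in c(1, 0)) {
        m <- if (lb == 1) object$split[[ci]]$test else object$split[[ci]]$negatives$test
        if (nrow(m)) rows[[length(rows) + 1L]] <-
            data.frame(protein_a = prot[m[, 1]], protein_b = prot[m[, 2]],
                       context = ci, label = lb)
      }
    }
    newdata <- do.call(rbind, rows)
  }
  key <- paste(idx$protein, idx$context)
  ia <- match(paste(newdata$protein_a, newdata$context), key)
  ib <- match(paste(newdata$protein_b, newdata$context), key)
  if (anyNA(ia) || anyNA(ib)) stop("unknown (protein, context) pair in newdata")
  newdata$probability <- decode_edge(Z[idx$node_id[ia], , drop = FALSE], rel,
                                     Z[idx$node_id[ib], , drop = FALSE])
  newdata
}

#' @export
residuals.contextppi <- function(object, ...) {
  pr <- predict(object)
  pr$label - pr$probability
}

#' @export
plot.contextppi <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$log$epoch, x$log$total, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "objective")
  ev <- x$log[!is.na(x$log$val_auroc), ]
  graphics::plot(ev$epoch, ev$val_auroc, type = "b", xlab = "epoch",
                 ylab = "validation AUROC", main = "model selection")
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
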