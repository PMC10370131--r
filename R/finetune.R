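# Target-prioritization fine-tuning: leakage-free label splitting at the
# protein-identity level, an MLP head over contextualized embeddings, and
# per-context ranking of candidate targets.

#' Split target labels without protein-identity leakage
#'
#' Proteins (not their context-specific representations) are assigned to
#' train/validation/test, so that every representation of a protein shares
#' its split. A greedy repair pass then reassigns proteins so that each
#' context has at least one positive in every split where feasible
#' (contexts are visited in order of ascending positive count; contexts
#' with no positives at all are excluded with a warning). The achieved
#' fractions may therefore deviate from the requested ratios.
#'
#' @param labels Data frame with `protein` and `label` (0/1).
#' @param graph An [multiscale_graph()]; labeled proteins absent from every
#'   context are dropped with a warning.
#' @param ratios Length-3 numeric summing to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param seed Integer seed.
#' @return An object of class `"target_labels"`: data frame `protein`,
#'   `label`, `split`.
#' @export
split_targets <- function(labels, graph, ratios = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  stopifnot(sum(labels$label == 1) >= 1, sum(labels$label == 0) >= 1)
  set.seed(seed)
  known <- labels$protein %in% graph$node_index$protein
  if (any(!known)) {
    warning(sum(!known), " labeled protein(s) absent from every context; dropped")
    labels <- labels[known, , drop = FALSE]
  }
  labels <- labels[!duplicated(labels$protein), , drop = FALSE]
  n <- nrow(labels)
  base <- floor(n * ratios)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * ratios - base
    give <- order(-frac, seq_along(ratios))[seq_len(rem)]
    base[give] <- base[give] + 1L
  }
  split <- rep(c("train", "val", "test"), base)[sample.int(n)]
  out <- data.frame(protein = labels$protein, label = labels$label,
                    split = split, stringsAsFactors = FALSE)

  # greedy coverage repair: each context should see >= 1 positive per split
  ctx_prot <- lapply(graph$contexts, `[[`, "nodes")
  pos_per_ctx <- vapply(ctx_prot, function(p) {
    sum(out$label == 1 & out$protein %in% p)
  }, integer(1))
  no_pos <- names(pos_per_ctx)[pos_per_ctx == 0]
  if (length(no_pos)) {
    warning("context(s) without any positive label, excluded from coverage: ",
            paste(no_pos, collapse = ", "))
  }
  for (ci in names(sort(pos_per_ctx[pos_per_ctx > 0]))) {
    pool <- out$protein %in% ctx_prot[[ci]] & out$label == 1
    if (sum(pool) < 3) next  # cannot cover three splits
    for (sp in c("train", "val", "test")) {
      if (any(pool & out$split == sp)) next
      # move a positive from the best-represented split of this context
      counts <- table(factor(out$split[pool], levels = c("train", "val", "test")))
      donor_sp <- names(counts)[which.max(counts)]
      cand <- which(pool & out$split == donor_sp)
      out$split[cand[1]] <- sp
    }
  }
  structure(out, class = c("target_labels", "data.frame"))
}

#' Train the target-prioritization head
#'
#' A small feedforward classifier (input, one hidden layer, output) on the
#' per-(protein, context) embeddings, with layer normalization and dropout
#' between the input and hidden layers, trained with binary cross-entropy;
#' the checkpoint maximizing validation average precision is kept.
#'
#' @param fit A fitted [contextppi] model (or a list with `protein`
#'   embeddings and `index` as in its `embeddings` slot).
#' @param targets A [split_targets()] result.
#' @param hidden Hidden widths (input projection, hidden layer).
#' @param epochs,lr,dropout,weight_decay Optimization settings.
#' @param seed Integer seed.
#' @return An object of class `"target_head"` with `predictions` (data
#'   frame `protein`, `context`, `score`, `label`, `split`), `params`,
#'   `best_epoch`, `log`.
#' @export
train_target_head <- function(fit, targets, hidden = c(32, 16), epochs = 150,
                              lr = 0.001, dropout = 0.5, weight_decay = 1e-4,
                              seed = 1) {
  emb <- if (inherits(fit, "contextppi")) fit$embeddings else fit
  stopifnot(inherits(targets, "target_labels"))
  set.seed(seed)
  idx <- emb$index
  rows <- merge(idx, targets, by = "protein")
  if (!nrow(rows)) stop("no labeled protein has an embedding")
  if (!any(rows$split == "train")) stop("empty training split")
  X <- emb$protein[rows$node_id, , drop = FALSE]
  y <- rows$label
  d <- ncol(X)

  p <- list(W1 = .glorot(d, hidden[1]), b1 = matrix(0, 1, hidden[1]),
            g1 = matrix(1, 1, hidden[1]), be1 = matrix(0, 1, hidden[1]),
            W2 = .glorot(hidden[1], hidden[2]), b2 = matrix(0, 1, hidden[2]),
            W3 = .glorot(hidden[2], 1), b3 = matrix(0, 1, 1))
  opt <- adam_new(p, stats::setNames(rep(lr, length(p)), names(p)))

  head_forward <- function(tp, P, X, training) {
    h <- ad_add(tp, ad_mm(tp, ad_leaf(tp, X), P("W1")), P("b1"))
    h <- ad_relu(tp, h)
    h <- ad_layernorm(tp, h, P("g1"), P("be1"))
    if (training && dropout > 0) {
      keep <- 1 - dropout
      m <- matrix(stats::rbinom(length(h$value), 1, keep) / keep,
                  nrow(h$value), ncol(h$value))
      h <- ad_dropout(tp, h, m)
    }
    h <- ad_relu(tp, ad_add(tp, ad_mm(tp, h, P("W2")), P("b2")))
    ad_add(tp, ad_mm(tp, h, P("W3")), P("b3"))   # logits
  }

  tr <- rows$split == "train"; va <- rows$split == "val"
  best <- list(ap = -Inf, params = p, epoch = NA_integer_)
  log_rows <- list()
  for (epoch in seq_len(epochs)) {
    tp <- tape_new()
    cache <- new.env(parent = emptyenv())
    P <- function(nm) {
      if (is.null(cache[[nm]])) cache[[nm]] <- ad_leaf(tp, p[[nm]], name = nm)
      cache[[nm]]
    }
    logits <- head_forward(tp, P, X[tr, , drop = FALSE], TRUE)
    loss <- .ad_bce_logits(tp, logits, y[tr])
    grads <- ad_backward(tp, loss)
    p <- adam_step(opt, p, grads, weight_decay, c("g1", "be1", "b1", "b2", "b3"))
    ap <- NA_real_
    if (epoch %% 5 == 0 || epoch == epochs) {
      sc <- .head_scores(p, X[va, , drop = FALSE], hidden)
      ap <- if (length(unique(y[va])) == 2) .average_precision(sc, y[va]) else NA_real_
      if (!is.na(ap) && ap > best$ap) best <- list(ap = ap, params = p, epoch = epoch)
    }
    log_rows[[epoch]] <- c(epoch = epoch, loss = loss$value[1], val_ap = ap)
  }
  if (is.na(best$epoch)) best <- list(ap = NA_real_, params = p, epoch = epochs)

  scores <- .head_scores(best$params, X, hidden)
  predictions <- data.frame(protein = rows$protein, context = rows$context,
                            score = scores, label = rows$label,
                            split = rows$split, stringsAsFactors = FALSE)
  structure(list(predictions = predictions, params = best$params,
                 best_epoch = best$epoch,
                 log = as.data.frame(do.call(rbind, log_rows))),
            class = "target_head")
}

.head_scores <- function(p, X, hidden) {
  if (nrow(X) == 0) return(numeric(0))
  h <- pmax(X %*% p$W1 + matrix(p$b1, nrow(X), hidden[1], byrow = TRUE), 0)
  mu <- rowMeans(h); s <- sqrt(rowMeans((h - mu)^2) + 1e-5)
  h <- (h - mu) / s * matrix(p$g1, nrow(X), hidden[1], byrow = TRUE) +
    matrix(p$be1, nrow(X), hidden[1], byrow = TRUE)
  h <- pmax(h %*% p$W2 + matrix(p$b2, nrow(X), hidden[2], byrow = TRUE), 0)
  as.numeric(stats::plogis(h %*% p$W3 + p$b3[1]))
}

# Area under the precision-recall curve in the average-precision form.
.average_precision <- function(scores, labels) {
  o <- order(-scores)
  lab <- labels[o]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec * lab) / sum(lab)
}

#' Rank cell-type contexts by test-set APR@K
#'
#' @param predictions Prediction table from [train_target_head()] (or any
#'   data frame with `protein`, `context`, `score`, `label`, and optionally
#'   `split`, in which case only test rows are used). A list of tables
#'   (e.g. from multiple seeds) is averaged per context.
#' @param K Cutoff for [apr_at_k()].
#' @return Data frame `context`, `apr` ordered by decreasing APR@K;
#'   contexts without test positives are omitted with a warning.
#' @export
rank_contexts <- function(predictions, K = 5) {
  tables <- if (is.data.frame(predictions)) list(predictions) else predictions
  per_seed <- lapply(tables, function(df) {
    if ("split" %in% names(df)) df <- df[df$split == "test", , drop = FALSE]
    out <- lapply(split(df, df$context), function(dd) {
      if (sum(dd$label == 1) == 0) return(NULL)
      dd <- dd[order(-dd$score, dd$protein), ]
      data.frame(context = dd$context[1],
                 apr = apr_at_k(dd$label, min(K, nrow(dd))))
    })
    dropped <- names(out)[vapply(out, is.null, logical(1))]
    if (length(dropped)) {
      warning("context(s) without test positives omitted: ",
              paste(dropped, collapse = ", "))
    }
    do.call(rbind, out)
  })
  merged <- do.call(rbind, per_seed)
  agg <- stats::aggregate(apr ~ context, merged, mean)
  agg <- agg[order(-agg$apr, agg$context), ]
  rownames(agg) <- NULL
  agg
}

#' Rank contexts for a single protein by head score
#'
#' @param predictions Prediction table (as in [rank_contexts()]).
#' @param protein Protein identity.
#' @return Data frame `context`, `score` in decreasing score order.
#' @export
rank_contexts_for_protein <- function(predictions, protein) {
  df <- predictions[predictions$protein == protein, , drop = FALSE]
  if (!nrow(df)) stop("unknown protein: ", protein)
  df <- df[order(-df$score, df$context), c("context", "score")]
  rownames(df) <- NULL
  df
}
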