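#' Assemble the training-ready multi-scale graph
#'
#' Gives every (protein, context) pair its own node id while recording the
#' underlying protein identity, and attaches the metagraph. Initial features
#' are added separately with [init_protein_features()].
#'
#' @param contexts Named list of context networks (each with `nodes`,
#'   `edges`), e.g. from [synth_multiscale_graph()] or
#'   [build_context_network()].
#' @param metagraph A [build_metagraph()] result covering the same contexts.
#' @return An object of class `"ms_graph"` with fields `contexts` (per
#'   context: `nodes`, `edges`, `node_ids`, `edge_idx` as a 2-column matrix
#'   of node ids), `metagraph`, `node_index` (data frame `protein`,
#'   `context`, `node_id`), `identities`, `n_nodes`, and `features` (NULL
#'   until initialized).
#' @export
multiscale_graph <- function(contexts, metagraph) {
  stopifnot(length(contexts) >= 1)
  if (is.null(names(contexts)) || any(names(contexts) == "")) {
    names(contexts) <- vapply(contexts, function(x) x$context_id, character(1))
  }
  stopifnot(all(names(contexts) %in% metagraph$cell_types))
  offset <- 0L
  node_index <- list()
  ctx_out <- list()
  for (ci in names(contexts)) {
    cx <- contexts[[ci]]
    nodes <- sort(cx$nodes)
    ids <- offset + seq_along(nodes)
    names(ids) <- nodes
    ei <- cbind(ids[cx$edges$protein_a], ids[cx$edges$protein_b])
    stopifnot(!anyNA(ei))
    ctx_out[[ci]] <- list(context_id = ci, nodes = nodes,
                          edges = cx$edges, node_ids = ids,
                          edge_idx = unname(ei))
    node_index[[ci]] <- data.frame(protein = nodes, context = ci,
                                   node_id = unname(ids), stringsAsFactors = FALSE)
    offset <- offset + length(nodes)
  }
  node_index <- do.call(rbind, node_index)
  rownames(node_index) <- NULL
  structure(list(contexts = ctx_out, metagraph = metagraph,
                 node_index = node_index,
                 identities = sort(unique(node_index$protein)),
                 n_nodes = offset, features = NULL),
            class = "ms_graph")
}

#' Initialize protein features
#'
#' Every distinct protein identity receives one standard-normal vector,
#' reused at each of its (protein, context) nodes so that a protein keeps
#' its identity across contexts.
#'
#' @param graph An [multiscale_graph()] object.
#' @param d_in Feature dimension (1024 at atlas scale).
#' @param seed Integer seed.
#' @return The graph with a `features` matrix (identities x `d_in`,
#'   rownames = protein identities).
#' @export
init_protein_features <- function(graph, d_in = 1024, seed = 1) {
  stopifnot(inherits(graph, "ms_graph"), d_in >= 1)
  set.seed(seed)
  f <- matrix(stats::rnorm(length(graph$identities) * d_in),
              nrow = length(graph$identities),
              dimnames = list(graph$identities, NULL))
  graph$features <- f
  graph
}

#' Split protein-protein edges into train / validation / test
#'
#' Edges are split uniformly at random per context at the given ratios;
#' remainders go to the split with the largest fractional share (train
#' first on ties). Metagraph edges are never split. A context with fewer
#' edges than splits keeps everything in train, with a warning. Frozen
#' negative non-edges of matching cardinality are attached to every split.
#'
#' @param graph An [multiscale_graph()] object.
#' @param ratios Length-3 numeric summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed (also freezes the validation/test negatives).
#' @return An object of class `"edge_split"`: per context, a list with
#'   `train`, `val`, `test` (2-column node-id matrices) and `negatives`
#'   (same structure).
#' @export
split_edges <- function(graph, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(inherits(graph, "ms_graph"), length(ratios) == 3,
            abs(sum(ratios) - 1) < 1e-8, all(ratios >= 0))
  set.seed(seed)
  out <- list()
  for (ci in names(graph$contexts)) {
    ei <- graph$contexts[[ci]]$edge_idx
    n <- nrow(ei)
    if (n < 3) {
      warning("context ", ci, " has fewer edges than splits; all assigned to train")
      counts <- c(n, 0L, 0L)
    } else {
      base <- floor(n * ratios)
      rem <- n - sum(base)
      if (rem > 0) {
        frac <- n * ratios - base
        give <- order(-frac, seq_along(ratios))[seq_len(rem)]
        base[give] <- base[give] + 1L
      }
      counts <- base
    }
    perm <- sample.int(n)
    lab <- rep(c("train", "val", "test"), counts)
    sp <- list(train = ei[perm[lab == "train"], , drop = FALSE],
               val   = ei[perm[lab == "val"], , drop = FALSE],
               test  = ei[perm[lab == "test"], , drop = FALSE])
    sp$negatives <- lapply(sp, function(pos) {
      sample_negatives(graph, pos, ci)
    })
    out[[ci]] <- sp
  }
  structure(out, class = "edge_split")
}

#' Sample negative (non-)edges within a context
#'
#' For each positive edge (u, v), draws a node w of the same context with
#' (u, w) not an edge of that context, by rejection against the full edge
#' set (falling back to corrupting v when u is saturated). The positive to
#' negative ratio is 1:1 by default.
#'
#' @param graph An [multiscale_graph()] object.
#' @param positives 2-column matrix of node ids (edges of `context`).
#' @param context Context id.
#' @param ratio Negatives per positive.
#' @param seed Optional integer seed; when NULL the current RNG state is used
#'   (so per-epoch resampling stays under the trainer's seed).
#' @return 2-column matrix of node-id non-edges.
#' @export
sample_negatives <- function(graph, positives, context, ratio = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cx <- graph$contexts[[context]]
  stopifnot(!is.null(cx))
  ids <- unname(cx$node_ids)
  n <- length(ids)
  if (nrow(cx$edge_idx) >= n * (n - 1) / 2) stop("no negatives available: complete graph")
  adj <- .adjacency_sets(cx$edge_idx, ids)
  if (nrow(positives) == 0 || ratio <= 0) return(matrix(integer(0), 0, 2))
  src <- rep(positives[, 1], ratio)
  alt <- rep(positives[, 2], ratio)
  out <- matrix(0L, length(src), 2)
  for (k in seq_along(src)) {
    u <- src[k]
    cand <- setdiff(ids, c(adj[[as.character(u)]], u))
    if (length(cand) == 0) {
      u <- alt[k]
      cand <- setdiff(ids, c(adj[[as.character(u)]], u))
      if (length(cand) == 0) stop("no negatives available for edge ", k)
    }
    out[k, ] <- c(u, cand[sample.int(length(cand), 1L)])
  }
  out
}

.adjacency_sets <- function(edge_idx, ids) {
  adj <- stats::setNames(vector("list", length(ids)), as.character(ids))
  if (nrow(edge_idx) > 0) {
    a <- split(edge_idx[, 2], edge_idx[, 1])
    b <- split(edge_idx[, 1], edge_idx[, 2])
    for (nm in names(a)) adj[[nm]] <- c(adj[[nm]], a[[nm]])
    for (nm in names(b)) adj[[nm]] <- c(adj[[nm]], b[[nm]])
  }
  adj
}

#' Serialize an edge split as a TSV
#'
#' Writes one row per positive and negative edge with columns
#' `src`, `dst`, `context`, `split`, `label`.
#'
#' @param split An [split_edges()] result.
#' @param graph The graph it was computed on.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_edge_split <- function(split, graph, path) {
  prot <- graph$node_index$protein[order(graph$node_index$node_id)]
  rows <- list()
  for (ci in names(split)) {
    for (sp in c("train", "val", "test")) {
      pos <- split[[ci]][[sp]]
      neg <- split[[ci]]$negatives[[sp]]
      if (nrow(pos)) rows[[length(rows) + 1L]] <-
          data.frame(src = prot[pos[, 1]], dst = prot[pos[, 2]],
                     context = ci, split = sp, label = 1L)
      if (nrow(neg)) rows[[length(rows) + 1L]] <-
          data.frame(src = prot[neg[, 1]], dst = prot[neg[, 2]],
                     context = ci, split = sp, label = 0L)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
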