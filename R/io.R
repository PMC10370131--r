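# Plain-text readers and writers for the formats the pipeline exchanges:
# MTX + TSV expression bundles, edge-list TSVs, typed metagraph TSVs, and
# embedding tables.

#' Write an expression bundle (MTX + gene / cell metadata TSVs)
#'
#' @param expr List with `counts` (gene x cell sparse matrix) and `cell_meta`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(expr$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = rownames(expr$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression bundle written by [write_expression()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A list with `counts`, `genes`, `cell_meta`.
#' @export
read_expression <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)$gene
  cell_meta <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, cell_meta$cell_id)
  list(counts = counts, genes = genes, cell_meta = cell_meta)
}

#' Read / write a two-column protein edge list TSV
#'
#' @param path File path.
#' @return `read_edge_tsv`: data frame with `protein_a`, `protein_b`.
#' @export
read_edge_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param edges Data frame with two character columns.
#' @rdname read_edge_tsv
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write context networks as per-context edge-list TSVs
#'
#' @param contexts Named list of context networks (`nodes`, `edges`).
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_context_networks <- function(contexts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ci in names(contexts)) {
    write_edge_tsv(contexts[[ci]]$edges, file.path(dir, paste0(ci, ".edges.tsv")))
  }
  invisible(dir)
}

#' Write a metagraph as a typed edge TSV (src, dst, edge_type)
#'
#' Edge types are `cc` (cell-cell), `ct` (cell-tissue) and `tt`
#' (tissue-tissue, child to parent).
#'
#' @param mg A [build_metagraph()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_metagraph <- function(mg, path) {
  rows <- rbind(
    if (nrow(mg$cc_edges)) data.frame(src = mg$cc_edges$cell_type_a,
                                      dst = mg$cc_edges$cell_type_b, edge_type = "cc"),
    if (nrow(mg$ct_edges)) data.frame(src = mg$ct_edges$cell_type,
                                      dst = mg$ct_edges$tissue, edge_type = "ct"),
    if (nrow(mg$tt_edges)) data.frame(src = mg$tt_edges$child,
                                      dst = mg$tt_edges$parent, edge_type = "tt"))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor significance table
#'
#' @param path TSV with columns `cell_type_a`, `cell_type_b`, `p_value`.
#' @return Data frame.
#' @export
read_lr_table <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Read a tissue ontology TSV (child, parent)
#'
#' @param path File path.
#' @return Data frame with `child`, `parent`.
#' @export
read_ontology <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Read a target label TSV (protein, label)
#'
#' @param path File path.
#' @return Data frame with `protein` (character) and `label` (0/1 integer).
#' @export
read_target_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "label") %in% names(df)),
            all(df$label %in% c(0L, 1L)))
  df
}
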