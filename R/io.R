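#' Write an expression matrix to disk
#'
#' Sparse MatrixMarket (`matrix.mtx` + `genes.tsv` + `cells.tsv`) or a
#' single dense TSV with gene ids in the first column.
#'
#' @param m an [expression_matrix()].
#' @param dir output directory (created if missing).
#' @param format `"mtx"` or `"tsv"`.
#' @return the directory, invisibly.
#' @export
write_expression <- function(m, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass(m), sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "cells.tsv"))
  } else {
    df <- data.frame(gene_id = rownames(m), unclass(m), check.names = FALSE)
    utils::write.table(df, file.path(dir, "matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(expr_scale(m), file.path(dir, "scale.txt"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param dir directory holding the files.
#' @param scale override the recorded scale tag.
#' @return an `expr_mat`.
#' @export
read_expression <- function(dir, scale = NULL) {
  scale_file <- file.path(dir, "scale.txt")
  scale <- scale %||% if (file.exists(scale_file)) readLines(scale_file) else "tpm"
  if (file.exists(file.path(dir, "matrix.mtx"))) {
    x <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
    rownames(x) <- readLines(file.path(dir, "genes.tsv"))
    colnames(x) <- readLines(file.path(dir, "cells.tsv"))
  } else {
    df <- utils::read.table(file.path(dir, "matrix.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE)
    x <- as.matrix(df[, -1, drop = FALSE])
    rownames(x) <- df[[1]]
  }
  expression_matrix(x, scale = scale)
}

#' Write gene annotation as a BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `gene_id` (0-based half-open), plus
#' `arm` when present.
#'
#' @param genes annotation tibble (`gene_id`, `chrom`, `start`, `end`, ...).
#' @param path output file.
#' @export
write_gene_annotation <- function(genes, path) {
  cols <- intersect(c("chrom", "start", "end", "gene_id", "arm"),
                    names(genes))
  utils::write.table(genes[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene annotation TSV
#'
#' @param path file written by [write_gene_annotation()] (or any TSV with a
#'   header naming `chrom`, `start`, `end`, `gene_id`).
#' @return tibble.
#' @export
read_gene_annotation <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
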