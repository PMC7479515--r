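#' Log-transform TPM expression
#'
#' Computes E = log2(TPM/10 + 1). TPM values are divided by 10 before the
#' log because full-length single-cell libraries sample on the order of
#' 100,000 transcripts, so TPM overstates the counting depth tenfold.
#'
#' @param m an [expression_matrix()] on the `"tpm"` scale.
#' @return an `expr_mat` on the `"log"` scale.
#' @export
log_transform <- function(m) {
  assert_scale(m, "tpm", "log_transform()")
  if (any(m < 0)) stop("TPM values must be non-negative", call. = FALSE)
  restamp(log2(unclass(m) / 10 + 1), m, scale = "log")
}

#' Quality-control filter for full-length (Smart-seq2-like) cells
#'
#' Removes cells with fewer than `min_genes` detected genes (TPM > 0) or a
#' mean housekeeping expression (on the E scale) below `min_hk`.
#'
#' @param m `expr_mat` on the `"tpm"` scale.
#' @param housekeeping_genes character vector of housekeeping gene ids; the
#'   intersection with the matrix rows is used.
#' @param min_genes minimum detected genes per cell (default 2000).
#' @param min_hk minimum mean housekeeping E per cell (default 2.5).
#' @return list with `matrix` (filtered `expr_mat`) and `qc`, a tibble with
#'   one row per input cell: `cell_id`, `n_detected`, `mean_hk`, `pass`,
#'   `reason`.
#' @export
qc_filter_smartseq <- function(m, housekeeping_genes,
                               min_genes = 2000, min_hk = 2.5) {
  assert_scale(m, "tpm", "qc_filter_smartseq()")
  hk <- intersect(housekeeping_genes, rownames(m))
  if (length(hk) == 0L) {
    stop("no housekeeping genes found in the matrix", call. = FALSE)
  }
  n_detected <- colSums(unclass(m) > 0)
  mean_hk <- colMeans(log2(unclass(m)[hk, , drop = FALSE] / 10 + 1))
  pass_genes <- n_detected >= min_genes
  pass_hk <- mean_hk >= min_hk
  reason <- dplyr::case_when(
    !pass_genes & !pass_hk ~ "low_genes;low_housekeeping",
    !pass_genes ~ "low_genes",
    !pass_hk ~ "low_housekeeping",
    TRUE ~ NA_character_
  )
  qc <- tibble::tibble(
    cell_id = colnames(m),
    n_detected = as.integer(n_detected),
    mean_hk = unname(mean_hk),
    pass = pass_genes & pass_hk,
    reason = reason
  )
  keep <- qc$cell_id[qc$pass]
  list(matrix = restamp(unclass(m)[, keep, drop = FALSE], m), qc = qc)
}

#' Remove lowly expressed genes
#'
#' A gene is retained iff it has TPM above `min_tpm` in at least
#' `min_cells` cells.
#'
#' @inheritParams qc_filter_smartseq
#' @param min_tpm expression threshold defining "expressed" (default 10).
#' @param min_cells minimum number of expressing cells (default 10).
#' @return filtered `expr_mat`.
#' @export
filter_genes <- function(m, min_tpm = 10, min_cells = 10) {
  assert_scale(m, "tpm", "filter_genes()")
  keep <- rowSums(unclass(m) > min_tpm) >= min_cells
  restamp(unclass(m)[keep, , drop = FALSE], m)
}

#' Per-gene aggregate expression
#'
#' Ea(i) = log2(mean(TPM_i) + 1), the population-level expression of each
#' gene. Used downstream to match control genes of comparable expression.
#'
#' @inheritParams qc_filter_smartseq
#' @return tibble with `gene_id` and `ea`.
#' @export
aggregate_expression <- function(m) {
  assert_scale(m, "tpm", "aggregate_expression()")
  if (ncol(m) == 0L) stop("matrix has no cells", call. = FALSE)
  tibble::tibble(gene_id = rownames(m),
                 ea = log2(rowMeans(unclass(m)) + 1))
}

#' Center log expression per gene
#'
#' Relative expression Er = E - mean(E), computed per gene within each
#' centering group (typically one anatomical compartment). With
#' `group = NULL` all cells form one group, which is also how scores are
#' re-centered across compartments for pan-compartment comparisons.
#'
#' @param m `expr_mat` on the `"log"` scale.
#' @param group optional per-cell grouping factor; defaults to the matrix
#'   compartment labels if present, otherwise a single group.
#' @return `expr_mat` on the `"centered"` scale.
#' @export
center_expression <- function(m, group = NULL) {
  assert_scale(m, "log", "center_expression()")
  group <- group %||% attr(m, "compartment") %||% rep("all", ncol(m))
  group <- as.character(group)
  vals <- unclass(m)
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) == 1L) {
      message("centering group '", g, "' has a single cell; its values become 0")
    }
    vals[, idx] <- vals[, idx, drop = FALSE] -
      rowMeans(vals[, idx, drop = FALSE])
  }
  restamp(vals, m, scale = "centered")
}

#' Quality-control filter for UMI (10X-like) cells
#'
#' Retains cells whose detected-gene count lies within `[mean/2, 2*mean]`
#' of the pre-filter mean across cells and whose mitochondrial UMI fraction
#' is at most `max_mito`.
#'
#' @param counts `expr_mat` on the `"umi"` scale.
#' @param mito_genes character vector of mitochondrial gene ids, or a
#'   regular expression prefix (e.g. `"^MT-"`) matched against rownames.
#' @param max_mito maximum mitochondrial fraction (default 0.05).
#' @return list with `matrix` and `qc` tibble (`cell_id`, `n_detected`,
#'   `mito_frac`, `pass`, `reason`).
#' @export
qc_filter_umi <- function(counts, mito_genes = "^MT-", max_mito = 0.05) {
  assert_scale(counts, "umi", "qc_filter_umi()")
  vals <- unclass(counts)
  if (length(mito_genes) == 1L && !mito_genes %in% rownames(vals)) {
    mito <- grep(mito_genes, rownames(vals), value = TRUE)
  } else {
    mito <- intersect(mito_genes, rownames(vals))
  }
  n_detected <- colSums(vals > 0)
  mu <- mean(n_detected)
  pass_genes <- n_detected >= mu / 2 & n_detected <= 2 * mu
  if (length(mito) == 0L) {
    warning("no mitochondrial genes found; skipping the mito-fraction rule")
    mito_frac <- rep(NA_real_, ncol(vals))
    pass_mito <- rep(TRUE, ncol(vals))
  } else {
    mito_frac <- colSums(vals[mito, , drop = FALSE]) / pmax(colSums(vals), 1)
    pass_mito <- mito_frac <= max_mito
  }
  reason <- dplyr::case_when(
    !pass_genes & !pass_mito ~ "gene_count;high_mito",
    !pass_genes ~ "gene_count",
    !pass_mito ~ "high_mito",
    TRUE ~ NA_character_
  )
  qc <- tibble::tibble(
    cell_id = colnames(vals),
    n_detected = as.integer(n_detected),
    mito_frac = unname(mito_frac),
    pass = pass_genes & pass_mito,
    reason = reason
  )
  keep <- qc$cell_id[qc$pass]
  list(matrix = restamp(vals[, keep, drop = FALSE], counts), qc = qc)
}
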