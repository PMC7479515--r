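#' Pairwise correlation of program scores
#'
#' Pearson correlation between program score vectors over a common cell
#' set (typically scores computed after re-centering expression across all
#' compartments), with a Ward dendrogram ordering on 1 - r for display.
#' Zero-variance score vectors yield `NA` correlations and are reported as
#' missing.
#'
#' @param scores wide score tibble (`cell_id` plus program columns).
#' @return object of class `program_correlation`: list with `r`
#'   (programs x programs matrix), `order` (display order).
#' @export
correlate_program_scores <- function(scores) {
  programs <- setdiff(names(scores), "cell_id")
  m <- as.matrix(scores[programs])
  r <- suppressWarnings(stats::cor(m))
  dimnames(r) <- list(programs, programs)
  diag(r) <- 1
  r_fill <- r
  r_fill[is.na(r_fill)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - r_fill), method = "ward.D2")
  structure(list(r = r, order = programs[hc$order]),
            class = "program_correlation")
}

#' @export
print.program_correlation <- function(x, ...) {
  cat(sprintf("<program_correlation> %d programs\n", nrow(x$r)))
  invisible(x)
}

#' Correlate population profiles with reference cell-type profiles
#'
#' Pearson correlation between each population's median expression profile
#' and each reference profile, restricted to a pooled list of
#' population-specific signature genes so shared housekeeping structure
#' does not dominate. Genes missing from either side are dropped pairwise
#' with a message.
#'
#' @param populations genes x populations profile matrix.
#' @param references genes x references profile matrix (e.g. median
#'   profiles of atlas cell types, user-supplied).
#' @param genes pooled signature gene ids used for the correlation.
#' @return tibble: `population`, `reference`, `r`, `n_genes`.
#' @export
correlate_profiles <- function(populations, references, genes) {
  shared <- Reduce(intersect, list(genes, rownames(populations),
                                   rownames(references)))
  dropped <- length(genes) - length(shared)
  if (dropped > 0) message(dropped, " pooled gene(s) missing from a profile set")
  if (length(shared) < 3) stop("fewer than 3 shared genes", call. = FALSE)
  r <- stats::cor(populations[shared, , drop = FALSE],
                  references[shared, , drop = FALSE])
  tibble::as_tibble(r, rownames = "population") |>
    tidyr::pivot_longer(-"population", names_to = "reference",
                        values_to = "r") |>
    dplyr::mutate(n_genes = length(shared))
}

#' Classify genes as shared or tumor-type specific
#'
#' Given per-gene aggregated log2 expression in two tumor types, a gene is
#' `common` if it exceeds `expr_min` in both (this rule takes precedence),
#' `a_specific` if it exceeds `expr_min` in A and A - B exceeds
#' `diff_min`, `b_specific` symmetrically, and `none` otherwise.
#'
#' @param expr tibble/data.frame with columns `gene_id`, `a`, `b`
#'   (aggregated log2 expression in tumor types A and B).
#' @param expr_min expression floor (default 3).
#' @param diff_min specificity margin (default 2).
#' @return the input with a `class` column in
#'   {common, a_specific, b_specific, none}.
#' @export
shared_specific_genes <- function(expr, expr_min = 3, diff_min = 2) {
  stopifnot(all(c("gene_id", "a", "b") %in% names(expr)))
  tibble::as_tibble(expr) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$a > expr_min & .data$b > expr_min ~ "common",
      .data$a > expr_min & .data$a - .data$b > diff_min ~ "a_specific",
      .data$b > expr_min & .data$b - .data$a > diff_min ~ "b_specific",
      TRUE ~ "none"
    ))
}
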