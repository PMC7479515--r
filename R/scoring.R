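#' Expression-matched control gene sets for a signature
#'
#' For each signature gene, picks the `n_control` genes whose aggregate
#' expression Ea is closest to that gene's (excluding the gene itself, ties
#' broken by gene id). Scoring against these controls cancels the
#' cell-complexity component of a raw mean, so a random gene set scores
#' about zero in every cell.
#'
#' @param ea aggregate-expression tibble from [aggregate_expression()]
#'   (columns `gene_id`, `ea`).
#' @param signature character vector of signature gene ids.
#' @param n_control control genes per signature gene (default 100; capped
#'   at universe size minus one).
#' @return named list mapping each signature gene to its control genes.
#' @export
build_control_sets <- function(ea, signature, n_control = 100) {
  missing_genes <- setdiff(signature, ea$gene_id)
  if (length(missing_genes)) {
    stop("signature genes absent from the universe: ",
         paste(utils::head(missing_genes, 3), collapse = ", "), call. = FALSE)
  }
  universe <- ea$gene_id
  vals <- stats::setNames(ea$ea, universe)
  n_control <- min(n_control, length(universe) - 1L)
  out <- lapply(signature, function(g) {
    d <- abs(vals - vals[[g]])
    d <- d[names(d) != g]
    names(d)[order(d, names(d), method = "radix")][seq_len(n_control)]
  })
  stats::setNames(out, signature)
}

#' Control-matched signature score per cell
#'
#' SC(i) = mean(Er over signature genes) - mean(Er over pooled control
#' genes). Controls of all signature genes are concatenated with
#' multiplicity (the pooled control set is `n_control`-fold larger than the
#' signature), which equals averaging per-gene paired differences.
#'
#' @param er `expr_mat` on the `"centered"` scale.
#' @param signature character vector of signature gene ids.
#' @param controls control map from [build_control_sets()]; built on the
#'   fly from `ea` if omitted.
#' @param ea aggregate expression (required when `controls` is missing).
#' @return tibble with `cell_id` and `score`.
#' @export
score_cells <- function(er, signature, controls = NULL, ea = NULL) {
  assert_scale(er, "centered", "score_cells()")
  if (length(signature) == 0) stop("empty signature", call. = FALSE)
  signature <- intersect(signature, rownames(er))
  if (length(signature) == 0) {
    stop("no signature genes present in the matrix", call. = FALSE)
  }
  if (is.null(controls)) {
    if (is.null(ea)) stop("supply `controls` or `ea`", call. = FALSE)
    controls <- build_control_sets(ea, signature)
  }
  pooled <- unlist(controls[signature], use.names = FALSE)
  sig_mean <- colMeans(unclass(er)[signature, , drop = FALSE])
  ctrl_mean <- colMeans(unclass(er)[pooled, , drop = FALSE])
  tibble::tibble(cell_id = colnames(er),
                 score = unname(sig_mean - ctrl_mean))
}

#' Score cells for many signatures at once
#'
#' @inheritParams score_cells
#' @param signatures named list of gene-id vectors.
#' @param ea aggregate expression used to build control sets.
#' @param n_control control genes per signature gene.
#' @return tibble in wide form: `cell_id` plus one score column per
#'   signature.
#' @export
score_signatures <- function(er, signatures, ea, n_control = 100) {
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  out <- tibble::tibble(cell_id = colnames(er))
  for (nm in names(signatures)) {
    sig <- intersect(signatures[[nm]], rownames(er))
    controls <- build_control_sets(ea, sig, n_control)
    out[[nm]] <- score_cells(er, sig, controls)$score
  }
  out
}

#' Assign cells to states and call cycling status
#'
#' Each cell is assigned the metaprogram with its maximum score (ties
#' broken lexicographically and logged). A cell is cycling iff the larger
#' of its S and G2M scores strictly exceeds `cyc_threshold`.
#'
#' @param scores wide score tibble from [score_signatures()] (`cell_id`
#'   plus one column per program).
#' @param programs program columns eligible for assignment; defaults to
#'   all score columns except the cycling ones.
#' @param s_id,g2m_id names of the S-phase and G2M score columns; if either
#'   is absent, cycling is left `NA` with a message.
#' @param cyc_threshold cycling-call threshold (default 1, strict).
#' @return tibble: `cell_id`, `state`, `state_score`, `cycling`.
#' @export
assign_states <- function(scores, programs = NULL, s_id = "S", g2m_id = "G2M",
                          cyc_threshold = 1) {
  score_cols <- setdiff(names(scores), "cell_id")
  programs <- programs %||% setdiff(score_cols, c(s_id, g2m_id))
  if (length(programs) == 0) stop("no program columns to assign", call. = FALSE)
  m <- as.matrix(scores[programs])
  best <- apply(m, 1, function(v) {
    top <- which(v == max(v))
    top[order(programs[top])][1]
  })
  ties <- apply(m, 1, function(v) sum(v == max(v)) > 1)
  if (any(ties)) {
    message(sum(ties), " cell(s) had tied maximum scores; ",
            "lexicographic tie-break applied")
  }
  if (s_id %in% score_cols && g2m_id %in% score_cols) {
    cycling <- pmax(scores[[s_id]], scores[[g2m_id]]) > cyc_threshold
  } else {
    message("S/G2M scores missing; cycling left undefined")
    cycling <- rep(NA, nrow(scores))
  }
  tibble::tibble(
    cell_id = scores$cell_id,
    state = programs[best],
    state_score = m[cbind(seq_len(nrow(m)), best)],
    cycling = cycling
  )
}

#' Stem-cell and lineage scores
#'
#' The NSC score of a cell is its neural-stem-cell-like program score minus
#' the larger of its two differentiation-trajectory scores (glial-progenitor
#' and ependymal). Cells with NSC score <= 0 (non-stem-like) additionally
#' get a lineage score, glial minus ependymal: positive values lean glial,
#' negative ependymal.
#'
#' @param scores wide score tibble (`cell_id` plus score columns).
#' @param nsc_id,glial_id,ependymal_id names of the three program columns.
#' @return tibble: `cell_id`, `nsc_score`, `lineage_score` (`NA` for
#'   NSC-like cells).
#' @export
nsc_lineage <- function(scores, nsc_id = "NSC", glial_id = "glial",
                        ependymal_id = "ependymal") {
  need <- c(nsc_id, glial_id, ependymal_id)
  if (!all(need %in% names(scores))) {
    stop("missing program score column(s): ",
         paste(setdiff(need, names(scores)), collapse = ", "), call. = FALSE)
  }
  nsc <- scores[[nsc_id]] - pmax(scores[[glial_id]], scores[[ependymal_id]])
  lineage <- ifelse(nsc <= 0, scores[[glial_id]] - scores[[ependymal_id]],
                    NA_real_)
  tibble::tibble(cell_id = scores$cell_id,
                 nsc_score = nsc, lineage_score = lineage)
}
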