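#' Cluster cells on relative expression
#'
#' PCA on the centered matrix followed by Ward hierarchical clustering of
#' the leading principal components, cut into `k` clusters. Entirely
#' deterministic, so repeated runs give identical labels.
#'
#' @param er `expr_mat` on the `"centered"` scale.
#' @param k number of clusters.
#' @param n_pcs principal components retained (default 20, capped by the
#'   matrix dimensions).
#' @return tibble with `cell_id` and `cluster` (integer).
#' @export
cluster_cells <- function(er, k, n_pcs = 20) {
  assert_scale(er, "centered", "cluster_cells()")
  if (k > ncol(er)) stop("more clusters than cells", call. = FALSE)
  n_pcs <- min(n_pcs, ncol(er) - 1L, nrow(er))
  pc <- stats::prcomp(t(unclass(er)), center = FALSE, rank. = n_pcs)
  hc <- stats::hclust(stats::dist(pc$x), method = "ward.D2")
  tibble::tibble(cell_id = colnames(er),
                 cluster = unname(stats::cutree(hc, k = k)))
}

#' Label clusters expressing normal cell-type markers
#'
#' A cluster is labeled with normal type T iff the cluster mean of the
#' control-matched marker score for T exceeds `threshold` and exceeds the
#' cluster means of every other type (ties go to the larger mean; an exact
#' tie is broken lexicographically and logged). At most one type per
#' cluster; clusters below threshold for every type stay unlabeled.
#'
#' @param clusters tibble from [cluster_cells()] (`cell_id`, `cluster`).
#' @param marker_scores wide score tibble from [score_signatures()] with
#'   one column per normal cell type.
#' @param threshold minimum mean score (default 1).
#' @return tibble with `cluster`, `normal_type` (`NA` if unlabeled) and
#'   `mean_score`.
#' @export
label_normal_clusters <- function(clusters, marker_scores, threshold = 1) {
  types <- setdiff(names(marker_scores), "cell_id")
  joined <- dplyr::inner_join(clusters, marker_scores, by = "cell_id")
  means <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(types), mean),
                     .groups = "drop")
  m <- as.matrix(means[types])
  pick <- apply(m, 1, function(v) {
    if (max(v) <= threshold) return(NA_integer_)
    top <- which(v == max(v))
    if (length(top) > 1) message("tied marker means; lexicographic tie-break")
    top[order(types[top])][1]
  })
  tibble::tibble(
    cluster = means$cluster,
    normal_type = ifelse(is.na(pick), NA_character_, types[pick]),
    mean_score = apply(m, 1, max)
  )
}

#' Integrate CNA calls and marker clusters into malignancy labels
#'
#' Classification rules: a cell is *normal* if it sits in a normal-labeled
#' cluster and is CNA-negative; *malignant* if it is CNA-positive and not
#' in a normal-labeled cluster; cells with discordant evidence are
#' *excluded* — unless the cell's sample is in `override_samples`, in which
#' case CNA-negative cells outside normal clusters are rescued as malignant
#' (the rule used for samples whose tumor cells lack detectable CNAs).
#' CNA-positive cells inside a normal cluster remain excluded.
#'
#' @param clusters tibble (`cell_id`, `cluster`).
#' @param cluster_labels tibble from [label_normal_clusters()].
#' @param cna_calls tibble (`cell_id`, `cna_call` logical).
#' @param samples optional tibble (`cell_id`, `sample_id`); required when
#'   `override_samples` is non-empty.
#' @param override_samples character vector of sample ids whose
#'   CNA-negative non-marker cells are treated as malignant.
#' @return tibble: `cell_id`, `cluster`, `normal_type`, `cna_call`,
#'   `final_class` in {malignant, normal, excluded}, `override_applied`.
#' @export
classify_cells <- function(clusters, cluster_labels, cna_calls,
                           samples = NULL, override_samples = character()) {
  x <- clusters |>
    dplyr::left_join(cluster_labels[c("cluster", "normal_type")],
                     by = "cluster") |>
    dplyr::inner_join(cna_calls[c("cell_id", "cna_call")], by = "cell_id")
  if (nrow(x) != nrow(clusters)) {
    stop("every clustered cell needs a CNA call", call. = FALSE)
  }
  if (length(override_samples)) {
    if (is.null(samples)) {
      stop("`samples` is required to apply sample overrides", call. = FALSE)
    }
    x <- dplyr::left_join(x, samples[c("cell_id", "sample_id")],
                          by = "cell_id")
  } else {
    x$sample_id <- NA_character_
  }
  in_marker <- !is.na(x$normal_type)
  overridable <- x$sample_id %in% override_samples
  x |>
    dplyr::mutate(
      override_applied = !in_marker & !.data$cna_call & overridable,
      final_class = dplyr::case_when(
        in_marker & !.data$cna_call ~ "normal",
        !in_marker & .data$cna_call ~ "malignant",
        .data$override_applied ~ "malignant",
        TRUE ~ "excluded"
      )
    ) |>
    dplyr::select("cell_id", "cluster", "normal_type", "cna_call",
                  "final_class", "override_applied")
}
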