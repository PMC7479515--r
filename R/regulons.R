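#' Aggregate binarized regulon activity per cell state
#'
#' For each (state, regulon) pair, the average relative activity is the
#' proportion of the state's cells in which the regulon is active.
#'
#' @param activity binary cells x regulons matrix (rownames = cell ids).
#' @param assignments tibble (`cell_id`, `state`) covering all rows.
#' @return object of class `regulon_activity`: list with `activity`
#'   (states x regulons matrix of proportions) and `sizes` (named state
#'   sizes).
#' @export
aggregate_activity <- function(activity, assignments) {
  if (!all(activity %in% c(0, 1))) {
    stop("activity matrix must be binary", call. = FALSE)
  }
  missing_cells <- setdiff(rownames(activity), assignments$cell_id)
  if (length(missing_cells)) {
    stop("unlabeled cells in activity matrix: ",
         paste(utils::head(missing_cells, 3), collapse = ", "), call. = FALSE)
  }
  states <- stats::setNames(assignments$state, assignments$cell_id)
  lab <- states[rownames(activity)]
  agg <- rowsum(activity, lab) / as.vector(table(lab)[sort(unique(lab))])
  structure(list(activity = agg,
                 sizes = table(lab)[rownames(agg)]),
            class = "regulon_activity")
}

#' @export
print.regulon_activity <- function(x, ...) {
  cat(sprintf("<regulon_activity> %d states x %d regulons\n",
              nrow(x$activity), ncol(x$activity)))
  invisible(x)
}

#' Select state-specific transcription-factor regulons
#'
#' A regulon is specific to a state iff its average relative activity
#' there strictly exceeds `min_activity` and is at least `min_ratio` times
#' its activity in every other state. With `min_ratio > 1` a regulon can
#' be specific to at most one state.
#'
#' @param x a [aggregate_activity()] result (or a states x regulons
#'   matrix of proportions).
#' @param min_activity activity floor (default 0.5, strict).
#' @param min_ratio required fold over every other state (default 1.5,
#'   non-strict).
#' @return tibble: `state`, `regulon`, `activity`, `max_other`.
#' @export
select_specific_tfs <- function(x, min_activity = 0.5, min_ratio = 1.5) {
  a <- if (inherits(x, "regulon_activity")) x$activity else x
  if (nrow(a) < 2) warning("single state: the ratio rule is vacuous")
  out <- list()
  for (j in seq_len(ncol(a))) {
    for (i in seq_len(nrow(a))) {
      other <- a[-i, j]
      max_other <- if (length(other)) max(other) else 0
      if (a[i, j] > min_activity && a[i, j] >= min_ratio * max_other) {
        out[[length(out) + 1L]] <- tibble::tibble(
          state = rownames(a)[i], regulon = colnames(a)[j],
          activity = a[i, j], max_other = max_other
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(state = character(), regulon = character(),
                          activity = numeric(), max_other = numeric()))
  }
  dplyr::bind_rows(out)
}
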