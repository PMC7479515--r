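#' @importFrom generics tidy glance
NULL

#' Tidy an NMF fit into long gene weights
#'
#' @param x an `nmf_fit`.
#' @param ... unused.
#' @return tibble: `factor`, `gene_id`, `weight`.
#' @method tidy nmf_fit
#' @export
tidy.nmf_fit <- function(x, ...) {
  tibble::as_tibble(x$w, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "factor",
                        values_to = "weight") |>
    dplyr::arrange(.data$factor, dplyr::desc(.data$weight))
}

#' One-row summary of an NMF fit
#'
#' @inheritParams tidy.nmf_fit
#' @return tibble: `k`, `iters`, `loss`, `monotone` (was the objective
#'   non-increasing).
#' @method glance nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, iters = x$iters, loss = utils::tail(x$loss, 1),
    monotone = all(diff(x$loss) <= 1e-9 * max(x$loss[1], 1))
  )
}

#' Tidy Kaplan-Meier curves into a step-function table
#'
#' @param x a `km_result`.
#' @param ... unused.
#' @return tibble: `group`, `time`, `n_risk`, `n_event`, `estimate`.
#' @method tidy km_result
#' @export
tidy.km_result <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- sub("^grp=", "", as.character(s$strata))
  tibble::tibble(group = grp, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, estimate = s$surv)
}

#' One-row summary of a Kaplan-Meier / log-rank analysis
#'
#' @inheritParams tidy.km_result
#' @return tibble: `statistic` (log-rank chi-square), `df`, `p_value`,
#'   `n`, `events`.
#' @method glance km_result
#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(statistic = x$chisq, df = 1, p_value = x$p_value,
                 n = sum(x$n), events = sum(x$events))
}

#' Tidy a program correlation matrix into long form
#'
#' @param x a `program_correlation`.
#' @param ... unused.
#' @return tibble: `program_a`, `program_b`, `r`.
#' @method tidy program_correlation
#' @export
tidy.program_correlation <- function(x, ...) {
  tibble::as_tibble(x$r, rownames = "program_a") |>
    tidyr::pivot_longer(-"program_a", names_to = "program_b",
                        values_to = "r")
}

#' Tidy aggregated regulon activity into long form
#'
#' @param x a `regulon_activity`.
#' @param ... unused.
#' @return tibble: `state`, `regulon`, `activity`, `n_cells`.
#' @method tidy regulon_activity
#' @export
tidy.regulon_activity <- function(x, ...) {
  tibble::as_tibble(x$activity, rownames = "state") |>
    tidyr::pivot_longer(-"state", names_to = "regulon",
                        values_to = "activity") |>
    dplyr::mutate(n_cells = as.integer(x$sizes[.data$state]))
}
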