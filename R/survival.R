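#' Score bulk samples for a metaprogram signature
#'
#' Applies the single-cell control-matched scoring formula to a bulk
#' samples-by-genes cohort: log-transform, center genes across samples,
#' build expression-matched control sets from the cohort's aggregate
#' expression, and score each sample for the signature's top genes.
#'
#' @param bulk `expr_mat` on the `"tpm"` scale (genes x samples).
#' @param signature character vector of signature gene ids (e.g. a
#'   metaprogram's top 30 genes) or a `metaprogram` object.
#' @param min_present minimum fraction of signature genes that must be in
#'   the matrix (default 0.5; fewer is an error).
#' @return tibble with `sample_id` and `score`.
#' @export
score_bulk <- function(bulk, signature, min_present = 0.5) {
  assert_scale(bulk, "tpm", "score_bulk()")
  if (inherits(signature, "metaprogram")) signature <- signature$genes$gene_id
  present <- intersect(signature, rownames(bulk))
  if (length(present) < min_present * length(signature)) {
    stop("only ", length(present), "/", length(signature),
         " signature genes present in the bulk matrix", call. = FALSE)
  }
  ea <- aggregate_expression(bulk)
  er <- center_expression(log_transform(bulk), group = rep("all", ncol(bulk)))
  sc <- score_cells(er, present, ea = ea)
  tibble::tibble(sample_id = sc$cell_id, score = sc$score)
}

#' Split samples into high and low score groups
#'
#' Default method: 1-D Ward hierarchical clustering of the scores into two
#' clusters; the cluster with the larger mean is labeled `high`. A
#' median-split fallback labels scores above the median `high`. Labels are
#' invariant to adding a constant to all scores.
#'
#' @param scores tibble (`sample_id`, `score`) from [score_bulk()].
#' @param method `"two_cluster"` (default) or `"median"`.
#' @return the tibble with a `group` factor column (levels low, high).
#' @export
dichotomize <- function(scores, method = c("two_cluster", "median")) {
  method <- match.arg(method)
  s <- scores$score
  if (length(s) < 4) stop("need at least 4 samples", call. = FALSE)
  if (diff(range(s)) == 0) stop("all scores identical", call. = FALSE)
  if (method == "two_cluster") {
    hc <- stats::hclust(stats::dist(s), method = "ward.D2")
    cl <- stats::cutree(hc, k = 2)
    hi <- which.max(tapply(s, cl, mean))
    group <- ifelse(cl == as.integer(names(hi)), "high", "low")
  } else {
    group <- ifelse(s > stats::median(s), "high", "low")
  }
  dplyr::mutate(scores, group = factor(group, levels = c("low", "high")))
}

#' Kaplan-Meier curves and log-rank test for a two-group cohort
#'
#' Product-limit survival estimates per group and the two-sample log-rank
#' chi-square (1 df), computed with the survival package.
#'
#' @param cohort tibble with `time` (> 0), `event` (0/1) and `group` (two
#'   levels), e.g. [dichotomize()] output joined to outcomes.
#' @return object of class `km_result`: list with `fit` (a
#'   `survival::survfit` object), `chisq`, `p_value`, `n` (per-group
#'   sizes), `events` (per-group observed events).
#' @export
km_logrank <- function(cohort) {
  stopifnot(all(c("time", "event", "group") %in% names(cohort)))
  if (any(cohort$time <= 0)) stop("times must be positive", call. = FALSE)
  grp <- droplevels(factor(cohort$group))
  if (nlevels(grp) != 2) stop("exactly two non-empty groups required", call. = FALSE)
  if (sum(cohort$event) < 1) stop("at least one event required", call. = FALSE)
  surv <- survival::Surv(cohort$time, cohort$event)
  fit <- survival::survfit(surv ~ grp)
  sd <- survival::survdiff(surv ~ grp)
  chisq <- unname(sd$chisq)
  structure(
    list(fit = fit, chisq = chisq,
         p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         n = sd$n, events = sd$obs),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> log-rank chi-square = %.3f (1 df), p = %.3g\n",
              x$chisq, x$p_value))
  invisible(x)
}

#' Score-versus-covariate association
#'
#' Spearman correlation of a per-sample score with a numeric covariate
#' (e.g. age), a small utility for cohort descriptives.
#'
#' @param scores tibble (`sample_id`, `score`).
#' @param covariate numeric vector aligned with `scores` rows.
#' @return tibble with `rho` and `p_value`.
#' @export
score_covariate_cor <- function(scores, covariate) {
  ct <- suppressWarnings(
    stats::cor.test(scores$score, covariate, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}
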