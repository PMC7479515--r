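#' Select over-dispersed genes
#'
#' Ranks genes by a binned variance z-score: genes are binned into
#' `n_bins` equal-frequency bins of mean log expression, and each gene's
#' log-expression variance is z-scored within its bin, so highly variable
#' genes are identified relative to genes of comparable expression level.
#'
#' @param m `expr_mat` on the `"log"` scale (one sample's malignant cells).
#' @param n number of genes to return (default 10000; all genes if the
#'   matrix has fewer).
#' @param n_bins expression bins (default 20, capped so each bin holds at
#'   least 2 genes).
#' @return character vector of gene ids, most over-dispersed first.
#' @export
overdispersed_genes <- function(m, n = 10000, n_bins = 20) {
  assert_scale(m, "log", "overdispersed_genes()")
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  vals <- unclass(m)
  mu <- rowMeans(vals)
  v <- apply(vals, 1, stats::var)
  n_bins <- max(1L, min(n_bins, floor(nrow(vals) / 2)))
  bin <- ggplot2::cut_number(rank(mu, ties.method = "first"), n = n_bins,
                             labels = FALSE)
  z <- stats::ave(v, bin, FUN = function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  ord <- order(-z, rownames(vals), method = "radix")
  rownames(vals)[ord][seq_len(min(n, nrow(vals)))]
}

#' Non-negative matrix factorization of relative expression
#'
#' Factorizes a non-negative matrix V (genes x cells) as W H with k
#' factors, using multiplicative updates under the Frobenius objective and
#' a non-negative double-SVD initialization, which makes the fit
#' deterministic. A centered matrix is accepted and has its negative
#' values set to zero first, the convention for deriving expression
#' programs from relative expression.
#'
#' @param x matrix or `expr_mat`; `"centered"` matrices are clamped at 0.
#' @param k number of factors (<= min(genes, cells)).
#' @param max_iter maximum update iterations (default 300).
#' @param tol relative decrease of the objective that stops iteration.
#' @return object of class `nmf_fit`: list with `w` (genes x k), `h`
#'   (k x cells), `loss` (objective per iteration), `k`, `iters`.
#' @export
run_nmf <- function(x, k, max_iter = 300, tol = 1e-6) {
  v <- unclass(x)
  if (inherits(x, "expr_mat") && expr_scale(x) == "centered") {
    v <- pmax(v, 0)
  }
  if (any(v < 0)) stop("NMF input must be non-negative", call. = FALSE)
  if (k > min(dim(v))) {
    stop("k exceeds min(genes, cells)", call. = FALSE)
  }
  init <- nndsvd_init(v, k)
  w <- init$w
  h <- init$h
  eps <- .Machine$double.eps
  loss <- numeric(max_iter)
  prev <- Inf
  iters <- max_iter
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, v)) / (crossprod(w, w %*% h) + eps)
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
    loss[it] <- sum((v - w %*% h)^2)
    if (is.finite(prev) && (prev - loss[it]) <= tol * max(prev, eps)) {
      iters <- it
      break
    }
    prev <- loss[it]
  }
  dimnames(w) <- list(rownames(v), paste0("factor", seq_len(k)))
  dimnames(h) <- list(colnames(w), colnames(v))
  structure(list(w = w, h = h, loss = loss[seq_len(iters)], k = k,
                 iters = iters),
            class = "nmf_fit")
}

# Non-negative double SVD initialization (Boutsidis & Gallopoulos);
# zeros are filled with a small data-scaled constant so multiplicative
# updates can move every entry.
nndsvd_init <- function(v, k) {
  sv <- svd(v, nu = k, nv = k)
  w <- matrix(0, nrow(v), k)
  h <- matrix(0, k, ncol(v))
  w[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  h[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]
      vv <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(vv, 0); vn <- pmax(-vv, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        sig <- nup * nvp
        if (sig > 0) {
          w[, j] <- sqrt(sv$d[j] * sig) * up / nup
          h[j, ] <- sqrt(sv$d[j] * sig) * vp / nvp
        }
      } else {
        sig <- nun * nvn
        w[, j] <- sqrt(sv$d[j] * sig) * un / nun
        h[j, ] <- sqrt(sv$d[j] * sig) * vn / nvn
      }
    }
  }
  fill <- mean(v) / 100 + .Machine$double.eps
  w[w <= 0] <- fill
  h[h <= 0] <- fill
  list(w = w, h = h)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> k = %d, %d genes x %d cells, %d iterations, loss %.4g\n",
              x$k, nrow(x$w), ncol(x$h), x$iters, utils::tail(x$loss, 1)))
  invisible(x)
}

#' Top-weight genes of each NMF factor
#'
#' @param fit an [run_nmf()] fit.
#' @param n_top genes per factor (default 30); ties broken by gene id.
#' @return tibble: `factor`, `rank`, `gene_id`, `weight`.
#' @export
nmf_programs <- function(fit, n_top = 30) {
  stopifnot(inherits(fit, "nmf_fit"))
  purrr::map_dfr(colnames(fit$w), function(f) {
    wt <- fit$w[, f]
    ord <- order(-wt, names(wt), method = "radix")[seq_len(min(n_top, length(wt)))]
    tibble::tibble(factor = f, rank = seq_along(ord),
                   gene_id = names(wt)[ord], weight = unname(wt[ord]))
  })
}

#' Cluster program score vectors into correlated sets
#'
#' Programs are clustered on the Pearson correlation of their per-cell
#' score vectors (distance 1 - r, Ward linkage). The tree is cut at every
#' possible number of clusters, coarsest first, and the first cut in which
#' every multi-program cluster has mean pairwise correlation above
#' `min_avg_corr` is kept. Multi-program clusters are retained; singleton
#' programs are dropped unless whitelisted.
#'
#' @param scores wide score tibble (`cell_id` plus one column per program)
#'   with every program scored on the same cells.
#' @param min_avg_corr retention threshold on the mean pairwise Pearson
#'   correlation within a cluster (default 0.5).
#' @param whitelist program names kept even as singletons.
#' @return tibble: `program`, `cluster`, `cluster_size`, `mean_corr`
#'   (`NA` for singletons), `retained`. Invariant to program column order.
#' @export
cluster_programs <- function(scores, min_avg_corr = 0.5,
                             whitelist = character()) {
  programs <- sort(setdiff(names(scores), "cell_id"))
  if (length(programs) < 2) stop("need at least 2 programs", call. = FALSE)
  m <- as.matrix(scores[programs])
  r <- suppressWarnings(stats::cor(m))
  r[is.na(r)] <- 0
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
  n <- length(programs)
  mean_pair_corr <- function(members) {
    if (length(members) < 2) return(NA_real_)
    sub <- r[members, members]
    mean(sub[upper.tri(sub)])
  }
  chosen <- NULL
  for (k in seq_len(n)) {
    cl <- stats::cutree(hc, k = k)
    ok <- all(vapply(split(names(cl), cl), function(mem) {
      mc <- mean_pair_corr(mem)
      is.na(mc) || mc > min_avg_corr
    }, logical(1)))
    if (ok) {
      chosen <- cl
      break
    }
  }
  if (is.null(chosen)) chosen <- stats::setNames(seq_len(n), programs)
  sizes <- table(chosen)
  tibble::tibble(
    program = names(chosen),
    cluster = as.integer(chosen),
    cluster_size = as.integer(sizes[as.character(chosen)]),
    mean_corr = vapply(as.integer(chosen), function(cl) {
      mean_pair_corr(names(chosen)[chosen == cl])
    }, numeric(1)),
    retained = as.integer(sizes[as.character(chosen)]) > 1 |
      names(chosen) %in% whitelist
  ) |>
    dplyr::arrange(.data$cluster, .data$program)
}

#' Merge a correlated program set into a metaprogram
#'
#' Takes the top `n_top` genes by average NMF weight across the member
#' programs; genes missing from a member count as weight 0 there. Ties are
#' broken by gene id.
#'
#' @param weights genes x programs weight matrix (e.g. `cbind` of the `w`
#'   columns of per-sample fits over the union gene universe).
#' @param members program (column) names to merge.
#' @param name metaprogram name.
#' @param n_top genes in the metaprogram (default 30).
#' @return object of class `metaprogram`: list with `name`, `members`,
#'   `genes` (tibble `gene_id`, `mean_weight`, `rank`).
#' @export
merge_to_metaprogram <- function(weights, members, name = "metaprogram",
                                 n_top = 30) {
  if (length(members) == 0) stop("empty program cluster", call. = FALSE)
  missing_members <- setdiff(members, colnames(weights))
  if (length(missing_members)) {
    stop("unknown programs: ", paste(missing_members, collapse = ", "),
         call. = FALSE)
  }
  avg <- rowMeans(weights[, members, drop = FALSE])
  ord <- order(-avg, names(avg), method = "radix")[
    seq_len(min(n_top, length(avg)))]
  structure(
    list(name = name, members = members,
         genes = tibble::tibble(gene_id = names(avg)[ord],
                                mean_weight = unname(avg[ord]),
                                rank = seq_along(ord))),
    class = "metaprogram"
  )
}

#' @export
print.metaprogram <- function(x, ...) {
  cat(sprintf("<metaprogram> %s: %d genes from %d programs\n",
              x$name, nrow(x$genes), length(x$members)))
  invisible(x)
}

#' Subpopulation-specific signature genes
#'
#' One-vs-rest Wilcoxon rank-sum test per gene on uncentered log
#' expression. A gene enters a population's signature iff its
#' Bonferroni-adjusted p value (over tested genes) is below `p_cut`, its
#' mean log2 expression exceeds the rest by at least `min_diff` (1 log2
#' unit = 2-fold), and it is detected (E > 0) in at least `min_frac` of
#' the population's cells. Populations smaller than `min_cells` are
#' skipped with a warning. The rank-sum p value uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param m `expr_mat` on the `"log"` scale.
#' @param assignments tibble (`cell_id`, `state`).
#' @param p_cut adjusted p-value cutoff (default 0.05).
#' @param min_diff minimum mean log2 difference (default 1).
#' @param min_frac minimum detected fraction within the population
#'   (default 0.5).
#' @param min_cells smallest testable population (default 3).
#' @return tibble: `state`, `gene_id`, `p_adj`, `mean_diff`, `frac_expressed`.
#' @export
signature_genes <- function(m, assignments, p_cut = 0.05, min_diff = 1,
                            min_frac = 0.5, min_cells = 3) {
  assert_scale(m, "log", "signature_genes()")
  vals <- unclass(m)[, assignments$cell_id, drop = FALSE]
  states <- unique(assignments$state)
  out <- list()
  for (st in states) {
    in_pop <- assignments$state == st
    if (sum(in_pop) < min_cells) {
      warning("population '", st, "' has fewer than ", min_cells,
              " cells; skipped")
      next
    }
    p <- rowwise_ranksum_p(vals, in_pop)
    p_adj <- pmin(p * nrow(vals), 1)
    diff <- rowMeans(vals[, in_pop, drop = FALSE]) -
      rowMeans(vals[, !in_pop, drop = FALSE])
    frac <- rowMeans(vals[, in_pop, drop = FALSE] > 0)
    keep <- p_adj < p_cut & diff >= min_diff & frac >= min_frac
    if (any(keep)) {
      out[[st]] <- tibble::tibble(
        state = st, gene_id = rownames(vals)[keep],
        p_adj = p_adj[keep], mean_diff = diff[keep],
        frac_expressed = frac[keep]
      ) |> dplyr::arrange(.data$p_adj, .data$gene_id)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(state = character(), gene_id = character(),
                          p_adj = numeric(), mean_diff = numeric(),
                          frac_expressed = numeric()))
  }
  dplyr::bind_rows(out)
}

# Vectorized two-sided Wilcoxon rank-sum p values for every row of `x`,
# group 1 = columns with `in_pop` TRUE. Normal approximation with tie and
# continuity corrections (matches wilcox.test(exact = FALSE)).
rowwise_ranksum_p <- function(x, in_pop) {
  n1 <- sum(in_pop)
  n2 <- sum(!in_pop)
  n <- n1 + n2
  rk <- t(apply(x, 1, rank))
  w <- rowSums(rk[, in_pop, drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- apply(x, 1, function(v) {
    nt <- table(v)
    sum(nt^3 - nt)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- w - mu
  z <- z - sign(z) * 0.5
  z <- ifelse(sigma2 > 0, z / sqrt(sigma2), 0)
  2 * stats::pnorm(-abs(z))
}
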