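#' Order genes by chromosomal location
#'
#' Stable sort by (chromosome, start). Chromosome names are ordered
#' numerically where possible (`chr2` before `chr10`). Genes lacking a
#' chromosome or start position are dropped with a message.
#'
#' @param annotation tibble with `gene_id`, `chrom`, `start`.
#' @return the annotation tibble, ordered, restricted to annotated genes.
#' @export
order_genes <- function(annotation) {
  if (anyDuplicated(annotation$gene_id)) {
    stop("duplicate gene ids in annotation", call. = FALSE)
  }
  ok <- !is.na(annotation$chrom) & !is.na(annotation$start)
  if (any(!ok)) {
    message(sum(!ok), " gene(s) without coordinates excluded")
  }
  ann <- annotation[ok, , drop = FALSE]
  num <- suppressWarnings(as.numeric(sub("^chr", "", ann$chrom)))
  chrom_rank <- ifelse(is.na(num), Inf, num)
  ann[order(chrom_rank, ann$chrom, ann$start, method = "radix"), ,
      drop = FALSE]
}

#' Smoothed copy-number profile from relative expression
#'
#' Sorts genes by chromosomal location and computes the moving average of
#' relative expression over a dense sliding window of `window_size` genes
#' within each chromosome (step 1). Relative-expression values are clipped
#' to `[-cap, cap]` before averaging so single-gene outliers cannot mimic a
#' copy-number event. A chromosome with fewer than `window_size` genes
#' contributes a single window spanning all its genes.
#'
#' @param er `expr_mat` on the `"centered"` scale (genes x cells).
#' @param annotation gene annotation (`gene_id`, `chrom`, `start`); genes
#'   absent from `er` are ignored.
#' @param window_size genes per window (default 100).
#' @param cap clipping bound on relative expression (default 3).
#' @return object of class `cna_profile`: list with `windows`
#'   (windows x cells matrix), `window_info` (tibble: `window_id`, `chrom`,
#'   `from`, `to`, `n_genes` — indices into `gene_order`), `gene_order`
#'   (character), `window_size`, `cap`.
#' @export
compute_cna_profile <- function(er, annotation, window_size = 100, cap = 3) {
  assert_scale(er, "centered", "compute_cna_profile()")
  ann <- order_genes(annotation)
  ann <- ann[ann$gene_id %in% rownames(er), , drop = FALSE]
  if (nrow(ann) == 0) stop("no annotated genes in the matrix", call. = FALSE)
  x <- pmin(pmax(unclass(er)[ann$gene_id, , drop = FALSE], -cap), cap)

  info <- list()
  rows <- list()
  wid <- 0L
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    n <- length(idx)
    if (n < window_size) {
      starts <- 1L
      w <- n
    } else {
      starts <- seq_len(n - window_size + 1L)
      w <- window_size
    }
    cs <- rbind(0, apply(x[idx, , drop = FALSE], 2, cumsum))
    for (s in starts) {
      wid <- wid + 1L
      rows[[wid]] <- (cs[s + w, ] - cs[s, ]) / w
      info[[wid]] <- tibble::tibble(
        window_id = wid, chrom = ch,
        from = idx[s], to = idx[s] + w - 1L, n_genes = w
      )
    }
  }
  windows <- do.call(rbind, rows)
  rownames(windows) <- sprintf("w%05d", seq_len(wid))
  colnames(windows) <- colnames(er)
  structure(
    list(windows = windows, window_info = dplyr::bind_rows(info),
         gene_order = ann$gene_id, window_size = window_size, cap = cap),
    class = "cna_profile"
  )
}

#' @export
print.cna_profile <- function(x, ...) {
  cat(sprintf("<cna_profile> %d windows (size %d, cap %g) x %d cells\n",
              nrow(x$windows), x$window_size, x$cap, ncol(x$windows)))
  invisible(x)
}

#' Per-cell CNA signal
#'
#' Mean squared window value per cell: flat profiles score near zero,
#' profiles with arm-level deviations score high. When reference cells are
#' given, their mean window profile is subtracted first, so the signal
#' measures deviation from the diploid baseline rather than from the
#' cohort average (which is dominated by malignant cells in a typical
#' tumor sample).
#'
#' @param profile a [compute_cna_profile()] result.
#' @param reference optional character vector of reference cell ids in the
#'   profile, or a windows x cells reference matrix on the same window
#'   index.
#' @return tibble with `cell_id` and `signal`.
#' @export
cna_signal <- function(profile, reference = NULL) {
  w <- profile$windows
  if (!is.null(reference)) {
    ref <- if (is.character(reference)) {
      w[, intersect(reference, colnames(w)), drop = FALSE]
    } else {
      reference
    }
    w <- w - rowMeans(ref)
  }
  tibble::tibble(cell_id = colnames(w), signal = colMeans(w^2))
}

#' Call per-cell CNA status against spike-in reference cells
#'
#' Hierarchically clusters copy-number profiles of query and reference
#' cells together (distance 1 - Pearson over windows, Ward linkage) and
#' cuts the tree into `k` clusters. Clusters holding at least half of all
#' spike-in reference cells are deemed CNA-negative; cells in any other
#' cluster are called CNA-positive. The per-cell signal (mean squared
#' window deviation from the reference cells' mean profile, see
#' [cna_signal()]) is reported regardless of the call.
#'
#' @param profile a [compute_cna_profile()] covering query and reference
#'   cells (or queries only, if `reference` is a matrix).
#' @param reference either a character vector of reference cell ids present
#'   in the profile, or a windows x cells matrix on the same window index.
#' @param k number of clusters to cut (default 2).
#' @return tibble: `cell_id`, `cluster`, `is_reference`, `cna_call`
#'   (logical), `signal`.
#' @export
call_cna_status <- function(profile, reference, k = 2) {
  w <- profile$windows
  if (is.character(reference)) {
    missing_ref <- setdiff(reference, colnames(w))
    if (length(missing_ref)) {
      stop("reference cells absent from profile: ",
           paste(utils::head(missing_ref, 3), collapse = ", "), call. = FALSE)
    }
    ref_ids <- reference
  } else {
    if (nrow(reference) != nrow(w)) {
      stop("reference matrix must share the profile's window index",
           call. = FALSE)
    }
    ref_ids <- colnames(reference)
    w <- cbind(w, reference)
  }
  if (length(ref_ids) < k) {
    stop("fewer reference profiles (", length(ref_ids),
         ") than clusters (", k, ")", call. = FALSE)
  }
  cl <- cut_correlation_tree(w, k)
  ref_share <- tapply(colnames(w) %in% ref_ids, cl, sum) / length(ref_ids)
  negative_clusters <- as.integer(names(ref_share)[ref_share >= 0.5])
  sig <- colMeans((w - rowMeans(w[, ref_ids, drop = FALSE]))^2)
  tibble::tibble(
    cell_id = colnames(w),
    cluster = as.integer(cl),
    is_reference = colnames(w) %in% ref_ids,
    cna_call = !(as.integer(cl) %in% negative_clusters),
    signal = unname(sig)
  )
}

# Ward tree on 1 - Pearson between columns; constant columns get
# correlation 0 with everything (distance 1). If every pairwise distance
# is (numerically) identical there is no structure to cut: everything is
# one cluster.
cut_correlation_tree <- function(x, k) {
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 1
  d <- stats::as.dist(1 - r)
  if (diff(range(d)) < 1e-10) {
    return(stats::setNames(rep(1L, ncol(x)), colnames(x)))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  stats::cutree(hc, k = k)
}
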