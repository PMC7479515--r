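#' Construct an expression matrix with a scale tag
#'
#' A thin S3 wrapper around a base genes-by-cells numeric matrix recording
#' which scale the values are on. The pipeline distinguishes four scales:
#' `"tpm"` (transcripts per million, each cell sums to 1e6), `"umi"` (raw
#' unique-molecular-identifier counts), `"log"` (E = log2(TPM/10 + 1)) and
#' `"centered"` (relative expression Er, per-gene mean-centered log values).
#'
#' @param x numeric matrix, genes in rows (rownames = gene ids), cells in
#'   columns (colnames = cell ids).
#' @param scale one of `"tpm"`, `"umi"`, `"log"`, `"centered"`.
#' @param compartment optional character vector of per-cell compartment
#'   labels (e.g. PF/ST/SP), recycled or named by cell id.
#' @return the matrix with class `expr_mat` and attributes `scale` and
#'   (optionally) `compartment`.
#' @export
expression_matrix <- function(x, scale = c("tpm", "umi", "log", "centered"),
                              compartment = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("`x` must have gene rownames and cell colnames", call. = FALSE)
  }
  if (scale %in% c("tpm", "umi") && any(x < 0)) {
    stop("negative values are not valid on the ", scale, " scale", call. = FALSE)
  }
  if (!is.null(compartment)) {
    if (length(compartment) == 1L) compartment <- rep(compartment, ncol(x))
    if (length(compartment) != ncol(x)) {
      stop("`compartment` must have one label per cell", call. = FALSE)
    }
    compartment <- stats::setNames(as.character(compartment), colnames(x))
  }
  structure(x, class = c("expr_mat", class(x)),
            scale = scale, compartment = compartment)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d cells, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

expr_scale <- function(x) attr(x, "scale") %||% "tpm"

assert_scale <- function(x, scale, what) {
  if (!identical(expr_scale(x), scale)) {
    stop(sprintf("%s expects a matrix on the '%s' scale, got '%s'",
                 what, scale, expr_scale(x)), call. = FALSE)
  }
  invisible(x)
}

# keep class/attrs when values change but shape survives
restamp <- function(values, template, scale = expr_scale(template)) {
  comp <- attr(template, "compartment")
  if (!is.null(comp)) comp <- comp[colnames(values)]
  expression_matrix(values, scale = scale, compartment = comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
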