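# Per-cell quality control, library-size normalization, and
# highly-variable-gene selection.

#' Compute per-cell QC metrics
#'
#' @param counts Gene x cell count matrix (dense or sparse, non-negative
#'   integers). Mitochondrial genes are recognized by their identifier
#'   prefix (default `"MT-"`, case-insensitive).
#' @param mito_pattern Regular expression identifying mitochondrial genes.
#' @return Tibble with one row per cell: `barcode`, `n_features` (genes with
#'   count > 0), `total_umi`, and `mito_pct` (percentage of UMIs from
#'   mitochondrial genes; 0 by convention for all-zero cells or when no
#'   mitochondrial gene exists).
#' @export
compute_qc <- function(counts, mito_pattern = "^MT-") {
  stopifnot_counts(counts)
  x <- as_dgc(counts)
  n_features <- Matrix::colSums(x > 0)
  total <- Matrix::colSums(x)
  mito <- grepl(mito_pattern, rownames(x) %||% character(nrow(x)),
                ignore.case = TRUE)
  mito_umi <- if (any(mito)) Matrix::colSums(x[mito, , drop = FALSE]) else 0
  mito_pct <- ifelse(total > 0, 100 * mito_umi / total, 0)
  tibble::tibble(
    barcode = colnames(x) %||% sprintf("cell%06d", seq_len(ncol(x))),
    n_features = as.integer(n_features),
    total_umi = as.numeric(total),
    mito_pct = as.numeric(mito_pct)
  )
}

#' Cell filter on feature count and mitochondrial percentage
#'
#' A cell is kept iff `min_features <= n_features <= max_features` and
#' `mito_pct <= max_mito_pct`. Boundary values are kept: removal requires a
#' strict violation (fewer than 200 or more than 2500 features, more than
#' 10% mitochondrial UMIs at the defaults).
#'
#' @param metrics Tibble from [compute_qc()].
#' @param min_features,max_features,max_mito_pct Filter thresholds.
#' @return Logical keep mask, one entry per cell, named by barcode.
#' @export
filter_cells <- function(metrics, min_features = 200, max_features = 2500,
                         max_mito_pct = 10) {
  stopifnot(is.data.frame(metrics),
            all(c("n_features", "mito_pct") %in% names(metrics)))
  if (min_features <= 0 || max_features <= 0 || max_mito_pct < 0 ||
      min_features >= max_features) {
    stop("thresholds must be positive with min_features < max_features",
         call. = FALSE)
  }
  keep <- metrics$n_features >= min_features &
    metrics$n_features <= max_features &
    metrics$mito_pct <= max_mito_pct
  stats::setNames(keep, metrics$barcode)
}

#' Library-size log-normalization
#'
#' `value = log(1 + scale * count / total_umi_of_cell)`, the standard
#' library-size scaling with a log1p transform.
#'
#' @param counts Gene x cell count matrix with no all-zero cells.
#' @param scale Target library size (default 1e4).
#' @return Sparse gene x cell matrix of normalized expression.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  stopifnot_counts(counts)
  x <- as_dgc(counts)
  total <- Matrix::colSums(x)
  if (any(total == 0)) {
    bad <- (colnames(x) %||% as.character(seq_len(ncol(x))))[total == 0]
    stop("cells with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5),
         call. = FALSE)
  }
  per_col <- rep.int(total, diff(x@p))
  x@x <- log1p(x@x * scale / per_col)
  x
}

#' Rank genes by variance-stabilized dispersion and take the top set
#'
#' Genes are ranked by the residual of their log variance against a running
#' median trend over the mean (both on the normalized scale); ties are
#' broken lexicographically by gene id so the ranking is deterministic.
#'
#' @param normalized Gene x cell normalized matrix from [normalize_log()].
#' @param n_top Number of genes to return.
#' @return Character vector of the selected gene ids, ordered by decreasing
#'   dispersion residual, with the full ranking tibble in attribute
#'   `"stats"`.
#' @export
select_hvg <- function(normalized, n_top = 2000) {
  stopifnot_counts(normalized)
  x <- as_dgc(normalized)
  if (n_top > nrow(x)) {
    stop("`n_top` must not exceed the number of genes", call. = FALSE)
  }
  gene <- rownames(x) %||% sprintf("gene%06d", seq_len(nrow(x)))
  mu <- Matrix::rowMeans(x)
  v <- row_vars_sparse(x)
  logv <- log(v + 1e-12)
  ord <- order(mu)
  k <- min(51L, nrow(x) - (1 - nrow(x) %% 2)) # odd window <= n
  trend <- numeric(length(mu))
  trend[ord] <- stats::runmed(logv[ord], k = max(k, 1L), endrule = "median")
  resid <- logv - trend
  stats_tbl <- tibble::tibble(gene = gene, mean = mu, variance = v,
                              dispersion = resid)
  sel <- stats_tbl[order(-stats_tbl$dispersion, stats_tbl$gene), ]
  out <- utils::head(sel$gene, n_top)
  attr(out, "stats") <- sel
  out
}
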