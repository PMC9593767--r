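# One-vs-rest Wilcoxon rank-sum marker detection with BH adjustment.

#' Find cluster marker genes by one-vs-rest Wilcoxon rank-sum tests
#'
#' For every cluster, each gene is tested between the cluster's cells and
#' all other cells with the Wilcoxon rank-sum test (exact null distribution
#' when both groups are small and the gene has no tied values, normal
#' approximation with tie and continuity corrections otherwise). Log2 fold
#' changes are computed on means of `expm1(normalized)` with a pseudocount
#' of 1, and p-values are Benjamini-Hochberg adjusted across the whole
#' table before the effect-size filters are applied.
#'
#' @param normalized Gene x cell normalized matrix.
#' @param labels Per-cell cluster labels (length = ncol).
#' @param min_log2fc Minimum absolute log2 fold change to report.
#' @param min_pct Minimum expression fraction in either group.
#' @return Tibble with columns gene, cluster, log2fc, pct_in, pct_out, p,
#'   p_adj, ordered by cluster then p.
#' @export
find_markers <- function(normalized, labels, min_log2fc = 0.25, min_pct = 0.1) {
  stopifnot_counts(normalized)
  x <- as_dgc(normalized)
  if (length(labels) != ncol(x)) {
    stop("`labels` must have one entry per cell", call. = FALSE)
  }
  cl <- factor(labels)
  if (nlevels(cl) < 2) stop("need at least 2 clusters", call. = FALSE)
  sizes <- table(cl)
  if (any(sizes < 3)) {
    stop("clusters with fewer than 3 cells: ",
         paste(names(sizes)[sizes < 3], collapse = ", "), call. = FALSE)
  }
  n <- ncol(x)
  n_genes <- nrow(x)
  genes <- rownames(x) %||% sprintf("gene%06d", seq_len(n_genes))
  ind <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cl), x = 1,
                              dims = c(n, nlevels(cl)))

  nnz <- as.matrix((x > 0) %*% ind) # genes x clusters nonzero counts
  xe <- x
  xe@x <- expm1(xe@x)
  esum <- as.matrix(xe %*% ind)
  n_in <- as.numeric(sizes)
  n_out <- n - n_in

  mean_in <- sweep(esum, 2, n_in, "/")
  mean_out <- sweep(sweep(esum, 1, rowSums(esum), FUN = function(a, b) b - a),
                    2, n_out, "/")
  log2fc <- log2((mean_in + 1) / (mean_out + 1))
  pct_in <- sweep(nnz, 2, n_in, "/")
  pct_out <- sweep(sweep(nnz, 1, rowSums(nnz), FUN = function(a, b) b - a),
                   2, n_out, "/")

  # Rank sums and tie terms per gene (dense row sweep).
  xd <- as.matrix(x)
  ranksum <- matrix(0, n_genes, nlevels(cl))
  ties <- numeric(n_genes)
  cl_int <- as.integer(cl)
  for (g in seq_len(n_genes)) {
    v <- xd[g, ]
    r <- rank(v)
    ranksum[g, ] <- rowsum(r, cl_int)[, 1]
    tt <- rle(sort(v))$lengths
    ties[g] <- sum(tt^3 - tt)
  }

  pmat <- matrix(NA_real_, n_genes, nlevels(cl))
  for (kk in seq_len(nlevels(cl))) {
    n1 <- n_in[kk]; n2 <- n_out[kk]
    U <- ranksum[, kk] - n1 * (n1 + 1) / 2
    use_exact <- n1 < 50 & n2 < 50 & ties == 0
    if (any(use_exact)) {
      Ue <- U[use_exact]
      p_up <- stats::pwilcox(Ue - 1, n1, n2, lower.tail = FALSE)
      p_dn <- stats::pwilcox(Ue, n1, n2)
      pmat[use_exact, kk] <- pmin(1, 2 * pmin(p_up, p_dn))
    }
    if (any(!use_exact)) {
      Ua <- U[!use_exact]
      mu <- n1 * n2 / 2
      sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - ties[!use_exact] / (n * (n - 1))))
      z <- Ua - mu
      z <- (z - sign(z) * 0.5) / sigma
      pmat[!use_exact, kk] <- pmin(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    }
  }

  out <- tibble::tibble(
    gene = rep(genes, nlevels(cl)),
    cluster = rep(levels(cl), each = n_genes),
    log2fc = as.vector(log2fc),
    pct_in = as.vector(pct_in),
    pct_out = as.vector(pct_out),
    p = as.vector(pmat)
  )
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[abs(out$log2fc) >= min_log2fc &
               pmax(out$pct_in, out$pct_out) >= min_pct, ]
  dplyr::arrange(out, .data$cluster, .data$p, dplyr::desc(.data$log2fc))
}
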