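# Graph-based clustering with subsampled-ARI stability selection: the
# two-step clustering engine. Clustering builds a kNN graph on the top
# principal components of the scaled HVG matrix and runs Leiden modularity
# optimization at a given resolution; the stability scan reclusters 90%
# subsamples and compares them to the full-data reference with the adjusted
# Rand index, and the working resolution is the highest one before the mean
# ARI starts to decline.

#' PCA embedding of the scaled HVG matrix
#'
#' Genes are z-scored across cells (values clipped at 10 standard
#' deviations, the usual guard against outlier cells dominating a
#' component) and the top principal components are computed with a
#' truncated SVD.
#'
#' @param normalized Gene x cell normalized matrix.
#' @param genes Optional gene subset (e.g., from [select_hvg()]).
#' @param n_pcs Number of principal components (default 30).
#' @param seed Seed for the randomized SVD initialization.
#' @return Cells x PCs numeric matrix with barcodes as row names.
#' @export
embed_pca <- function(normalized, genes = NULL, n_pcs = 30, seed = 0L) {
  stopifnot_counts(normalized)
  x <- as_dgc(normalized)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing)) {
      stop("genes not present in the matrix: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    x <- x[genes, , drop = FALSE]
  }
  m <- t(as.matrix(x)) # cells x genes
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  keep <- sdv > 0
  m <- sweep(m[, keep, drop = FALSE], 2, mu[keep], "-")
  m <- sweep(m, 2, sdv[keep], "/")
  m[m > 10] <- 10
  m[m < -10] <- -10
  n_pcs <- min(n_pcs, dim(m) - 1L)
  emb <- with_seed(seed, {
    if (n_pcs < min(dim(m)) / 3) {
      sv <- irlba::irlba(m, nv = n_pcs)
      sv$u %*% diag(sv$d, n_pcs, n_pcs)
    } else {
      sv <- svd(m, nu = n_pcs, nv = 0)
      sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
    }
  })
  rownames(emb) <- rownames(m)
  colnames(emb) <- paste0("PC", seq_len(ncol(emb)))
  emb
}

knn_graph <- function(embedding, k = 15) {
  n <- nrow(embedding)
  if (n <= k) {
    stop(sprintf("need more than k = %d cells to build the kNN graph (got %d)",
                 k, n), call. = FALSE)
  }
  nn <- FNN::get.knn(embedding, k = k)
  edges <- cbind(rep(seq_len(n), k), as.vector(nn$nn.index))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

cluster_graph <- function(graph, resolution, seed = 0L) {
  memb <- with_seed(seed, {
    igraph::cluster_leiden(graph, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = 2)$membership
  })
  # relabel contiguous from 0, largest cluster first
  sizes <- sort(table(memb), decreasing = TRUE)
  as.integer(match(memb, as.integer(names(sizes))) - 1L)
}

#' Cluster cells by Leiden community detection on a kNN graph
#'
#' @param embedding Cells x dims matrix (e.g., from [embed_pca()]).
#' @param resolution Positive resolution parameter of the modularity
#'   objective.
#' @param seed Seed for the community-detection refinement.
#' @param k Number of nearest neighbors of the graph.
#' @return Integer vector of 0-based, size-ordered cluster labels named by
#'   the embedding's row names, with attributes `resolution`, `seed`, `k`.
#' @export
cluster_cells <- function(embedding, resolution, seed = 0L, k = 15) {
  stopifnot(is.matrix(embedding), is.numeric(resolution), resolution > 0)
  g <- knn_graph(embedding, k = k)
  labels <- cluster_graph(g, resolution, seed)
  structure(stats::setNames(labels, rownames(embedding)),
            resolution = resolution, seed = seed, k = k,
            class = "cluster_labels")
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Returns 1 for the degenerate case where both partitions carry no
#' information to compare (e.g., one block each).
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  if (anyNA(labels_a) || anyNA(labels_b)) {
    stop("labels must not contain NA", call. = FALSE)
  }
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  ct <- Matrix::sparseMatrix(i = a, j = b, x = 1,
                             dims = c(max(a), max(b)))
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- comb2(ct@x)
  sum_a <- comb2(Matrix::rowSums(ct))
  sum_b <- comb2(Matrix::colSums(ct))
  expected <- sum_a * sum_b / (n * (n - 1) / 2)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < .Machine$double.eps * max(1, max_idx)) {
    return(1)
  }
  (sum_ij - expected) / (max_idx - expected)
}

#' Clustering stability scan over resolutions by subsampled ARI
#'
#' For each resolution the full data set is clustered once (the reference);
#' then for each iteration a fraction of cells is drawn without replacement,
#' the subsample is reclustered from its own kNN graph, and the ARI is
#' computed between the subsample solution and the reference labels
#' restricted to the same cells. Iteration `i` draws its subsample with seed
#' `seed + i`, so the same subsample serves every resolution.
#'
#' @param embedding Cells x dims matrix.
#' @param resolutions Ascending vector of at least two resolutions.
#' @param subsample_fraction Fraction of cells per subsample (0 < f < 1);
#'   subsample size is `floor(fraction * n)`.
#' @param n_iterations Subsample iterations per resolution (default 20).
#' @param seed Base seed.
#' @param k Neighbors of the kNN graph.
#' @return Tibble of class `stability_table` with columns `resolution`,
#'   `iteration`, `ari` and attributes recording the scan parameters.
#' @export
stability_scan <- function(embedding, resolutions, subsample_fraction = 0.9,
                           n_iterations = 20, seed = 0L, k = 15) {
  if (length(resolutions) < 2) {
    stop("need at least 2 resolutions to scan", call. = FALSE)
  }
  if (subsample_fraction <= 0 || subsample_fraction >= 1) {
    stop("`subsample_fraction` must be in (0, 1)", call. = FALSE)
  }
  resolutions <- sort(resolutions)
  n <- nrow(embedding)
  m <- floor(subsample_fraction * n)
  if (m <= k) {
    stop("subsample smaller than the graph neighborhood k", call. = FALSE)
  }
  g_full <- knn_graph(embedding, k = k)
  reference <- lapply(resolutions, function(r) cluster_graph(g_full, r, seed))
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    idx <- with_seed(seed + i, sample.int(n, m))
    g_sub <- knn_graph(embedding[idx, , drop = FALSE], k = k)
    ari <- vapply(seq_along(resolutions), function(j) {
      sub_labels <- cluster_graph(g_sub, resolutions[j], seed + i)
      adjusted_rand_index(sub_labels, reference[[j]][idx])
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      resolution = resolutions, iteration = i, ari = ari,
      n_clusters = vapply(reference, function(r) length(unique(r)), integer(1)))
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$resolution,
                        .data$iteration)
  structure(out, subsample_fraction = subsample_fraction,
            n_iterations = n_iterations, seed = seed, k = k,
            class = c("stability_table", class(out)))
}

#' Per-resolution stability summary
#'
#' @param table A `stability_table` from [stability_scan()].
#' @return Tibble with per-resolution mean and sd of the ARI.
#' @export
stability_summary <- function(table) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(table), .data$resolution),
                   mean_ari = mean(.data$ari), sd_ari = stats::sd(.data$ari),
                   .groups = "drop")
}

#' Select the working resolution from a stability scan
#'
#' Returns the highest resolution before the mean ARI begins to decline:
#' with mean ARI `m(r_1), ..., m(r_K)` over ascending resolutions, the
#' smallest `k` with `m(r_(k+1)) <= m(r_k) - delta` gives `r_k`; if the mean
#' ARI never drops by more than `delta`, the last resolution is returned.
#' Leading resolutions whose reference partition is a single cluster are
#' excluded from the rule (when the scan recorded cluster counts): a
#' one-block partition is reproduced by any subsample trivially, so its
#' ARI of 1 is vacuous and would make the first real clustering look like
#' a decline.
#'
#' @param table A `stability_table` (or a tibble with `resolution` and
#'   `ari` columns).
#' @param delta Decline threshold on the mean ARI (default 0.05).
#' @return The selected resolution (numeric scalar).
#' @export
select_resolution <- function(table, delta = 0.05) {
  s <- stability_summary(table)
  s <- s[order(s$resolution), ]
  if ("n_clusters" %in% names(table)) {
    nc <- tapply(table$n_clusters, table$resolution, max)[as.character(s$resolution)]
    informative <- which(nc > 1)
    if (length(informative) && informative[1] > 1) {
      s <- s[informative[1]:nrow(s), ]
    }
  }
  if (nrow(s) == 1) {
    warning("single resolution in the stability table; returning it as-is")
    return(s$resolution)
  }
  m <- s$mean_ari
  drops <- which(m[-1] <= m[-length(m)] - delta)
  if (length(drops)) s$resolution[drops[1]] else s$resolution[nrow(s)]
}

#' Second-step clustering of a cell subset
#'
#' Re-runs the whole clustering pipeline on a subset of cells (typically
#' the neutrophil cluster): re-selects HVGs within the subset, re-embeds
#' with PCA, scans resolutions for stability, selects the working
#' resolution, and clusters at it.
#'
#' @param normalized Gene x cell normalized matrix.
#' @param cells Barcodes (column names) of the subset.
#' @param resolutions Resolutions for the stability scan.
#' @param n_hvg,n_pcs,k Embedding and graph parameters.
#' @param subsample_fraction,n_iterations,delta Stability-scan parameters.
#' @param seed Base seed.
#' @return List with `labels` (cluster_labels), `resolution`, `stability`
#'   (stability_table), `embedding`, and `hvg`.
#' @export
subcluster <- function(normalized, cells, resolutions = c(0.05, 0.1, 0.15, 0.2, 0.4, 0.6),
                       n_hvg = 2000, n_pcs = 30, k = 15,
                       subsample_fraction = 0.9, n_iterations = 20,
                       delta = 0.05, seed = 0L) {
  x <- as_dgc(normalized)[, cells, drop = FALSE]
  hvg <- select_hvg(x, n_top = min(n_hvg, nrow(x)))
  emb <- embed_pca(x, genes = hvg, n_pcs = n_pcs, seed = seed)
  stab <- stability_scan(emb, resolutions, subsample_fraction = subsample_fraction,
                         n_iterations = n_iterations, seed = seed, k = k)
  res <- select_resolution(stab, delta = delta)
  labels <- cluster_cells(emb, resolution = res, seed = seed, k = k)
  list(labels = labels, resolution = res, stability = stab,
       embedding = emb, hvg = as.character(hvg))
}
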