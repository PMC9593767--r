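# Non-negative matrix factorization with multiplicative updates, consensus
# rank-selection metrics (cophenetic, dispersion, silhouette, RSS), module
# usage, and top-gene reporting.

#' Factorize a non-negative matrix
#'
#' Minimizes the Frobenius reconstruction error `||V - WH||^2` by
#' multiplicative updates from random uniform initialization, stopping when
#' the relative RSS change per iteration falls below `tol`. The result is
#' canonicalized by scaling each column of `W` to unit L1 norm with the
#' compensating row scaling of `H`, which leaves `WH` unchanged.
#'
#' @param V Non-negative genes x cells matrix.
#' @param rank Factorization rank (< min(dim(V))).
#' @param seed Seed for the initialization.
#' @param max_iter Maximum number of update iterations.
#' @param tol Relative RSS-change stopping tolerance.
#' @return Object of class `nmf_fit` with `W` (genes x rank), `H` (rank x
#'   cells), `rss`, the per-iteration `rss_trace`, and `converged`.
#' @export
nmf_factorize <- function(V, rank, seed = 0L, max_iter = 1000, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("`V` must be non-negative", call. = FALSE)
  if (rank >= min(dim(V))) {
    stop("`rank` must be smaller than both dimensions of V", call. = FALSE)
  }
  eps <- .Machine$double.eps
  n <- nrow(V); m <- ncol(V)
  sc <- sqrt(mean(V) / rank)
  init <- with_seed(seed, list(
    W = matrix(stats::runif(n * rank, 0, sc * 2), n, rank),
    H = matrix(stats::runif(rank * m, 0, sc * 2), rank, m)
  ))
  W <- init$W; H <- init$H
  rss_trace <- numeric(max_iter)
  rss_old <- Inf
  converged <- FALSE
  v2 <- sum(V^2)
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    VHt <- tcrossprod(V, H)
    W <- W * VHt / (W %*% tcrossprod(H) + eps)
    # ||V - WH||^2 expanded via the cached cross-products (exact, avoids
    # forming WH): v2 - 2<V, WH> + <W'W, HH'>
    rss <- v2 - 2 * sum(W * VHt) + sum(crossprod(W) * tcrossprod(H))
    n_iter <- iter
    rss_trace[iter] <- rss
    if (is.finite(rss_old) && (rss_old - rss) <= tol * max(rss_old, eps)) {
      converged <- TRUE
      break
    }
    rss_old <- rss
  }
  rss_trace <- rss_trace[seq_len(n_iter)]
  l1 <- pmax(colSums(W), eps)
  W <- sweep(W, 2, l1, "/")
  H <- H * l1
  modules <- paste0("M", seq_len(rank))
  dimnames(W) <- list(rownames(V), modules)
  dimnames(H) <- list(modules, colnames(V))
  structure(list(W = W, H = H, rank = rank, rss = rss_trace[length(rss_trace)],
                 rss_trace = rss_trace, iterations = length(rss_trace),
                 converged = converged, seed = seed),
            class = "nmf_fit")
}

#' Consensus NMF metrics over candidate ranks
#'
#' For each rank, `n_runs` factorizations are run from different seeds
#' (`seed + run`); each run assigns every cell to its argmax metagene, and
#' the consensus matrix `C` records the fraction of runs co-assigning each
#' cell pair. The rank metrics are: the cophenetic coefficient (Pearson
#' correlation between the consensus dissimilarity `1 - C` and the
#' cophenetic distances of its average-linkage hierarchical clustering),
#' dispersion (`mean(4 (C - 1/2)^2)`, 1 for a binary consensus), the mean
#' silhouette width of the consensus clustering under `1 - C`, and the
#' best-run RSS.
#'
#' @param V Non-negative genes x cells matrix.
#' @param ranks Candidate ranks (>= 2 values, each >= 2).
#' @param n_runs Runs per rank (>= 10).
#' @param seed Base seed.
#' @param max_iter,tol Per-run factorization controls (defaults favour many
#'   moderately converged runs, which is what the consensus needs).
#' @return Tibble of class `rank_metrics`: rank, cophenetic, rss,
#'   dispersion, silhouette, n_runs.
#' @export
consensus_metrics <- function(V, ranks, n_runs = 30, seed = 0L,
                              max_iter = 200, tol = 1e-5) {
  V <- as.matrix(V)
  if (length(ranks) < 2) stop("need at least 2 candidate ranks", call. = FALSE)
  if (n_runs < 10) stop("`n_runs` must be at least 10", call. = FALSE)
  if (any(ranks >= ncol(V))) {
    stop("ranks must be smaller than the number of cells", call. = FALSE)
  }
  m <- ncol(V)
  rows <- lapply(ranks, function(r) {
    C <- matrix(0, m, m)
    best_rss <- Inf
    for (run in seq_len(n_runs)) {
      fit <- nmf_factorize(V, r, seed = seed + run, max_iter = max_iter,
                           tol = tol)
      assign <- max.col(t(fit$H), ties.method = "first")
      ind <- matrix(0, m, r)
      ind[cbind(seq_len(m), assign)] <- 1
      C <- C + tcrossprod(ind)
      best_rss <- min(best_rss, fit$rss)
    }
    C <- C / n_runs
    d <- stats::as.dist(1 - C)
    hc <- stats::hclust(d, method = "average")
    coph <- suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
    if (!is.finite(coph)) coph <- 1 # all pairs fully consistent
    disp <- mean(4 * (C - 0.5)^2)
    clus <- stats::cutree(hc, k = r)
    sil <- if (length(unique(clus)) > 1) {
      mean(cluster::silhouette(clus, d)[, "sil_width"])
    } else NA_real_
    tibble::tibble(rank = r, cophenetic = coph, rss = best_rss,
                   dispersion = disp, silhouette = sil, n_runs = n_runs)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rank_metrics", class(out)))
}

#' Select the factorization rank from consensus metrics
#'
#' Default rule: the rank maximizing the cophenetic coefficient, with ties
#' broken by higher dispersion and then by the smaller rank. The full
#' metrics table remains available so the collective judgment over all four
#' statistics stays auditable.
#'
#' @param metrics A `rank_metrics` tibble from [consensus_metrics()].
#' @return The selected rank (integer).
#' @export
select_rank <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 2)
  ord <- order(-metrics$cophenetic, -metrics$dispersion, metrics$rank)
  as.integer(metrics$rank[ord[1]])
}

#' Per-cell module usage proportions
#'
#' Each cell's H column is normalized to sum 1.
#'
#' @param H An `nmf_fit` or a rank x cells non-negative matrix.
#' @return Tibble with `cell`, `module`, `usage` (long form; usages of a
#'   cell sum to 1).
#' @export
module_usage <- function(H) {
  if (inherits(H, "nmf_fit")) H <- H$H
  H <- as.matrix(H)
  if (any(H < 0)) stop("`H` must be non-negative", call. = FALSE)
  tot <- colSums(H)
  if (any(tot == 0)) {
    bad <- (colnames(H) %||% as.character(seq_len(ncol(H))))[tot == 0]
    stop("all-zero usage column for cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  U <- sweep(H, 2, tot, "/")
  tibble::tibble(
    cell = rep(colnames(H) %||% as.character(seq_len(ncol(H))), each = nrow(H)),
    module = rep(rownames(H) %||% paste0("M", seq_len(nrow(H))), ncol(H)),
    usage = as.vector(U)
  )
}

#' Aggregate per-cell module usage to per-sample means
#'
#' @param usage Long usage tibble from [module_usage()].
#' @param sample_ids Named character vector mapping cell -> sample, or a
#'   data frame with `cell` and `sample_id` columns.
#' @return Tibble with `sample_id`, `module`, `usage` (mean over the
#'   sample's cells).
#' @export
aggregate_usage <- function(usage, sample_ids) {
  if (is.data.frame(sample_ids)) {
    sample_ids <- stats::setNames(sample_ids$sample_id, sample_ids$cell)
  }
  usage |>
    dplyr::mutate(sample_id = unname(sample_ids[.data$cell])) |>
    dplyr::group_by(.data$sample_id, .data$module) |>
    dplyr::summarise(usage = mean(.data$usage), .groups = "drop")
}

#' Top-weighted genes per metagene module
#'
#' @param W An `nmf_fit` or a genes x rank non-negative matrix.
#' @param n Genes per module.
#' @return Tibble with `module`, `rank` (1 = heaviest), `gene`, `weight`;
#'   ties broken deterministically by gene id.
#' @export
top_genes <- function(W, n = 20) {
  if (inherits(W, "nmf_fit")) W <- W$W
  W <- as.matrix(W)
  if (n > nrow(W)) stop("`n` must not exceed the number of genes", call. = FALSE)
  genes <- rownames(W) %||% sprintf("gene%06d", seq_len(nrow(W)))
  mods <- colnames(W) %||% paste0("M", seq_len(ncol(W)))
  rows <- lapply(seq_len(ncol(W)), function(j) {
    ord <- order(-W[, j], genes)[seq_len(n)]
    tibble::tibble(module = mods[j], rank = seq_len(n), gene = genes[ord],
                   weight = W[ord, j])
  })
  dplyr::bind_rows(rows)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: rank %d, %d genes x %d cells, rss %.4g (%d iterations%s)\n",
              x$rank, nrow(x$W), ncol(x$H), x$rss, x$iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}
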