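# Signature-matrix construction from labeled single cells and bulk
# deconvolution by non-negative least squares.

#' Build a cell-type signature matrix from labeled single-cell data
#'
#' Takes the union of the top `markers_per_type` marker genes per type
#' (ranked by log2 fold change from [find_markers()]) and records each
#' type's mean linear-scale expression (`expm1` of the normalized values)
#' over those genes.
#'
#' @param normalized Gene x cell normalized matrix.
#' @param labels Per-cell type labels (each type needs >= 10 cells).
#' @param markers_per_type Markers requested per type (capped with a
#'   warning at the number of available genes).
#' @return Object of class `signature_matrix`: `profile` (marker genes x
#'   types), `markers` (the marker table used), `condition` (condition
#'   number of the profile).
#' @export
build_signature_matrix <- function(normalized, labels, markers_per_type = 50) {
  stopifnot_counts(normalized)
  cl <- factor(labels)
  sizes <- table(cl)
  if (any(sizes < 10)) {
    stop("types with fewer than 10 cells: ",
         paste(names(sizes)[sizes < 10], collapse = ", "), call. = FALSE)
  }
  if (markers_per_type > nrow(normalized)) {
    warning("`markers_per_type` exceeds the number of genes; capping")
    markers_per_type <- nrow(normalized)
  }
  mk <- find_markers(normalized, cl, min_log2fc = 0, min_pct = 0)
  mk_top <- mk |>
    dplyr::filter(.data$log2fc > 0) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_max(.data$log2fc, n = markers_per_type, with_ties = FALSE) |>
    dplyr::ungroup()
  genes <- sort(unique(mk_top$gene))
  x <- as_dgc(normalized)[genes, , drop = FALSE]
  x@x <- expm1(x@x)
  ind <- Matrix::sparseMatrix(i = seq_len(ncol(x)), j = as.integer(cl), x = 1,
                              dims = c(ncol(x), nlevels(cl)))
  profile <- sweep(as.matrix(x %*% ind), 2, as.numeric(sizes), "/")
  dimnames(profile) <- list(genes, levels(cl))
  cond <- kappa(profile, exact = TRUE)
  if (cond > 1e6) {
    warning(sprintf("signature matrix is ill-conditioned (kappa = %.3g)", cond))
  }
  structure(list(profile = profile, markers = mk_top, condition = cond),
            class = "signature_matrix")
}

#' Estimate cell-type fractions in bulk samples
#'
#' Per sample, the bulk profile is restricted to the genes shared with the
#' signature, bulk and signature columns are brought to a common scale by
#' total-sum scaling, and fractions are estimated by non-negative least
#' squares (`min ||b - S f||_2, f >= 0`) followed by renormalization to sum
#' 1. Log-scale bulk input (maximum value < 50) is detected and reversed
#' with `expm1` with a warning.
#'
#' @param bulk Genes x samples non-negative matrix.
#' @param signature A `signature_matrix` or a plain genes x types matrix.
#' @return Object of class `deconv_result`: `fractions` (tibble, one row
#'   per sample, one column per type), `residuals` (per-sample residual
#'   norm), `method`.
#' @export
deconvolve <- function(bulk, signature) {
  profile <- if (inherits(signature, "signature_matrix")) signature$profile
             else as.matrix(signature)
  bulk <- as.matrix(bulk)
  if (any(bulk < 0)) stop("`bulk` must be non-negative", call. = FALSE)
  if (max(bulk) < 50) {
    warning("`bulk` looks log-scale (max < 50); applying expm1")
    bulk <- expm1(bulk)
  }
  shared <- intersect(rownames(profile), rownames(bulk))
  coverage <- length(shared) / nrow(profile)
  if (coverage < 0.5) {
    missing <- setdiff(rownames(profile), rownames(bulk))
    stop(sprintf(
      "only %.0f%% of signature genes present in bulk; missing e.g. %s",
      100 * coverage, paste(utils::head(missing, 5), collapse = ", ")),
      call. = FALSE)
  }
  S0 <- profile[shared, , drop = FALSE]
  sj <- colSums(S0)
  S <- sweep(S0, 2, sj, "/")
  B <- bulk[shared, , drop = FALSE]
  samples <- colnames(B) %||% sprintf("sample%03d", seq_len(ncol(B)))
  est <- matrix(0, ncol(B), ncol(S),
                dimnames = list(samples, colnames(S)))
  resid <- numeric(ncol(B))
  for (j in seq_len(ncol(B))) {
    b <- B[, j]
    b <- b / sum(b)
    fit <- pracma::lsqnonneg(S, b)
    # coefficients live in scaled-column units; dividing by the column
    # totals converts them back to mixture weights over the original
    # profiles before renormalizing to fractions
    f <- fit$x / sj
    if (sum(f) == 0) f <- rep(1 / length(f), length(f))
    est[j, ] <- f / sum(f)
    resid[j] <- sqrt(sum((b - S %*% fit$x)^2))
  }
  structure(list(
    fractions = tibble::as_tibble(cbind(
      tibble::tibble(sample_id = samples), tibble::as_tibble(est))),
    residuals = tibble::tibble(sample_id = samples, residual = resid),
    method = "nnls"
  ), class = "deconv_result")
}

#' Evaluate deconvolution estimates against known fractions
#'
#' @param est A `deconv_result`.
#' @param truth Long tibble with `sample_id`, `type`, `fraction` (e.g.,
#'   from [simulate_pseudobulk()]); types absent from a sample count as 0.
#' @return Tibble with per-type `rmse` and `pearson_r` across samples
#'   (`pearson_r` is `NA` when the true fractions are constant or a single
#'   sample is evaluated), plus overall means in attribute `"overall"`.
#' @export
evaluate_deconv <- function(est, truth) {
  stopifnot(inherits(est, "deconv_result"))
  long_est <- tidyr::pivot_longer(est$fractions, -"sample_id",
                                  names_to = "type", values_to = "estimate")
  if (!all(long_est$sample_id %in% truth$sample_id)) {
    stop("`truth` does not cover all estimated samples", call. = FALSE)
  }
  joined <- dplyr::left_join(long_est, truth,
                             by = c("sample_id", "type")) |>
    dplyr::mutate(fraction = dplyr::coalesce(.data$fraction, 0))
  per_type <- joined |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      rmse = sqrt(mean((.data$estimate - .data$fraction)^2)),
      pearson_r = if (dplyr::n() >= 3 && stats::sd(.data$fraction) > 0 &&
                      stats::sd(.data$estimate) > 0) {
        stats::cor(.data$estimate, .data$fraction)
      } else NA_real_,
      .groups = "drop"
    )
  attr(per_type, "overall") <- c(
    rmse = mean(per_type$rmse),
    pearson_r = mean(per_type$pearson_r, na.rm = TRUE)
  )
  per_type
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("Signature matrix: %d marker genes x %d types (kappa %.3g)\n",
              nrow(x$profile), ncol(x$profile), x$condition))
  invisible(x)
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("Deconvolution (%s): %d samples x %d types\n", x$method,
              nrow(x$fractions), ncol(x$fractions) - 1))
  print(utils::head(x$fractions, 5))
  invisible(x)
}
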