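# Functional signature scoring and the two-component Gaussian-mixture
# apoptotic classifier.

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene ids.
#' @param weights Optional per-gene weights, each +1 or -1 (positive or
#'   negative relationship with the scored condition).
#' @return A list of class `signature_set`.
#' @export
signature_set <- function(name, genes, weights = NULL) {
  if (anyDuplicated(genes)) stop("signature genes must be unique", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != length(genes) || !all(weights %in% c(-1, 1))) {
      stop("weights must be one +1/-1 value per gene", call. = FALSE)
    }
    weights <- stats::setNames(as.numeric(weights), genes)
  }
  structure(list(name = name, genes = genes, weights = weights),
            class = "signature_set")
}

#' Read signature sets from a YAML file
#'
#' The file maps signature names to either a plain gene list or a mapping
#' `genes:` / `weights:` for weighted signatures.
#'
#' @param path Path to the YAML file.
#' @return Named list of [signature_set()] objects.
#' @export
read_signatures <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    item <- raw[[nm]]
    if (is.list(item) && !is.null(item$genes)) {
      signature_set(nm, unlist(item$genes), unlist(item$weights))
    } else {
      signature_set(nm, unlist(item))
    }
  })
  stats::setNames(out, names(raw))
}

resolve_signature <- function(normalized, signature, need_weights = FALSE) {
  if (is.character(signature)) signature <- signature_set("signature", signature)
  stopifnot(inherits(signature, "signature_set"))
  present <- intersect(signature$genes, rownames(normalized))
  absent <- setdiff(signature$genes, present)
  if (!length(present)) {
    stop(sprintf("no gene of signature '%s' is present in the matrix",
                 signature$name), call. = FALSE)
  }
  if (length(absent)) {
    warning(sprintf("signature '%s': dropping %d absent gene(s): %s",
                    signature$name, length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")))
  }
  if (need_weights && is.null(signature$weights)) {
    stop(sprintf("signature '%s' has no weights", signature$name), call. = FALSE)
  }
  signature$genes <- present
  if (!is.null(signature$weights)) signature$weights <- signature$weights[present]
  signature
}

#' Mean-expression signature score
#'
#' The per-cell score is the unweighted mean of normalized expression over
#' the signature genes present in the matrix (absent genes are dropped with
#' a warning).
#'
#' @param normalized Gene x cell normalized matrix.
#' @param signature A [signature_set()] or plain character vector of genes.
#' @return Named numeric vector of per-cell scores.
#' @export
score_mean <- function(normalized, signature) {
  stopifnot_counts(normalized)
  sig <- resolve_signature(normalized, signature)
  x <- as_dgc(normalized)[sig$genes, , drop = FALSE]
  stats::setNames(as.numeric(Matrix::colMeans(x)), colnames(normalized))
}

#' Weighted z-score signature score
#'
#' Each gene's normalized expression is z-scored across all cells; the
#' per-cell score is the mean of `weight * z` over the signature genes,
#' with weights +1/-1 marking positive and negative relationships.
#' Zero-variance genes are dropped.
#'
#' @inheritParams score_mean
#' @return Named numeric vector of per-cell scores.
#' @export
score_weighted_z <- function(normalized, signature) {
  stopifnot_counts(normalized)
  sig <- resolve_signature(normalized, signature, need_weights = TRUE)
  x <- as.matrix(as_dgc(normalized)[sig$genes, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) {
    stop(sprintf("all genes of signature '%s' are constant", sig$name),
         call. = FALSE)
  }
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  w <- sig$weights[keep]
  stats::setNames(as.numeric(colMeans(w * z)), colnames(normalized))
}

#' Score several signatures at once
#'
#' @param normalized Gene x cell normalized matrix.
#' @param signatures Named list of [signature_set()] objects; weighted
#'   signatures are scored with [score_weighted_z()], plain ones with
#'   [score_mean()].
#' @return Tibble with `barcode` and one column per signature.
#' @export
score_signatures <- function(normalized, signatures) {
  scores <- lapply(signatures, function(sig) {
    if (is.null(sig$weights)) score_mean(normalized, sig)
    else score_weighted_z(normalized, sig)
  })
  tibble::as_tibble(c(list(barcode = colnames(normalized)), scores))
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Expectation-maximization from several starts (a below/above-median
#' responsibility split first, random responsibilities for the rest), with
#' the best log-likelihood solution kept. Component variances are floored
#' at `1e-6 * var(values)` to prevent collapse onto single points, and
#' components are canonicalized so component 1 has the lower mean.
#'
#' @param values Numeric vector (>= 10 finite values with positive sd).
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations per start.
#' @param n_init Number of starts.
#' @param seed Seed for the random starts.
#' @return Object of class `gmm1d`: means, variances, weights, per-cell
#'   responsibilities (posterior of component 2, the higher mean),
#'   log-likelihood trace of the best start, and a convergence flag.
#' @export
fit_gmm_1d <- function(values, tol = 1e-8, max_iter = 500, n_init = 5,
                       seed = 0L) {
  v <- values[is.finite(values)]
  if (length(v) < 10 || stats::sd(v) == 0) {
    stop("need >= 10 finite values with positive sd", call. = FALSE)
  }
  var_floor <- 1e-6 * stats::var(v)
  n <- length(v)

  run_em <- function(resp) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # M step
      wsum <- colSums(resp)
      wsum <- pmax(wsum, 1e-12)
      pi_k <- wsum / n
      mu <- colSums(resp * v) / wsum
      va <- pmax(colSums(resp * (outer(v, mu, "-")^2)) / wsum, var_floor)
      # E step + log-likelihood
      dens <- cbind(pi_k[1] * stats::dnorm(v, mu[1], sqrt(va[1])),
                    pi_k[2] * stats::dnorm(v, mu[2], sqrt(va[2])))
      tot <- rowSums(dens)
      tot <- pmax(tot, .Machine$double.xmin)
      ll <- sum(log(tot))
      resp <- dens / tot
      trace <- c(trace, ll)
      if (ll - ll_old < tol && iter > 1) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(mu = mu, va = va, pi = pi_k, resp = resp, trace = trace,
         converged = converged)
  }

  fits <- with_seed(seed, {
    lapply(seq_len(n_init), function(init) {
      resp <- if (init == 1) {
        r <- as.numeric(v > stats::median(v))
        cbind(1 - 0.9 * r - 0.05, 0.9 * r + 0.05)
      } else {
        r <- stats::runif(n)
        cbind(1 - r, r)
      }
      run_em(resp)
    })
  })
  best <- fits[[which.max(vapply(fits, function(f) max(f$trace), numeric(1)))]]
  ord <- order(best$mu)
  resp2 <- best$resp[, ord[2]]
  full_resp <- rep(NA_real_, length(values))
  full_resp[is.finite(values)] <- resp2
  structure(list(
    means = best$mu[ord], variances = best$va[ord], weights = best$pi[ord],
    responsibilities = stats::setNames(full_resp, names(values)),
    loglik_trace = best$trace, loglik = max(best$trace),
    converged = best$converged, n = n
  ), class = "gmm1d")
}

#' Classify cells as apoptotic from a fitted mixture
#'
#' The component with the higher mean score is designated the apoptotic
#' group; a cell is called apoptotic when its posterior for that component
#' exceeds 0.5 (a tie at exactly 0.5 is resolved as non-apoptotic).
#'
#' @param fit A `gmm1d` fit of the apoptotic score.
#' @return Tibble with `cell`, `posterior` (apoptotic-component posterior)
#'   and `apoptotic`; the apoptotic fraction is in attribute `"fraction"`.
#' @export
classify_apoptotic <- function(fit) {
  stopifnot(inherits(fit, "gmm1d"))
  post <- fit$responsibilities
  label <- !is.na(post) & post > 0.5
  out <- tibble::tibble(
    cell = names(post) %||% as.character(seq_along(post)),
    posterior = as.numeric(post), apoptotic = label
  )
  attr(out, "fraction") <- mean(label[!is.na(post)])
  out
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("Two-component Gaussian mixture (1-D EM)\n")
  cat(sprintf("  means: %.4f / %.4f\n", x$means[1], x$means[2]))
  cat(sprintf("  sds:   %.4f / %.4f\n", sqrt(x$variances[1]), sqrt(x$variances[2])))
  cat(sprintf("  weights: %.3f / %.3f; logLik %.2f (%s)\n",
              x$weights[1], x$weights[2], x$loglik,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
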