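# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_gmm_1d Tidy the component parameters (one row per
#'   component).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.gmm1d <- function(x, ...) {
  tibble::tibble(
    component = c(1L, 2L),
    mean = x$means, variance = x$variances, weight = x$weights
  )
}

#' @describeIn fit_gmm_1d One-row model summary.
#' @export
glance.gmm1d <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n = x$n, iterations = length(x$loglik_trace),
    converged = x$converged
  )
}

#' @describeIn logistic_irls Tidy coefficient table (term, estimate,
#'   std_error, statistic, p).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.logit_fit <- function(x, ...) {
  x$coefficients
}

#' @describeIn logistic_irls One-row model summary.
#' @export
glance.logit_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, logLik = x$loglik, df = nrow(x$coefficients),
    converged = x$converged
  )
}

#' @describeIn nmf_factorize Tidy gene loadings (long form).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.nmf_fit <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$W) %||% as.character(seq_len(nrow(x$W))), x$rank),
    module = rep(colnames(x$W), each = nrow(x$W)),
    weight = as.vector(x$W)
  )
}

#' @describeIn nmf_factorize One-row fit summary.
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble::tibble(rank = x$rank, rss = x$rss, iterations = x$iterations,
                 converged = x$converged)
}

#' @describeIn deconvolve Long (sample, type, fraction) table with
#'   residual norms joined per sample.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.deconv_result <- function(x, ...) {
  tidyr::pivot_longer(x$fractions, -"sample_id", names_to = "type",
                      values_to = "fraction") |>
    dplyr::left_join(x$residuals, by = "sample_id")
}
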