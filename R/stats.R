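# Association statistics: correlation and two-sample tests, Holm
# correction, ROC/AUC, and the interaction logistic model fitted by IRLS.

stat_row <- function(method, estimate, statistic, df, p) {
  tibble::tibble(method = method, estimate = estimate, statistic = statistic,
                 df = df, p = p)
}

#' Pearson correlation test
#'
#' Two-sided test of the Pearson correlation via
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return One-row tibble: method, estimate (r), statistic, df, p.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_row("pearson", unname(ct$estimate), unname(ct$statistic),
           unname(ct$parameter), ct$p.value)
}

#' Welch two-sample t test
#'
#' @param x,y Numeric group vectors (each n >= 2, non-degenerate).
#' @return One-row tibble: method, estimate (mean difference), statistic,
#'   Satterthwaite df, p (two-sided).
#' @export
welch_test <- function(x, y) {
  check_two_groups(x, y)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  stat_row("welch", unname(diff(rev(tt$estimate))), unname(tt$statistic),
           unname(tt$parameter), tt$p.value)
}

#' Student (pooled-variance) two-sample t test
#'
#' @inheritParams welch_test
#' @return One-row tibble like [welch_test()], with pooled df `n1 + n2 - 2`.
#' @export
student_test <- function(x, y) {
  check_two_groups(x, y)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  stat_row("student", unname(diff(rev(tt$estimate))), unname(tt$statistic),
           unname(tt$parameter), tt$p.value)
}

check_two_groups <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(c(x, y)) == 0) {
    stop("degenerate groups: all values identical", call. = FALSE)
  }
  invisible(NULL)
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The AUC is the mean over all positive-negative pairs of
#' `[score_pos > score_neg] + 1/2 [tie]`, computed via midranks; it equals
#' the trapezoidal area under the ROC curve. An optional percentile
#' bootstrap CI resamples cells with replacement within each class.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or two-level factor); both
#'   classes must be present.
#' @param ci Compute a bootstrap confidence interval?
#' @param n_boot Bootstrap replicates.
#' @param conf_level Confidence level.
#' @param seed Bootstrap seed.
#' @return One-row tibble: auc, n_pos, n_neg, ci_low, ci_high.
#' @export
roc_auc <- function(scores, labels, ci = FALSE, n_boot = 2000,
                    conf_level = 0.95, seed = 0L) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  lab <- as.logical(if (is.factor(labels)) as.integer(labels) - 1 else labels)
  if (anyNA(lab) || length(unique(lab)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  auc_point <- auc_ustat(scores, lab)
  lo <- hi <- NA_real_
  if (ci) {
    pos <- scores[lab]; neg <- scores[!lab]
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        auc_ustat(c(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
                  c(rep(TRUE, length(pos)), rep(FALSE, length(neg))))
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    lo <- unname(qs[1]); hi <- unname(qs[2])
  }
  tibble::tibble(auc = auc_point, n_pos = sum(lab), n_neg = sum(!lab),
                 ci_low = lo, ci_high = hi)
}

auc_ustat <- function(scores, lab) {
  r <- rank(scores)
  n1 <- sum(lab); n0 <- sum(!lab)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic regression with an exposure-modifier interaction, by IRLS
#'
#' Fits `outcome ~ exposure * modifier + adjustments` by iteratively
#' reweighted least squares (Newton-Raphson on the binomial log-likelihood)
#' to a gradient norm below `tol`. Continuous covariates are standardized
#' (and thereby centered, so the interaction column is a product of
#' centered fractions and the main effects stay interpretable); standard
#' errors come from the inverse Fisher information, p-values are Wald.
#'
#' @param data Data frame holding all variables.
#' @param outcome Name of the binary outcome column.
#' @param exposure,modifier Names of the interacting covariates.
#' @param adjust Names of adjustment covariates (binary 0/1 columns are
#'   left unscaled).
#' @param standardize Standardize continuous covariates (default TRUE).
#' @param tol Convergence tolerance on the max absolute score.
#' @param max_iter Maximum IRLS iterations (non-convergence is an error).
#' @return Object of class `logit_fit` with `coefficients` (tibble: term,
#'   estimate, std_error, statistic, p), `vcov`, `fitted`, `converged`,
#'   and the scaling info needed for prediction.
#' @export
logistic_irls <- function(data, outcome = "shock",
                          exposure = "neutrophil_pct",
                          modifier = "monocyte_pct",
                          adjust = c("age", "sex"),
                          standardize = TRUE, tol = 1e-8, max_iter = 100) {
  if (is.null(exposure) != is.null(modifier)) {
    stop("`exposure` and `modifier` must be given together (or both NULL ",
         "for an intercept-only/adjustment-only model)", call. = FALSE)
  }
  vars <- c(outcome, exposure, modifier, adjust)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("columns not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) stop("`outcome` must be binary", call. = FALSE)
  n <- length(y)

  scale_info <- list()
  col_for <- function(v) {
    x <- as.numeric(data[[v]])
    if (standardize && length(unique(x)) > 2) {
      mu <- mean(x); sdv <- stats::sd(x)
      scale_info[[v]] <<- c(mean = mu, sd = sdv)
      (x - mu) / sdv
    } else {
      scale_info[[v]] <<- c(mean = 0, sd = 1)
      x
    }
  }
  cols <- list(`(Intercept)` = rep(1, n))
  if (!is.null(exposure)) {
    xe <- col_for(exposure)
    xm <- col_for(modifier)
    cols[[exposure]] <- xe
    cols[[modifier]] <- xm
    cols[[paste0(exposure, ":", modifier)]] <- xe * xm
  }
  for (v in adjust) cols[[v]] <- col_for(v)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  p <- ncol(X)
  if (n <= 10 * p) {
    stop(sprintf("need n > 10 x parameters (n = %d, p = %d)", n, p),
         call. = FALSE)
  }

  beta <- rep(0, p)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    score <- crossprod(X, y - mu)
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- mu * (1 - mu)
    if (any(w < 1e-10) && max(abs(beta)) > 15) {
      stop("detected (quasi-)separation: fitted probabilities collapsed to 0/1",
           call. = FALSE)
    }
    info <- crossprod(X, X * w)
    beta <- beta + solve(info, score)
  }
  if (!converged) {
    stop(sprintf("IRLS did not converge in %d iterations", max_iter),
         call. = FALSE)
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  vcov <- solve(crossprod(X, X * (mu * (1 - mu))))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  zstat <- as.vector(beta) / se
  coefs <- tibble::tibble(
    term = colnames(X), estimate = as.vector(beta), std_error = se,
    statistic = zstat, p = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  )
  structure(list(
    coefficients = coefs, vcov = vcov, fitted = mu, converged = converged,
    outcome = outcome, exposure = exposure, modifier = modifier,
    adjust = adjust, scale_info = scale_info, n = n,
    data_ranges = if (!is.null(exposure)) {
      list(exposure = range(data[[exposure]]),
           modifier = range(data[[modifier]]))
    },
    modifier_values = if (!is.null(modifier)) as.numeric(data[[modifier]]),
    loglik = sum(y * log(pmax(mu, 1e-300)) +
                   (1 - y) * log(pmax(1 - mu, 1e-300)))
  ), class = "logit_fit")
}

#' Predicted shock probability along the exposure, stratified by modifier
#'
#' Evaluates the fitted interaction model on a grid of exposure values at
#' fixed modifier quantiles, holding adjustment covariates at their
#' reference (mean for continuous, 0 for binary) values.
#'
#' @param fit A `logit_fit`.
#' @param exposure_grid Exposure values (default: 25 points spanning the
#'   observed range; values outside the observed range trigger a warning).
#' @param modifier_quantiles Modifier quantiles defining the strata.
#' @return Tibble: exposure, modifier_quantile, modifier_value,
#'   probability.
#' @export
stratified_effect_curve <- function(fit, exposure_grid = NULL,
                                    modifier_quantiles = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(fit, "logit_fit"))
  rng <- fit$data_ranges$exposure
  if (is.null(exposure_grid)) {
    exposure_grid <- seq(rng[1], rng[2], length.out = 25)
  } else if (any(exposure_grid < rng[1] | exposure_grid > rng[2])) {
    warning("exposure grid extends outside the observed range")
  }
  mod_vals <- stats::quantile(fit$modifier_values, modifier_quantiles)
  sc <- fit$scale_info
  ze <- (exposure_grid - sc[[fit$exposure]]["mean"]) / sc[[fit$exposure]]["sd"]
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  rows <- lapply(seq_along(mod_vals), function(i) {
    zm <- (mod_vals[i] - sc[[fit$modifier]]["mean"]) / sc[[fit$modifier]]["sd"]
    eta <- beta["(Intercept)"] + beta[fit$exposure] * ze +
      beta[fit$modifier] * zm +
      beta[paste0(fit$exposure, ":", fit$modifier)] * ze * zm
    # adjustment covariates at reference: standardized continuous -> 0,
    # binary -> 0, so they contribute nothing to eta
    tibble::tibble(exposure = exposure_grid,
                   modifier_quantile = modifier_quantiles[i],
                   modifier_value = unname(mod_vals[i]),
                   probability = stats::plogis(unname(eta)))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Interaction logistic model (IRLS), n = %d, logLik = %.2f\n",
              x$n, x$loglik))
  print(x$coefficients)
  invisible(x)
}
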