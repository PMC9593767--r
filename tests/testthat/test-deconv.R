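make_labeled_fixture <- function() {
  cached("deconv_fixture", {
    fx <- tiny_atlas()
    refined <- ifelse(is.na(fx$cells$subtype), fx$cells$cell_type,
                      fx$cells$subtype)
    keep_types <- names(which(table(refined) >= 10))
    sel <- refined %in% keep_types
    list(normalized = fx$normalized[, sel],
         counts = fx$sim$counts[, colnames(fx$normalized)[sel]],
         labels = refined[sel],
         samples = fx$cells$sample_id[sel])
  })
}

test_that("signature matrix holds per-type linear means of top markers", {
  fx <- make_labeled_fixture()
  sig <- build_signature_matrix(fx$normalized, fx$labels, markers_per_type = 15)
  expect_true(all(sig$profile >= 0))
  expect_true(all(table(sig$markers$cluster) <= 15))
  expect_setequal(colnames(sig$profile), unique(fx$labels))
  # entries are the per-type mean of expm1(normalized)
  g <- rownames(sig$profile)[1]
  tp <- colnames(sig$profile)[1]
  manual <- mean(expm1(fx$normalized[g, fx$labels == tp]))
  expect_equal(sig$profile[g, tp], manual, tolerance = 1e-12)
  # planted subtypes are distinguishable: no near-collinear signature pair
  cors <- stats::cor(sig$profile)
  expect_lt(max(cors[upper.tri(cors)]), 0.95)
  expect_error(build_signature_matrix(fx$normalized,
                                      replace(fx$labels, 1:3, "rare")),
               "fewer than 10")
  expect_warning(build_signature_matrix(fx$normalized, fx$labels,
                                        markers_per_type = 1e5), "capping")
})

test_that("noiseless mixtures of signature columns are recovered exactly", {
  fx <- make_labeled_fixture()
  sig <- build_signature_matrix(fx$normalized, fx$labels, markers_per_type = 25)
  S <- sig$profile
  set.seed(14)
  f_true <- t(vapply(1:8, function(i) {
    f <- stats::rgamma(ncol(S), 1)
    f / sum(f)
  }, numeric(ncol(S))))
  bulk <- S %*% t(f_true) * 1e3
  colnames(bulk) <- sprintf("mix%02d", 1:8)
  est <- deconvolve(bulk, sig)
  est_mat <- as.matrix(est$fractions[, colnames(S)])
  expect_lt(max(abs(est_mat - f_true)), 0.01)
  # bulk equal to one signature column -> indicator fractions
  one <- deconvolve(matrix(S[, 2] * 500, ncol = 1,
                           dimnames = list(rownames(S), "b1")), sig)
  est1 <- as.matrix(one$fractions[, colnames(S)])
  expect_gt(est1[1, 2], 0.99)
  # scale invariance of each bulk column
  est_scaled <- deconvolve(bulk * 37.5, sig)
  expect_equal(as.matrix(est_scaled$fractions[, colnames(S)]), est_mat,
               tolerance = 1e-9)
  # an unexpressed dummy gene changes nothing
  S2 <- rbind(S, DUMMY = 0)
  bulk2 <- rbind(bulk, DUMMY = 0)
  est_dummy <- deconvolve(bulk2, S2)
  expect_equal(as.matrix(est_dummy$fractions[, colnames(S)]), est_mat,
               tolerance = 1e-9)
})

test_that("gene-coverage and scale guards fire", {
  fx <- make_labeled_fixture()
  sig <- build_signature_matrix(fx$normalized, fx$labels, markers_per_type = 20)
  S <- sig$profile
  bulk <- matrix(S[, 1] * 200, ncol = 1,
                 dimnames = list(rownames(S), "b1"))
  few <- bulk[1:floor(nrow(S) * 0.3), , drop = FALSE]
  expect_error(deconvolve(few, sig), "signature genes present")
  expect_warning(deconvolve(log1p(bulk), sig), "log-scale")
})

test_that("pseudobulk deconvolution tracks the true fractions", {
  fx <- make_labeled_fixture()
  sig <- build_signature_matrix(fx$normalized, fx$labels, markers_per_type = 30)
  pb <- simulate_pseudobulk(fx$counts, fx$labels, fx$samples, noise_cv = 0)
  est <- deconvolve(pb$bulk, sig)
  ev <- evaluate_deconv(est, pb$fractions)
  # the severity-associated subtype is the fraction the analysis relies on
  expect_gt(ev$pearson_r[ev$type == "Neu1"], 0.8)
  expect_lt(attr(ev, "overall")["rmse"], 0.1)
})

test_that("deconvolution evaluation guards its degenerate cases", {
  truth <- tibble::tibble(sample_id = rep(c("s1", "s2", "s3"), each = 2),
                          type = rep(c("A", "B"), 3),
                          fraction = c(0.3, 0.7, 0.5, 0.5, 0.8, 0.2))
  est <- structure(list(
    fractions = tibble::tibble(sample_id = c("s1", "s2", "s3"),
                               A = c(0.3, 0.5, 0.8), B = c(0.7, 0.5, 0.2)),
    residuals = tibble::tibble(sample_id = c("s1", "s2", "s3"),
                               residual = 0),
    method = "nnls"), class = "deconv_result")
  ev <- evaluate_deconv(est, truth)
  expect_equal(ev$rmse, c(0, 0))
  expect_equal(ev$pearson_r, c(1, 1))
  # permuted estimates decorrelate
  set.seed(9)
  r_perm <- replicate(50, {
    p <- sample(3)
    est2 <- est
    est2$fractions$A <- est$fractions$A[p]
    est2$fractions$B <- est$fractions$B[p]
    mean(evaluate_deconv(est2, truth)$pearson_r)
  })
  expect_lt(abs(mean(r_perm)), 0.35)
  # single sample: correlation undefined, rmse still valid
  est1 <- est
  est1$fractions <- est1$fractions[1, ]
  est1$residuals <- est1$residuals[1, ]
  ev1 <- evaluate_deconv(est1, truth)
  expect_true(all(is.na(ev1$pearson_r)))
  expect_equal(ev1$rmse, c(0, 0))
})
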