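test_that("mean signature scores reduce to the defining arithmetic", {
  m <- Matrix::Matrix(matrix(2, 3, 4, dimnames = list(c("a", "b", "c"),
                                                      sprintf("c%d", 1:4))),
                      sparse = TRUE)
  # constant matrix -> constant score
  expect_equal(unname(score_mean(m, c("a", "b"))), rep(2, 4))
  # single-gene signature is that gene's expression
  m2 <- m
  m2[1, ] <- c(1, 2, 3, 4)
  expect_equal(unname(score_mean(m2, "a")), c(1, 2, 3, 4))
  # absent genes are dropped with a warning; all-absent errors
  expect_warning(s <- score_mean(m2, c("a", "zz")), "absent")
  expect_equal(unname(s), c(1, 2, 3, 4))
  expect_error(suppressWarnings(score_mean(m2, c("zz"))), "no gene")
  # linearity: adding a constant shifts every score by that constant
  m3 <- m2
  m3@x <- m3@x + 1.5
  expect_equal(score_mean(m3, c("a", "b")), score_mean(m2, c("a", "b")) + 1.5)
})

test_that("weighted z scores follow the +1/-1 z-average definition", {
  set.seed(4)
  m <- matrix(stats::rnorm(40), 2, 20,
              dimnames = list(c("up", "down"), sprintf("c%02d", 1:20)))
  ms <- Matrix::Matrix(m, sparse = TRUE)
  sig <- signature_set("aging", c("up", "down"), c(1, -1))
  s <- score_weighted_z(ms, sig)
  z <- t(scale(t(m)))
  expect_equal(unname(s), unname(colMeans(c(1, -1) * z)), tolerance = 1e-12)
  # each per-gene z column has mean 0, so single-gene +1 score is the z-score
  s1 <- score_weighted_z(ms, signature_set("one", "up", 1))
  expect_equal(unname(s1), unname(z["up", ]), tolerance = 1e-12)
  expect_lt(abs(mean(s1)), 1e-9)
  # flipping all weights negates every score exactly
  flipped <- signature_set("flip", c("up", "down"), c(-1, 1))
  expect_equal(score_weighted_z(ms, flipped), -s, tolerance = 1e-12)
  # direct arithmetic: a cell at z = (1, -0.5) with weights (+1, -1)
  zc <- which.min(abs(z["up", ] - 1))
  expected <- (z["up", zc] - z["down", zc]) / 2
  expect_equal(unname(s[zc]), unname(expected))
  expect_error(signature_set("bad", c("a", "b"), c(1, 2)), "\\+1/-1")
  expect_error(score_weighted_z(ms, signature_set("nw", "up")), "no weights")
})

test_that("packaged signature YAML round-trips into signature sets", {
  sigs <- read_signatures(system.file("extdata", "signatures.yaml",
                                      package = "neumod"))
  expect_true(all(c("apoptosis", "aging", "neutrophil_markers") %in% names(sigs)))
  expect_null(sigs$apoptosis$weights)
  expect_equal(unname(sigs$aging$weights), c(1, 1, 1, -1, -1, -1))
})

test_that("EM recovers a well-separated mixture and is monotone", {
  set.seed(19)
  v <- c(stats::rnorm(2500, 0, 1), stats::rnorm(2500, 4, 1))
  fit <- fit_gmm_1d(v, seed = 1)
  expect_lt(abs(fit$means[1] - 0), 0.1)
  expect_lt(abs(fit$means[2] - 4), 0.1)
  expect_lt(abs(fit$weights[1] - 0.5), 0.03)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(fit$converged)
  # canonical order: component 1 is the lower mean
  expect_lt(fit$means[1], fit$means[2])

  calls <- classify_apoptotic(fit)
  truth <- rep(c(FALSE, TRUE), each = 2500)
  expect_gt(mean(calls$apoptotic == truth), 0.95)

  # cross-check the maximized likelihood against an independent EM engine
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust)) # Mclust needs its namespace attached
  mc <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("degenerate mixture inputs behave as documented", {
  expect_error(fit_gmm_1d(rep(1, 50)), "positive sd")
  expect_error(fit_gmm_1d(c(1, 2)), "10 finite")
  # single Gaussian: components nearly coincide, split is near chance
  set.seed(2)
  v <- stats::rnorm(2000)
  fit <- fit_gmm_1d(v, seed = 3)
  expect_lt(abs(fit$means[2] - fit$means[1]), 1.5)
  # equal-parameter tie: posteriors exactly 0.5 -> nobody is apoptotic
  tie <- structure(list(
    means = c(0, 0), variances = c(1, 1), weights = c(0.5, 0.5),
    responsibilities = rep(0.5, 10), loglik_trace = 0, loglik = 0,
    converged = TRUE, n = 10), class = "gmm1d")
  calls <- classify_apoptotic(tie)
  expect_equal(attr(calls, "fraction"), 0)
})

test_that("planted apoptosis program separates scored cells", {
  fx <- tiny_atlas()
  neu <- !is.na(fx$cells$subtype)
  sigs <- read_signatures(system.file("extdata", "signatures.yaml",
                                      package = "neumod"))
  s <- score_mean(fx$normalized[, neu], sigs$apoptosis)
  apop <- fx$cells$apoptotic[neu]
  expect_lt(stats::wilcox.test(s[apop], s[!apop],
                               alternative = "greater")$p.value, 1e-6)
})
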