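test_that("an exact low-rank matrix is recovered to numerical precision", {
  set.seed(6)
  w <- stats::runif(30)
  h <- stats::runif(50)
  V <- outer(w, h)
  fit <- nmf_factorize(V, 1, seed = 2)
  expect_lt(fit$rss / sum(V^2), 1e-6)
  expect_error(nmf_factorize(V - 1, 1), "non-negative")
  expect_error(nmf_factorize(V, 30), "smaller")
})

test_that("updates keep factors non-negative and the objective monotone", {
  mm <- simulate_module_matrix(n_genes = 120, n_cells = 150, n_modules = 3,
                               genes_per_module = 30, seed = 9)
  fit <- nmf_factorize(mm$V, 3, seed = 1)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  # rss never increases across iterations (up to fp roundoff of the
  # expanded norm computation)
  expect_true(all(diff(fit$rss_trace) <= 1e-8 * fit$rss_trace[1]))
  # canonical L1 scaling leaves the reconstruction unchanged
  expect_equal(unname(colSums(fit$W)), rep(1, 3), tolerance = 1e-12)
  recon <- fit$W %*% fit$H
  expect_lt(abs(sum((mm$V - recon)^2) - fit$rss) / fit$rss, 1e-6)
})

test_that("best-of-restarts rss is non-increasing in the rank", {
  mm <- simulate_module_matrix(n_genes = 100, n_cells = 120, n_modules = 3,
                               genes_per_module = 25, seed = 3)
  best <- function(r) min(vapply(1:5, function(s)
    nmf_factorize(mm$V, r, seed = s, max_iter = 300)$rss, numeric(1)))
  rs <- vapply(2:4, best, numeric(1))
  expect_true(all(diff(rs) <= 0))
})

test_that("consensus metrics hit their ideal values on disjoint blocks", {
  # three blocks of cells, each expressing its own gene block only
  set.seed(12)
  V <- matrix(0.01, 60, 90)
  for (b in 1:3) {
    V[(b - 1) * 20 + 1:20, (b - 1) * 30 + 1:30] <-
      matrix(stats::runif(600, 5, 10), 20, 30)
  }
  met <- consensus_metrics(V, ranks = c(3, 4), n_runs = 10, seed = 1)
  r3 <- met[met$rank == 3, ]
  expect_equal(r3$cophenetic, 1, tolerance = 1e-9)
  expect_equal(r3$dispersion, 1, tolerance = 1e-9)
  expect_equal(select_rank(met), 3)
  expect_error(consensus_metrics(V, ranks = 3, n_runs = 10), "2 candidate")
  expect_error(consensus_metrics(V, ranks = c(3, 4), n_runs = 5), "n_runs")
  expect_error(consensus_metrics(V, ranks = c(3, 95), n_runs = 10), "cells")
})

test_that("rank selection follows cophenetic-then-dispersion tie-breaks", {
  met <- tibble::tibble(rank = c(3, 4, 5), cophenetic = c(0.99, 0.95, 0.80),
                        rss = c(3, 2, 1), dispersion = c(0.9, 0.8, 0.7),
                        silhouette = c(0.8, 0.7, 0.6), n_runs = 10)
  expect_equal(select_rank(met), 3)
  met$cophenetic <- c(0.99, 0.99, 0.8)
  met$dispersion <- c(0.6, 0.8, 0.7)
  expect_equal(select_rank(met), 4)
  met$dispersion <- c(0.8, 0.8, 0.7)
  expect_equal(select_rank(met), 3) # remaining tie -> smaller rank
})

test_that("module usage is a normalized partition of each cell", {
  H <- rbind(M1 = c(2, 1, 0.5), M2 = c(0, 1, 0.5), M3 = c(0, 2, 1))
  colnames(H) <- c("a", "b", "c")
  u <- module_usage(H)
  expect_equal(u$usage[u$cell == "a"], c(1, 0, 0))
  sums <- tapply(u$usage, u$cell, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  H0 <- H; H0[, 2] <- 0
  expect_error(module_usage(H0), "all-zero")
  agg <- aggregate_usage(u, c(a = "s1", b = "s1", c = "s2"))
  expect_equal(agg$usage[agg$sample_id == "s1" & agg$module == "M1"],
               mean(c(1, 1 / 4)))
})

test_that("top genes are weight-ranked with deterministic ties", {
  W <- matrix(0, 5, 2, dimnames = list(c("e", "d", "c", "b", "a"), NULL))
  W["c", 1] <- 3
  W[c("a", "b"), 2] <- 2 # tied -> alphabetical
  tg <- top_genes(W, n = 2)
  expect_equal(tg$gene[tg$module == "M1"][1], "c")
  expect_equal(tg$gene[tg$module == "M2"], c("a", "b"))
  expect_error(top_genes(W, n = 10), "exceed")
  # fully disjoint planted modules give disjoint top lists
  mm <- simulate_module_matrix(n_genes = 120, n_cells = 150, n_modules = 3,
                               genes_per_module = 30, overlap = 0,
                               noise_cv = 0.1, seed = 5)
  fit <- nmf_factorize(mm$V, 3, seed = 2)
  tg <- top_genes(fit, n = 15)
  lists <- split(tg$gene, tg$module)
  expect_equal(length(unique(unlist(lists))), 45)
})

test_that("severity-coupled module usage is recovered from the factorization", {
  samples <- sprintf("S%02d", 1:32)
  set.seed(30)
  severity <- stats::setNames(sample(2:22, 32, replace = TRUE), samples)
  mm <- simulate_module_matrix(
    n_genes = 150, n_cells = 640, n_modules = 3, genes_per_module = 40,
    sample_ids = rep(samples, each = 20), severity = severity,
    coupled_module = 2, coupling = 1.5, seed = 8)
  fit <- nmf_factorize(mm$V, 3, seed = 4)
  usage <- module_usage(fit)
  agg <- aggregate_usage(usage, stats::setNames(mm$sample_ids, colnames(mm$V)))
  # identify the fitted module matching the planted coupled one by W cosine
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  match_idx <- which.max(vapply(1:3, function(j)
    cosine(mm$W_true[, 2], fit$W[, j]), numeric(1)))
  mod <- paste0("M", match_idx)
  per_sample <- agg[agg$module == mod, ]
  r <- stats::cor.test(per_sample$usage, severity[per_sample$sample_id])
  expect_gt(r$estimate, 0)
  expect_lt(r$p.value, 0.01)
})
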