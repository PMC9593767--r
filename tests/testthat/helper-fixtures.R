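# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete synthetic cohort used across modules.
tiny_atlas <- function() {
  cached("tiny_atlas", {
    sim <- simulate_atlas(sim_config(
      n_samples = 6, n_cells_per_sample = 350, n_genes = 900, seed = 42))
    qc <- compute_qc(sim$counts)
    keep <- filter_cells(qc)
    normalized <- normalize_log(sim$counts[, keep])
    cells <- sim$cells[match(colnames(normalized), sim$cells$barcode), ]
    list(sim = sim, qc = qc, keep = keep, normalized = normalized,
         cells = cells)
  })
}

# Two well-separated Gaussian blobs in a low-dimensional embedding.
two_blobs <- function(n_per = 100, d = 5, sep = 8, seed = 1) {
  set.seed(seed)
  emb <- rbind(
    matrix(stats::rnorm(n_per * d), n_per, d),
    matrix(stats::rnorm(n_per * d, mean = sep), n_per, d)
  )
  rownames(emb) <- sprintf("c%03d", seq_len(2 * n_per))
  list(embedding = emb, truth = rep(c(0, 1), each = n_per))
}

# Brute-force Hubert-Arabie ARI straight from the pair-counting definition:
# for every pair of items, tally agreement of co-membership.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  total <- n * (n - 1) / 2
  sum_ij <- n11
  sum_a <- n11 + n10
  sum_b <- n11 + n01
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-14) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Exact rank-sum p-value by enumerating all group assignments (tie-free
# data, small groups only).
wilcox_exact_enum <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(v), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Independent Newton-Raphson logistic fit (the oracle for logistic_irls);
# written directly from the score and Hessian of the Bernoulli likelihood.
logit_newton_oracle <- function(X, y, tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-as.vector(X %*% beta)))
    g <- t(X) %*% (y - p)
    Hm <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(Hm, g)
    beta <- beta + step
    if (max(abs(g)) < tol) break
  }
  list(beta = as.vector(beta), se = sqrt(diag(solve(Hm))))
}
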