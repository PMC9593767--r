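test_that("atlas simulation is bit-reproducible and internally consistent", {
  cfg <- sim_config(n_samples = 4, n_cells_per_sample = 120, n_genes = 850,
                    seed = 11)
  a <- simulate_atlas(cfg)
  b <- simulate_atlas(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)

  # counts are non-negative integers
  expect_true(all(a$counts@x >= 0))
  expect_true(all(a$counts@x == round(a$counts@x)))

  # planted per-sample fractions sum to 1
  sums <- tapply(a$truth$fractions$fraction, a$truth$fractions$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # shock implies a cardiovascular SOFA component of at least 2
  expect_true(all(a$samples$sofa_circulation[a$samples$shock] >= 2))
  expect_true(all(a$samples$sofa >= 0 & a$samples$sofa <= 24))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_genes = -5), "n_genes")
  expect_error(sim_config(n_mito_genes = 900, n_genes = 900), "n_mito_genes")
  expect_error(
    sim_config(major_type_proportions = c(Neutrophil = 0.6, Monocyte = 0.2)),
    "major_type_proportions")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(shock_model = list(intercept = 0)), "shock_model")
})

test_that("marker fold change materializes at the planted magnitude", {
  # expectation derived from the generator's mean model: markers are
  # up-shifted 2^3 in their type's gene-proportion vector before
  # renormalization, so the linear-scale normalized expression ratio
  # own-type vs rest is slightly below 8
  cfg <- sim_config(n_samples = 4, n_cells_per_sample = 300, n_genes = 850,
                    marker_log2fc = 3, seed = 5)
  sim <- simulate_atlas(cfg)
  norm <- normalize_log(sim$counts)
  lin <- norm
  lin@x <- expm1(lin@x)
  is_neu <- sim$cells$cell_type == "Neutrophil"
  mk <- sim$truth$markers
  neu_markers <- mk$gene[mk$role == "type_marker" & mk$target == "Neutrophil"]
  own <- Matrix::rowMeans(lin[neu_markers, is_neu])
  rest <- Matrix::rowMeans(lin[neu_markers, !is_neu])
  ratio <- mean(own) / mean(rest)
  expect_gt(ratio, 6)
  expect_lt(ratio, 10)
})

test_that("severity coupling drives the planted Neu1 fraction", {
  frac_by_sev <- function(coupling, seed) {
    cfg <- sim_config(n_samples = 30, n_cells_per_sample = 60, n_genes = 850,
                      severity_coupling = coupling, seed = seed)
    sim <- simulate_atlas(cfg)
    neu1 <- sim$cells |>
      dplyr::filter(!is.na(.data$subtype)) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(f = mean(.data$subtype == "Neu1"), .groups = "drop")
    merged <- dplyr::left_join(neu1, sim$samples, by = "sample_id")
    merged
  }
  # no planted effect: severity and Neu1 fraction uncorrelated
  m0 <- frac_by_sev(0, 21)
  expect_gt(stats::cor.test(m0$f, m0$sofa)$p.value, 0.05)
  # planted effect: strong positive association, monotone in the coupling
  m1 <- frac_by_sev(1, 21)
  m2 <- frac_by_sev(2.5, 21)
  hi1 <- mean(m1$f[m1$sofa > stats::median(m1$sofa)])
  hi2 <- mean(m2$f[m2$sofa > stats::median(m2$sofa)])
  expect_gt(stats::cor(m1$f, m1$sofa), 0)
  expect_gt(hi2, hi1)
})

test_that("pseudobulk mixtures are exact column sums without noise", {
  sim <- tiny_atlas()$sim
  pb <- simulate_pseudobulk(sim$counts, sim$cells$cell_type,
                            sim$cells$sample_id, noise_cv = 0)
  s1 <- sim$samples$sample_id[1]
  manual <- Matrix::rowSums(sim$counts[, sim$cells$sample_id == s1])
  expect_equal(pb$bulk[, s1], manual, ignore_attr = TRUE)
  sums <- tapply(pb$fractions$fraction, pb$fractions$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # degenerate case: one sample, one type -> indicator fraction vector
  one <- simulate_pseudobulk(sim$counts[, 1:20], rep("A", 20), rep("s1", 20))
  expect_equal(one$fractions$fraction, 1)

  # reproducible under noise, different under another seed
  n1 <- simulate_pseudobulk(sim$counts, sim$cells$cell_type,
                            sim$cells$sample_id, noise_cv = 0.1, seed = 3)
  n2 <- simulate_pseudobulk(sim$counts, sim$cells$cell_type,
                            sim$cells$sample_id, noise_cv = 0.1, seed = 3)
  expect_identical(n1$bulk, n2$bulk)
  expect_error(simulate_pseudobulk(sim$counts, sim$cells$cell_type,
                                   rep(NA_character_, ncol(sim$counts))),
               "sample id")
})

test_that("clinical table obeys the planted shock model", {
  cfg <- sim_config(shock_model = list(intercept = 0, neutrophil = 0,
                                       monocyte = 0, interaction = 0,
                                       age = 0, sex = 0))
  expect_error(simulate_clinical_table(cfg, 10), "at least 50")
  # all-null model: prevalence ~ 0.5 (binomial 99.9% band at n = 5000)
  clin <- simulate_clinical_table(cfg, 5000, seed = 8)
  expect_gt(mean(clin$shock), 0.5 - 3.3 * sqrt(0.25 / 5000))
  expect_lt(mean(clin$shock), 0.5 + 3.3 * sqrt(0.25 / 5000))
  expect_true(all(clin$neutrophil_pct + clin$monocyte_pct +
                    clin$band_pct <= 100))

  # null interaction is recovered as null
  cfg0 <- sim_config(shock_model = list(intercept = -0.5, neutrophil = 0.8,
                                        monocyte = -0.5, interaction = 0,
                                        age = 0.3, sex = 0.1))
  clin0 <- simulate_clinical_table(cfg0, 3000, seed = 9)
  fit <- logistic_irls(clin0)
  inter <- fit$coefficients[
    fit$coefficients$term == "neutrophil_pct:monocyte_pct", ]
  expect_lt(abs(inter$estimate), 2 * inter$std_error)
})

test_that("module-matrix generator plants recoverable usage structure", {
  mm <- simulate_module_matrix(n_genes = 200, n_cells = 300, n_modules = 3,
                               genes_per_module = 40, seed = 4)
  expect_true(all(mm$V >= 0))
  expect_equal(dim(mm$V), c(200, 300))
  expect_true(all(abs(rowSums(mm$usage_true) - 1) < 1e-12))
  # the dominant module has the largest planted usage for most cells
  agree <- mean(max.col(mm$usage_true) == mm$dominant)
  expect_gt(agree, 0.8)
})
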