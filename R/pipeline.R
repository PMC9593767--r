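# End-to-end orchestration: simulate -> QC -> first-pass clustering ->
# neutrophil subset -> stability-selected subtype clustering -> signature
# scoring -> NMF metagene modules -> pseudobulk deconvolution ->
# severity-association statistics, with one structured report.

#' Pipeline configuration
#'
#' Stage parameters default to the published workflow values where those
#' are printed (first-pass resolution 0.15, subtype-scan grid including
#' 0.2, 90% subsampling with 20 iterations, QC at 200/2500 features and
#' 10% mitochondrial UMIs) and to standard workflow defaults elsewhere.
#'
#' @param sim A [sim_config()] describing the synthetic cohort (its seed is
#'   overridden by the pipeline's stage seed so one global seed reproduces
#'   the whole run).
#' @param stages Named logical toggles for qc, cluster, subtypes, scoring,
#'   nmf, deconv, stats.
#' @param qc_min_features,qc_max_features,qc_max_mito QC thresholds.
#' @param norm_scale Library-size scale factor of the normalization.
#' @param n_hvg,n_pcs,knn_k Embedding parameters.
#' @param first_resolution First-pass clustering resolution.
#' @param subtype_resolutions Stability-scan grid for the second pass.
#' @param subsample_fraction,n_iterations,delta Stability-scan parameters.
#' @param signatures Path to a signature YAML (default: the packaged
#'   example signatures matching the generator's planted programs).
#' @param target_signature Name of the signature (in `signatures`) whose
#'   score identifies the clustering compartment to subcluster; defaults to
#'   canonical neutrophil markers.
#' @param nmf_ranks,nmf_runs,nmf_hvg NMF rank grid, consensus runs, and the
#'   number of most-variable genes of the target subtype fed to the
#'   factorization.
#' @param markers_per_type Signature-matrix markers per type.
#' @param pseudobulk_noise_cv Lognormal noise CV of the pseudobulk mixtures.
#' @param clinical_n Patients in the simulated clinical table.
#' @param seed Global seed; per-stage seeds are derived by fixed offsets.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c(qc = TRUE, cluster = TRUE,
                                       subtypes = TRUE, scoring = TRUE,
                                       nmf = TRUE, deconv = TRUE,
                                       stats = TRUE),
                            qc_min_features = 200, qc_max_features = 2500,
                            qc_max_mito = 10, norm_scale = 1e4,
                            n_hvg = 2000, n_pcs = 30, knn_k = 15,
                            first_resolution = 0.15,
                            subtype_resolutions = c(0.05, 0.1, 0.15, 0.2, 0.4, 0.6),
                            subsample_fraction = 0.9, n_iterations = 20,
                            delta = 0.05,
                            signatures = system.file("extdata", "signatures.yaml",
                                                     package = "neumod"),
                            target_signature = "neutrophil_markers",
                            nmf_ranks = 2:7, nmf_runs = 30, nmf_hvg = 500,
                            markers_per_type = 50,
                            pseudobulk_noise_cv = 0.1,
                            clinical_n = 500,
                            seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$seed)) stop("`seed` must be set", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Desk-scale example configuration
#'
#' The packaged fixture configuration used by the worked examples: a
#' 12-sample cohort at reduced gene and cell counts so a full pipeline run
#' completes in a few minutes on one core, with the NMF rank grid and
#' consensus runs scaled accordingly.
#'
#' @param seed Global pipeline seed.
#' @return A [pipeline_config()].
#' @export
example_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(n_samples = 12, n_cells_per_sample = 400,
                     n_genes = 1200, seed = seed),
    nmf_ranks = 2:5, nmf_runs = 15, nmf_hvg = 300,
    clinical_n = 400, seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a freshly simulated
#' cohort. Any stage failure halts the run with a diagnostic naming the
#' stage. Reruns with the same config and seed are bit-reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: per-stage status, parameters and
#'   key metrics, plus the stage objects in `$artifacts`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list(seed = seed,
                 version = as.character(utils::packageVersion("neumod")),
                 stages = list())
  art <- list()
  run_stage <- function(name, enabled, params, fun) {
    if (!enabled) {
      report$stages[[name]] <<- list(status = "skipped", params = params,
                                     metrics = list())
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(status = "ok", params = params,
                                   metrics = res$metrics)
    art[[name]] <<- res$artifacts
    invisible(NULL)
  }

  # -- simulate ---------------------------------------------------------
  run_stage("simulate", TRUE, list(seed = stage_seed(seed, "simulate")), function() {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(seed, "simulate")
    sim <- simulate_atlas(sim_cfg)
    list(metrics = list(n_cells = ncol(sim$counts), n_genes = nrow(sim$counts),
                        n_samples = nrow(sim$samples)),
         artifacts = list(sim = sim))
  })
  sim <- art$simulate$sim

  # -- qc ---------------------------------------------------------------
  run_stage("qc", config$stages[["qc"]],
            list(min_features = config$qc_min_features,
                 max_features = config$qc_max_features,
                 max_mito = config$qc_max_mito), function() {
    metrics <- compute_qc(sim$counts)
    keep <- filter_cells(metrics, config$qc_min_features,
                         config$qc_max_features, config$qc_max_mito)
    counts <- sim$counts[, keep, drop = FALSE]
    normalized <- normalize_log(counts, scale = config$norm_scale)
    list(metrics = list(cells_in = length(keep), cells_kept = sum(keep),
                        cells_removed = sum(!keep)),
         artifacts = list(qc = metrics, keep = keep, counts = counts,
                          normalized = normalized))
  })
  normalized <- art$qc$normalized
  cells <- sim$cells[match(colnames(normalized), sim$cells$barcode), ]

  # -- first-pass clustering -------------------------------------------
  run_stage("cluster", config$stages[["cluster"]],
            list(resolution = config$first_resolution, n_hvg = config$n_hvg,
                 n_pcs = config$n_pcs, k = config$knn_k), function() {
    s <- stage_seed(seed, "cluster1")
    hvg <- select_hvg(normalized, n_top = min(config$n_hvg, nrow(normalized)))
    emb <- embed_pca(normalized, genes = hvg, n_pcs = config$n_pcs, seed = s)
    labels <- cluster_cells(emb, resolution = config$first_resolution,
                            seed = s, k = config$knn_k)
    # The target compartment (neutrophils) is identified by a marker
    # signature score: every cluster whose mean score sits in the upper
    # half of the per-cluster score range is part of it. This is robust to
    # the first pass already splitting the compartment into subclusters.
    sigs <- read_signatures(config$signatures)
    sig <- sigs[[config$target_signature]]
    if (is.null(sig)) {
      stop(sprintf("target signature '%s' not found in %s",
                   config$target_signature, config$signatures), call. = FALSE)
    }
    sc <- score_mean(normalized, sig)
    cl_means <- tapply(sc, labels, mean)
    rel <- (cl_means - min(cl_means)) / max(max(cl_means) - min(cl_means), 1e-12)
    target <- as.integer(names(cl_means)[rel > 0.5])
    list(metrics = list(n_clusters = length(unique(labels)),
                        n_target_clusters = length(target),
                        target_cells = sum(labels %in% target)),
         artifacts = list(labels = labels, hvg = as.character(hvg),
                          embedding = emb, target = target))
  })

  target_cells <- character()
  if (!is.null(art$cluster)) {
    target_cells <- names(art$cluster$labels)[art$cluster$labels %in% art$cluster$target]
  }

  # -- subtype clustering (second step) --------------------------------
  run_stage("subtypes", config$stages[["subtypes"]] && length(target_cells) > 0,
            list(resolutions = config$subtype_resolutions,
                 subsample_fraction = config$subsample_fraction,
                 n_iterations = config$n_iterations, delta = config$delta),
            function() {
    s <- stage_seed(seed, "subtypes")
    sub <- subcluster(normalized, target_cells,
                      resolutions = config$subtype_resolutions,
                      n_hvg = config$n_hvg, n_pcs = config$n_pcs,
                      k = config$knn_k,
                      subsample_fraction = config$subsample_fraction,
                      n_iterations = config$n_iterations,
                      delta = config$delta, seed = s)
    markers <- find_markers(normalized[sub$hvg, target_cells], sub$labels)
    list(metrics = list(selected_resolution = sub$resolution,
                        n_subtypes = length(unique(sub$labels)),
                        mean_ari_at_selected = stability_summary(sub$stability) |>
                          dplyr::filter(.data$resolution == sub$resolution) |>
                          dplyr::pull(.data$mean_ari)),
         artifacts = list(sub = sub, markers = markers))
  })

  # -- signature scoring + apoptotic mixture ---------------------------
  run_stage("scoring", config$stages[["scoring"]] && !is.null(art$subtypes),
            list(signatures = config$signatures), function() {
    s <- stage_seed(seed, "scoring")
    sigs <- read_signatures(config$signatures)
    neu_norm <- normalized[, target_cells, drop = FALSE]
    scores <- score_signatures(neu_norm, sigs)
    gmm <- fit_gmm_1d(stats::setNames(scores$apoptosis, scores$barcode),
                      seed = s)
    calls <- classify_apoptotic(gmm)
    list(metrics = list(apoptotic_fraction = attr(calls, "fraction"),
                        gmm_mean_low = gmm$means[1],
                        gmm_mean_high = gmm$means[2]),
         artifacts = list(scores = scores, gmm = gmm, calls = calls))
  })

  # per-sample subtype fractions (used by nmf target choice and stats)
  subtype_frac <- NULL
  if (!is.null(art$subtypes)) {
    lab <- art$subtypes$sub$labels
    subtype_frac <- tibble::tibble(
      barcode = names(lab), subtype = paste0("N", lab),
      sample_id = cells$sample_id[match(names(lab), cells$barcode)]) |>
      dplyr::count(.data$sample_id, .data$subtype) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }

  # -- NMF metagene modules in the severity-associated subtype ---------
  run_stage("nmf", config$stages[["nmf"]] && !is.null(subtype_frac),
            list(ranks = config$nmf_ranks, n_runs = config$nmf_runs,
                 n_hvg = config$nmf_hvg), function() {
    s <- stage_seed(seed, "nmf")
    # target subtype = the one whose fraction tracks severity (Neu1 analogue)
    wide <- tidyr::pivot_wider(subtype_frac[, c("sample_id", "subtype", "fraction")],
                               names_from = "subtype", values_from = "fraction",
                               values_fill = 0) |>
      dplyr::left_join(sim$samples[, c("sample_id", "sofa")], by = "sample_id")
    subs <- setdiff(names(wide), c("sample_id", "sofa"))
    cors <- vapply(subs, function(st) stats::cor(wide[[st]], wide$sofa),
                   numeric(1))
    target_subtype <- subs[which.max(cors)]
    lab <- art$subtypes$sub$labels
    cells_t <- names(lab)[paste0("N", lab) == target_subtype]
    xs <- normalized[, cells_t, drop = FALSE]
    hvg <- select_hvg(xs, n_top = min(config$nmf_hvg, nrow(xs)))
    V <- as.matrix(xs[hvg, , drop = FALSE])
    metrics_tbl <- consensus_metrics(V, config$nmf_ranks,
                                     n_runs = config$nmf_runs, seed = s)
    best <- select_rank(metrics_tbl)
    fit <- nmf_factorize(V, best, seed = s)
    usage <- module_usage(fit)
    per_sample <- aggregate_usage(
      usage, stats::setNames(cells$sample_id[match(cells_t, cells$barcode)],
                             cells_t))
    # letters by descending total usage, mirroring the A..D convention
    totals <- usage |>
      dplyr::group_by(.data$module) |>
      dplyr::summarise(total = sum(.data$usage), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$total))
    letters_map <- stats::setNames(LETTERS[seq_len(nrow(totals))], totals$module)
    usage$module_letter <- unname(letters_map[usage$module])
    per_sample$module_letter <- unname(letters_map[per_sample$module])
    usage_sofa <- per_sample |>
      dplyr::left_join(sim$samples[, c("sample_id", "sofa")], by = "sample_id") |>
      dplyr::group_by(.data$module_letter) |>
      dplyr::summarise(r = stats::cor(.data$usage, .data$sofa), .groups = "drop")
    list(metrics = list(target_subtype = target_subtype,
                        selected_rank = best,
                        cophenetic_at_selected =
                          metrics_tbl$cophenetic[metrics_tbl$rank == best],
                        usage_sofa_r = stats::setNames(as.list(usage_sofa$r),
                                                       usage_sofa$module_letter)),
         artifacts = list(rank_metrics = metrics_tbl, fit = fit,
                          usage = usage, per_sample_usage = per_sample,
                          target_subtype = target_subtype,
                          letters = letters_map))
  })

  # -- pseudobulk deconvolution ----------------------------------------
  run_stage("deconv", config$stages[["deconv"]] && !is.null(subtype_frac),
            list(markers_per_type = config$markers_per_type,
                 noise_cv = config$pseudobulk_noise_cv), function() {
    s <- stage_seed(seed, "deconv")
    lab <- art$subtypes$sub$labels
    deconv_labels <- paste0("C", unclass(art$cluster$labels)[colnames(normalized)])
    names(deconv_labels) <- colnames(normalized)
    deconv_labels[names(lab)] <- paste0("N", lab)
    pb <- simulate_pseudobulk(art$qc$counts, unname(deconv_labels),
                              cells$sample_id,
                              noise_cv = config$pseudobulk_noise_cv, seed = s)
    sigm <- build_signature_matrix(normalized[art$cluster$hvg, , drop = FALSE],
                                   unname(deconv_labels),
                                   markers_per_type = config$markers_per_type)
    est <- deconvolve(pb$bulk, sigm)
    ev <- evaluate_deconv(est, pb$fractions)
    target_subtype <- art$nmf$target_subtype %||% "N0"
    r_target <- ev$pearson_r[ev$type == target_subtype]
    list(metrics = list(
      mean_rmse = unname(attr(ev, "overall")["rmse"]),
      target_subtype_r = if (length(r_target)) r_target else NA_real_),
      artifacts = list(pseudobulk = pb, signature = sigm, est = est,
                       evaluation = ev))
  })

  # -- association statistics ------------------------------------------
  run_stage("stats", config$stages[["stats"]] && !is.null(subtype_frac),
            list(clinical_n = config$clinical_n), function() {
    s <- stage_seed(seed, "stats")
    samp <- sim$samples
    wide <- tidyr::pivot_wider(subtype_frac[, c("sample_id", "subtype", "fraction")],
                               names_from = "subtype", values_from = "fraction",
                               values_fill = 0) |>
      dplyr::left_join(samp, by = "sample_id")
    subs <- grep("^N", names(wide), value = TRUE)
    cor_rows <- dplyr::bind_rows(lapply(subs, function(st) {
      dplyr::mutate(pearson_test(wide[[st]], wide$sofa_circulation),
                    term = st, .before = 1)
    }))
    cor_rows$p_holm <- holm_adjust(cor_rows$p)
    target_subtype <- art$nmf$target_subtype %||%
      cor_rows$term[which.max(cor_rows$estimate)]
    auc_frac <- roc_auc(wide[[target_subtype]], wide$shock)
    auc_modules <- NULL
    if (!is.null(art$nmf)) {
      mu <- tidyr::pivot_wider(
        art$nmf$per_sample_usage[, c("sample_id", "module_letter", "usage")],
        names_from = "module_letter", values_from = "usage") |>
        dplyr::left_join(samp[, c("sample_id", "shock")], by = "sample_id")
      mods <- sort(setdiff(names(mu), c("sample_id", "shock")))
      auc_modules <- stats::setNames(lapply(mods, function(m) {
        a <- roc_auc(mu[[m]], mu$shock)$auc
        max(a, 1 - a) # direction-free discrimination
      }), mods)
    }
    day_test <- NULL
    d1 <- wide[[target_subtype]][wide$day == 1]
    d5 <- wide[[target_subtype]][wide$day == 5]
    if (length(d1) >= 2 && length(d5) >= 2) {
      day_test <- student_test(d1, d5)
    }
    clin <- simulate_clinical_table(config$sim, config$clinical_n, seed = s)
    fit <- logistic_irls(clin)
    inter <- fit$coefficients[fit$coefficients$term == "neutrophil_pct:monocyte_pct", ]
    list(metrics = list(
      target_subtype = target_subtype,
      cor_sofa_circ_r = stats::setNames(as.list(cor_rows$estimate), cor_rows$term),
      auc_shock_target = auc_frac$auc,
      auc_shock_modules = auc_modules,
      day1_vs_day5_p = if (!is.null(day_test)) day_test$p else NA_real_,
      interaction_beta = inter$estimate, interaction_p = inter$p),
      artifacts = list(correlations = cor_rows, auc = auc_frac,
                       clinical = clin, logit = fit))
  })

  report$artifacts <- art
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report_files(report, config)
  report
}

#' Flatten a run report's metrics to a named numeric vector
#'
#' @param report A `run_report`.
#' @return Named numeric vector of every scalar metric, suitable for
#'   reproducibility comparison and JSON export.
#' @export
report_metrics <- function(report) {
  stopifnot(inherits(report, "run_report"))
  out <- c()
  for (st in names(report$stages)) {
    m <- report$stages[[st]]$metrics
    flat <- unlist(m)
    if (length(flat)) {
      num <- suppressWarnings(as.numeric(flat))
      names(num) <- paste(st, names(flat), sep = ".")
      out <- c(out, num[!is.na(num)])
    }
  }
  out
}

fnv_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 268435456
  sprintf("%07x", h)
}

write_report_files <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- report$artifacts
  info <- list(package = "neumod", version = report$version,
               seed = report$seed,
               config_hash = fnv_hash(config[setdiff(names(config), "out_dir")]))
  jsonlite::write_json(info, file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(lapply(report$stages, function(s)
    s[c("status", "params", "metrics")]),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(art$qc)) {
    utils::write.csv(art$qc$qc, file.path(config$out_dir, "qc_metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(art$subtypes)) {
    lab <- art$subtypes$sub$labels
    utils::write.csv(data.frame(barcode = names(lab), cluster = as.integer(lab)),
                     file.path(config$out_dir, "labels.csv"), row.names = FALSE)
    utils::write.csv(tibble::as_tibble(art$subtypes$sub$stability),
                     file.path(config$out_dir, "stability.csv"), row.names = FALSE)
    utils::write.csv(art$subtypes$markers,
                     file.path(config$out_dir, "markers.csv"), row.names = FALSE)
  }
  if (!is.null(art$nmf)) {
    utils::write.csv(art$nmf$rank_metrics,
                     file.path(config$out_dir, "rank_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(art$nmf$usage, file.path(config$out_dir, "usage.csv"),
                     row.names = FALSE)
  }
  if (!is.null(art$deconv)) {
    utils::write.csv(art$deconv$est$fractions,
                     file.path(config$out_dir, "fractions.csv"),
                     row.names = FALSE)
  }
  invisible(config$out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("neumod pipeline run (seed %d, version %s)\n", x$seed, x$version))
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    m <- report_metrics(structure(list(stages = x$stages[st]),
                                  class = "run_report"))
    cat(sprintf("  %-9s %-8s %s\n", st, s$status,
                paste(sprintf("%s=%.4g", sub("^[^.]+\\.", "", names(m)), m),
                      collapse = " ")))
  }
  invisible(x)
}
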