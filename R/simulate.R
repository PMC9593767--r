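# Synthetic cohort generator. Emulates the structure of a sepsis
# peripheral-blood single-cell atlas: ~9 major cell types dominated by
# neutrophils, four planted neutrophil subtypes with marker programs, a
# severity score per sample coupled to the immature-subtype fraction, and a
# shock outcome driven by a monocyte x neutrophil interaction. Every planted
# quantity is returned as ground truth so downstream stages can be tested
# for parameter recovery.

MAJOR_TYPES <- c(
  "Neutrophil", "Monocyte", "CD4_T", "CD8_T", "NK",
  "B", "Megakaryocyte", "DC", "Erythrocyte"
)

DEFAULT_MAJOR_PROPS <- c(
  Neutrophil = 0.55, Monocyte = 0.12, CD4_T = 0.10, CD8_T = 0.07,
  NK = 0.05, B = 0.05, Megakaryocyte = 0.03, DC = 0.02, Erythrocyte = 0.01
)

# Seed marker symbols per major type; remaining marker slots are filled with
# synthetic ids like "NEUTROPHIL.M07".
TYPE_MARKER_SEEDS <- list(
  Neutrophil = c("FCGR3B", "CXCR2", "IL1R2", "CD177", "S100A9", "CSF3R"),
  Monocyte = c("LYZ", "MS4A7", "CSF1R", "VCAN"),
  CD4_T = c("CD4", "IL7R", "CCR7"),
  CD8_T = c("CD8A", "CD8B", "GZMK"),
  NK = c("NKG7", "GNLY", "KLRD1"),
  B = c("MS4A1", "CD79A", "CD79B"),
  Megakaryocyte = c("PF4", "PPBP", "ITGA2B"),
  DC = c("FCER1A", "CLEC10A", "CD1C"),
  Erythrocyte = c("HBB", "HBA1", "ALAS2")
)

SUBTYPE_MARKER_SEEDS <- list(
  Neu1 = c("MMP9", "HP", "RGL4", "FCN1", "OLFM4", "PADI4"),
  Neu2 = c("FTH1", "TNFAIP3", "SIGLEC10", "CD14"),
  Neu3 = c("IFIT1", "ISG15", "RSAD2"),
  Neu4 = c("S100A4", "TXNIP", "NEAT1", "ZFP36")
)

# Functional programs planted inside neutrophils. `lfc` gives the log2
# multiplier applied per neutrophil subtype (Neu1 is the immature subtype:
# low maturation/aging/azurophil/interferon response).
PROGRAM_GENES <- list(
  apoptosis = c("CASP3", "CASP8", "BAX", "BAK1", "TP53", "FAS", "TNFRSF1A",
                "APAF1", "CYCS", "DIABLO", "BID", "PMAIP1"),
  maturation = c("MMP8", "CEACAM8", "LTF", "CAMP", "LCN2", "ARG1", "ORM1"),
  aging_pos = c("CXCR4", "ICAM1", "ITGAX"),
  aging_neg = c("SELL", "LRRN3", "PTGER2"),
  azurophil = c("MPO", "ELANE", "PRTN3", "CTSG", "DEFA3", "DEFA4", "AZU1"),
  ifn_response = c("IFI6", "MX1", "OAS1", "IFIT3", "IRF7", "SIGLEC1")
)

PROGRAM_LFC <- rbind(
  maturation   = c(Neu1 = -1.0, Neu2 = 0.5, Neu3 = 0.5, Neu4 = 0.5),
  aging_pos    = c(Neu1 = -0.7, Neu2 = 0.3, Neu3 = 0.3, Neu4 = 0.3),
  aging_neg    = c(Neu1 = 0.7, Neu2 = -0.3, Neu3 = -0.3, Neu4 = -0.3),
  azurophil    = c(Neu1 = -1.0, Neu2 = 0.3, Neu3 = 0.3, Neu4 = 0.3),
  ifn_response = c(Neu1 = -0.7, Neu2 = 0.0, Neu3 = 1.5, Neu4 = 0.0)
)

MITO_SYMBOLS <- c(
  "MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6", "MT-CO3",
  "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB"
)

#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_atlas()]. Defaults
#' emulate a sepsis peripheral-blood cohort: 32 samples from 12 patients on
#' days 1/3/5, a cell population dominated (>50%) by neutrophils split into
#' four subtypes, negative-binomial counts with lognormal library sizes, a
#' per-sample SOFA-like severity score coupled to the immature (Neu1-like)
#' subtype fraction, and a septic-shock label tied to the cardiovascular
#' SOFA component.
#'
#' @param n_samples Number of samples (one per patient-day).
#' @param n_cells_per_sample Cells drawn per sample.
#' @param n_genes Total genes, including mitochondrial genes.
#' @param n_mito_genes Number of "MT-"-prefixed mitochondrial genes.
#' @param major_type_proportions Named probability vector over major cell
#'   types; must sum to 1.
#' @param n_neutrophil_subtypes Number of planted neutrophil subtypes.
#' @param markers_per_type Marker genes planted per type and per subtype.
#' @param marker_log2fc Log2 fold change planted for marker genes in their
#'   assigned type.
#' @param nb_dispersion Shared negative-binomial dispersion (1/size).
#' @param libsize_log_mean,libsize_log_sd Log-scale mean and sd of the
#'   per-cell expected total UMI count.
#' @param severity_coupling Logit-scale slope linking standardized sample
#'   severity to the odds that a neutrophil belongs to the Neu1-like subtype.
#' @param shock_model Named list of logistic coefficients (intercept,
#'   neutrophil, monocyte, interaction, age, sex) used by
#'   [simulate_clinical_table()] on standardized covariates.
#' @param damaged_fraction Fraction of cells simulated as damaged (elevated
#'   mitochondrial share), the true positives for the mito QC filter.
#' @param damaged_mito_share Expected mitochondrial UMI share of damaged cells.
#' @param debris_fraction Fraction of cells with ~5% of the normal library
#'   size, the true positives for the low-feature QC filter.
#' @param apoptotic_fraction Fraction of non-Neu1 neutrophils carrying the
#'   planted apoptosis program (Neu1 cells get 40% of this rate).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 32,
                       n_cells_per_sample = 4000,
                       n_genes = 2000,
                       n_mito_genes = 13,
                       major_type_proportions = DEFAULT_MAJOR_PROPS,
                       n_neutrophil_subtypes = 4,
                       markers_per_type = 20,
                       marker_log2fc = 2,
                       nb_dispersion = 0.5,
                       libsize_log_mean = log(2000),
                       libsize_log_sd = 0.3,
                       severity_coupling = 1,
                       shock_model = list(intercept = -0.5, neutrophil = 0.8,
                                          monocyte = -0.5, interaction = -0.6,
                                          age = 0.3, sex = 0.1),
                       damaged_fraction = 0.05,
                       damaged_mito_share = 0.3,
                       debris_fraction = 0.02,
                       apoptotic_fraction = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_cells_per_sample = n_cells_per_sample,
    n_genes = n_genes, n_mito_genes = n_mito_genes,
    major_type_proportions = major_type_proportions,
    n_neutrophil_subtypes = n_neutrophil_subtypes,
    markers_per_type = markers_per_type, marker_log2fc = marker_log2fc,
    nb_dispersion = nb_dispersion, libsize_log_mean = libsize_log_mean,
    libsize_log_sd = libsize_log_sd, severity_coupling = severity_coupling,
    shock_model = shock_model, damaged_fraction = damaged_fraction,
    damaged_mito_share = damaged_mito_share,
    debris_fraction = debris_fraction,
    apoptotic_fraction = apoptotic_fraction, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_samples", "n_cells_per_sample", "n_genes", "n_mito_genes",
              "n_neutrophil_subtypes", "markers_per_type")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v != round(v)) {
      abort_cfg(f, "must be a positive integer count")
    }
  }
  p <- cfg$major_type_proportions
  if (is.null(names(p)) || any(!names(p) %in% MAJOR_TYPES)) {
    abort_cfg("major_type_proportions",
              paste("must be named with types among:",
                    paste(MAJOR_TYPES, collapse = ", ")))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    abort_cfg("major_type_proportions", "must be non-negative and sum to 1")
  }
  if (cfg$n_mito_genes >= cfg$n_genes) {
    abort_cfg("n_mito_genes", "must be smaller than n_genes")
  }
  for (f in c("nb_dispersion", "marker_log2fc")) {
    if (cfg[[f]] <= 0) abort_cfg(f, "must be positive")
  }
  for (f in c("damaged_fraction", "debris_fraction", "apoptotic_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort_cfg(f, "must be in [0, 1]")
  }
  needed <- c("intercept", "neutrophil", "monocyte", "interaction", "age", "sex")
  if (!all(needed %in% names(cfg$shock_model))) {
    abort_cfg("shock_model",
              paste("must contain coefficients:", paste(needed, collapse = ", ")))
  }
  min_genes <- cfg$n_mito_genes +
    cfg$markers_per_type * (length(p) + cfg$n_neutrophil_subtypes) +
    length(unlist(PROGRAM_GENES))
  if (cfg$n_genes < min_genes) {
    abort_cfg("n_genes", sprintf(
      "must be at least %d to hold mito, marker and program genes", min_genes))
  }
  invisible(cfg)
}

subtype_names <- function(n) paste0("Neu", seq_len(n))

fill_markers <- function(seeds, prefix, n) {
  out <- seeds[seq_len(min(length(seeds), n))]
  if (length(out) < n) {
    out <- c(out, sprintf("%s.M%02d", toupper(prefix), seq.int(length(out) + 1, n)))
  }
  out
}

# Gene universe: mito block, per-type markers, per-subtype markers, program
# genes, lognormal filler. Deterministic given the config sizes.
build_gene_table <- function(cfg) {
  subs <- subtype_names(cfg$n_neutrophil_subtypes)
  mito <- if (cfg$n_mito_genes <= length(MITO_SYMBOLS)) {
    MITO_SYMBOLS[seq_len(cfg$n_mito_genes)]
  } else {
    c(MITO_SYMBOLS, sprintf("MT-G%02d", seq_len(cfg$n_mito_genes - length(MITO_SYMBOLS))))
  }
  rows <- list(tibble::tibble(gene = mito, role = "mito", target = NA_character_,
                              log2fc = 0))
  for (tp in names(cfg$major_type_proportions)) {
    g <- fill_markers(TYPE_MARKER_SEEDS[[tp]] %||% character(), tp,
                      cfg$markers_per_type)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = g, role = "type_marker", target = tp, log2fc = cfg$marker_log2fc)
  }
  for (st in subs) {
    g <- fill_markers(SUBTYPE_MARKER_SEEDS[[st]] %||% character(), st,
                      cfg$markers_per_type)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = g, role = "subtype_marker", target = st, log2fc = cfg$marker_log2fc)
  }
  for (pg in names(PROGRAM_GENES)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = PROGRAM_GENES[[pg]], role = "program", target = pg, log2fc = NA_real_)
  }
  tab <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(tab$gene))
  n_fill <- cfg$n_genes - nrow(tab)
  if (n_fill > 0) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      gene = sprintf("G%05d", seq_len(n_fill)), role = "background",
      target = NA_character_, log2fc = 0))
  }
  tab
}

# Per-sample clinical layer. Severity (SOFA-like) is generated first, then
# subtype mixing follows, matching the direction of association without
# circularity. Shock is defined from the cardiovascular component
# (sofa_circulation >= 2).
draw_samples <- function(cfg) {
  n <- cfg$n_samples
  patient <- sprintf("P%02d", ((seq_len(n) - 1) %/% 3) + 1)
  day <- c(1, 3, 5)[((seq_len(n) - 1) %% 3) + 1]
  n_pat <- length(unique(patient))
  age_pat <- round(stats::runif(n_pat, 52, 90))
  sex_pat <- stats::rbinom(n_pat, 1, 0.75) # cohort is male-dominated
  # The cardiovascular component scales with overall severity (SOFA sums
  # its organ components), so severity, sofa_circulation and shock are
  # mutually consistent: shock is defined as sofa_circulation >= 2 and
  # feeds back a +2 severity bonus.
  sev_base <- sample(2:20, n, replace = TRUE)
  sofa_circ <- pmin(4, pmax(0, round(sev_base / 5 + stats::rnorm(n, 0, 0.8))))
  shock <- sofa_circ >= 2
  severity <- pmin(24L, sev_base + 2L * shock)
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)), patient = patient, day = day,
    age = age_pat[match(patient, unique(patient))],
    sex = sex_pat[match(patient, unique(patient))],
    sofa = as.integer(severity), sofa_circulation = as.integer(sofa_circ),
    shock = shock
  )
}

#' Simulate a single-cell sepsis atlas with ground truth
#'
#' Draws UMI counts as negative binomial (shared dispersion, lognormal
#' per-cell library size) over a gene universe with planted type markers,
#' neutrophil-subtype markers, and functional programs. The Neu1-like
#' subtype proportion increases with sample severity through a logit link
#' with slope `severity_coupling`. Damaged (high-mito) and debris
#' (low-library) cells are planted as QC-filter true positives.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sc_sim` with elements `counts` (dgCMatrix,
#'   genes x cells), `cells` (tibble of per-cell truth and metadata),
#'   `samples` (per-sample clinical tibble), and `truth` (list with
#'   `fractions`, `markers` and the echoed `config`).
#' @export
simulate_atlas <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  genes <- build_gene_table(cfg)
  subs <- subtype_names(cfg$n_neutrophil_subtypes)
  samples <- draw_samples(cfg)

  # Baseline relative expression: mito genes get a fixed 3% share,
  # everything else lognormal.
  base <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  is_mito <- genes$role == "mito"
  base[is_mito] <- mean(base[!is_mito]) # flat mito block before scaling
  base[is_mito] <- base[is_mito] / sum(base[is_mito]) * 0.03
  base[!is_mito] <- base[!is_mito] / sum(base[!is_mito]) * 0.97

  # Per-cell metadata.
  z_sev <- as.numeric(scale(samples$sofa))
  if (any(!is.finite(z_sev))) z_sev <- rep(0, nrow(samples))
  p_neu1 <- stats::plogis(stats::qlogis(0.25) + cfg$severity_coupling * z_sev)
  other_share <- c(0.4, 0.35, 0.25)

  cells_list <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    nc <- cfg$n_cells_per_sample
    alpha <- cfg$major_type_proportions * 200 # mild per-sample composition noise
    w <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    props <- w / sum(w)
    type <- sample(names(cfg$major_type_proportions), nc, replace = TRUE, prob = props)
    subtype <- rep(NA_character_, nc)
    is_neu <- type == "Neutrophil"
    if (any(is_neu)) {
      p1 <- p_neu1[s]
      rest <- other_share[seq_len(max(cfg$n_neutrophil_subtypes - 1, 0))]
      rest <- if (length(rest)) rest / sum(rest) * (1 - p1) else numeric()
      subtype[is_neu] <- sample(subs, sum(is_neu), replace = TRUE,
                                prob = c(p1, rest)[seq_along(subs)])
    }
    apop_p <- ifelse(subtype == "Neu1", 0.4 * cfg$apoptotic_fraction,
                     cfg$apoptotic_fraction)
    apoptotic <- is_neu & stats::runif(nc) < ifelse(is.na(apop_p), 0, apop_p)
    damaged <- stats::runif(nc) < cfg$damaged_fraction
    debris <- stats::runif(nc) < cfg$debris_fraction
    cells_list[[s]] <- tibble::tibble(
      barcode = sprintf("%s_C%05d", samples$sample_id[s], seq_len(nc)),
      sample_id = samples$sample_id[s], cell_type = type, subtype = subtype,
      apoptotic = apoptotic, damaged = damaged, debris = debris
    )
  }
  cells <- dplyr::bind_rows(cells_list)
  n_cells <- nrow(cells)

  # Expected total UMIs per cell (debris cells at 5% of normal).
  log_total <- stats::rnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd)
  total <- exp(log_total) * ifelse(cells$debris, 0.05, 1)

  # Gene-proportion vector per expression group. Group = refined type x
  # apoptotic x damaged; all cells in a group share the same proportions.
  refined <- ifelse(is.na(cells$subtype), cells$cell_type, cells$subtype)
  grp_key <- paste(refined, cells$apoptotic, cells$damaged, sep = "|")
  counts <- make_group_counts(cfg, genes, base, refined, grp_key,
                              cells$barcode, total)

  fractions <- cells |>
    dplyr::mutate(type = refined) |>
    dplyr::count(.data$sample_id, .data$type) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "type", "fraction")

  structure(list(
    counts = counts, cells = cells, samples = samples,
    truth = list(fractions = fractions,
                 markers = genes[genes$role %in% c("type_marker", "subtype_marker"), ],
                 config = cfg)
  ), class = "sc_sim")
}

# Build the sparse count matrix group by group (cells in a group share a
# mean vector up to their library size), chunked to bound dense memory.
make_group_counts <- function(cfg, genes, base, refined, grp_key, barcodes, total) {
  subs <- subtype_names(cfg$n_neutrophil_subtypes)
  size <- 1 / cfg$nb_dispersion
  n_genes <- cfg$n_genes
  group_prop <- function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    rtype <- parts[1]; apop <- parts[2] == "TRUE"; dam <- parts[3] == "TRUE"
    lfc <- numeric(n_genes)
    major <- if (rtype %in% subs) "Neutrophil" else rtype
    hit <- genes$role == "type_marker" & genes$target == major
    lfc[hit] <- cfg$marker_log2fc
    if (rtype %in% subs) {
      hit <- genes$role == "subtype_marker" & genes$target == rtype
      lfc[hit] <- cfg$marker_log2fc
      for (pg in rownames(PROGRAM_LFC)) {
        idx <- genes$role == "program" & genes$target == pg
        lfc[idx] <- lfc[idx] + PROGRAM_LFC[pg, rtype]
      }
      if (apop) {
        idx <- genes$role == "program" & genes$target == "apoptosis"
        lfc[idx] <- lfc[idx] + 1.5
      }
    }
    p <- base * 2^lfc
    if (dam) {
      mito <- genes$role == "mito"
      share <- sum(p[mito]) / sum(p)
      boost <- cfg$damaged_mito_share / (1 - cfg$damaged_mito_share) *
        (1 - share) / share
      p[mito] <- p[mito] * boost
    }
    p / sum(p)
  }

  keys <- unique(grp_key)
  blocks <- vector("list", 0)
  order_idx <- integer(0)
  for (key in keys) {
    idx <- which(grp_key == key)
    p <- group_prop(key)
    for (start in seq(1, length(idx), by = 2000)) {
      ii <- idx[start:min(start + 1999, length(idx))]
      mu <- outer(p, total[ii])
      m <- matrix(stats::rnbinom(length(mu), size = size, mu = mu),
                  nrow = n_genes)
      blocks[[length(blocks) + 1]] <- as_dgc(Matrix::Matrix(m, sparse = TRUE))
      order_idx <- c(order_idx, ii)
    }
  }
  counts <- do.call(cbind, blocks)
  counts <- counts[, order(order_idx), drop = FALSE]
  dimnames(counts) <- list(genes$gene, barcodes)
  counts
}

#' Aggregate single cells into noisy pseudobulk mixtures
#'
#' Each bulk column is the sum of counts of the cells of one sample,
#' optionally perturbed entrywise by multiplicative lognormal noise with the
#' given coefficient of variation. True fractions are the per-sample
#' cell-count proportions of `cell_labels`.
#'
#' @param counts Gene x cell count matrix.
#' @param cell_labels Character vector of per-cell type labels.
#' @param sample_ids Character vector of per-cell sample ids.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = exact column sums).
#' @param seed Optional seed for the noise draw.
#' @return List with `bulk` (genes x samples dense matrix) and `fractions`
#'   (tibble sample_id, type, fraction).
#' @export
simulate_pseudobulk <- function(counts, cell_labels, sample_ids,
                                noise_cv = 0, seed = NULL) {
  stopifnot_counts(counts)
  if (length(cell_labels) != ncol(counts) || length(sample_ids) != ncol(counts)) {
    stop("`cell_labels` and `sample_ids` must have one entry per cell", call. = FALSE)
  }
  if (anyNA(cell_labels)) stop("`cell_labels` must cover all cells", call. = FALSE)
  if (anyNA(sample_ids)) stop("unknown (missing) sample id", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be non-negative", call. = FALSE)
  samples <- sort(unique(sample_ids))
  ind <- Matrix::sparseMatrix(
    i = seq_along(sample_ids), j = match(sample_ids, samples), x = 1,
    dims = c(length(sample_ids), length(samples))
  )
  bulk <- as.matrix(counts %*% ind)
  dimnames(bulk) <- list(rownames(counts), samples)
  if (noise_cv > 0) {
    with_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- matrix(stats::rlnorm(length(bulk), -sdlog^2 / 2, sdlog),
                      nrow = nrow(bulk))
      bulk <- bulk * noise
    })
  }
  fractions <- tibble::tibble(sample_id = sample_ids, type = cell_labels) |>
    dplyr::count(.data$sample_id, .data$type) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "type", "fraction")
  list(bulk = bulk, fractions = fractions)
}

#' Simulate a clinical differential-count table with a planted shock model
#'
#' Cell-count percentages are drawn from a Dirichlet model (so the reported
#' fractions sum to at most 100%), and shock is drawn Bernoulli with a logit
#' given by `shock_model` applied to standardized covariates, including the
#' neutrophil x monocyte product term.
#'
#' @param config A [sim_config()] (its `shock_model` is used).
#' @param n_patients Number of patients (>= 50).
#' @param seed Integer seed.
#' @return Tibble with patient_id, neutrophil_pct, monocyte_pct, band_pct,
#'   age, sex, sofa_circulation, shock.
#' @export
simulate_clinical_table <- function(config, n_patients, seed = config$seed) {
  validate_sim_config(config)
  if (n_patients < 50) {
    stop("`n_patients` must be at least 50", call. = FALSE)
  }
  set.seed(seed)
  alpha <- c(neutrophil = 55, lymphocyte = 25, monocyte = 7, band = 4,
             eosinophil = 2, other = 7) * 2
  w <- matrix(stats::rgamma(n_patients * length(alpha),
                            shape = rep(alpha, each = n_patients), rate = 1),
              nrow = n_patients)
  pct <- w / rowSums(w) * 100
  colnames(pct) <- names(alpha)
  age <- round(stats::runif(n_patients, 52, 90))
  sex <- stats::rbinom(n_patients, 1, 0.5)
  zn <- as.numeric(scale(pct[, "neutrophil"]))
  zm <- as.numeric(scale(pct[, "monocyte"]))
  za <- as.numeric(scale(age))
  b <- config$shock_model
  eta <- b$intercept + b$neutrophil * zn + b$monocyte * zm +
    b$interaction * zn * zm + b$age * za + b$sex * sex
  shock <- stats::runif(n_patients) < stats::plogis(eta)
  sofa_circ <- ifelse(shock, sample(2:4, n_patients, replace = TRUE),
                      sample(0:1, n_patients, replace = TRUE))
  tibble::tibble(
    patient_id = sprintf("E%05d", seq_len(n_patients)),
    neutrophil_pct = pct[, "neutrophil"], monocyte_pct = pct[, "monocyte"],
    band_pct = pct[, "band"], age = age, sex = sex,
    sofa_circulation = as.integer(sofa_circ), shock = shock
  )
}

MODULE_GENE_SEEDS <- list(
  c("MMP9", "HP", "RGL4", "PADI4"),
  c("S100A12", "S100A8", "IL1R2", "CLEC4D"),
  c("NFKBIA", "CXCL8", "G0S2", "FTH1"),
  c("IFIT1", "ISG15", "MX1", "RSAD2")
)

#' Simulate a non-negative matrix with planted metagene modules
#'
#' Builds `V = W H` from block-structured non-negative factors plus
#' multiplicative gamma noise, with each cell dominated by one module
#' (Dirichlet usage concentrated on it). Adjacent modules share part of
#' their gene program (`overlap` > 0 adds a weaker ring-structured loading
#' of each gene block on the next module), which mirrors real
#' transcriptional programs and makes under-factorized consensus solutions
#' unstable. Optionally couples the probability of being dominated by
#' `coupled_module` to a per-sample severity score so usage-severity
#' associations can be tested against truth.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes loading on each module block.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param background Loading level of off-module genes.
#' @param overlap Relative strength of each gene block's secondary loading
#'   on the adjacent module (0 = fully disjoint modules).
#' @param alpha_own,alpha_other Dirichlet concentrations of a cell's usage
#'   on its dominant vs the remaining modules.
#' @param sample_ids Optional per-cell sample ids (required for coupling).
#' @param severity Optional per-sample named severity vector.
#' @param coupled_module Index of the severity-coupled module.
#' @param coupling Logit-scale slope of the coupling (0 = none).
#' @param seed Integer seed.
#' @return List with `V`, `W_true`, `usage_true`, `dominant`, and the inputs.
#' @export
simulate_module_matrix <- function(n_genes = 500, n_cells = 2000,
                                   n_modules = 4, genes_per_module = 60,
                                   noise_cv = 0.35, background = 0.03,
                                   overlap = 0.5, alpha_own = 4,
                                   alpha_other = 0.6,
                                   sample_ids = NULL, severity = NULL,
                                   coupled_module = 1, coupling = 0,
                                   seed = 1L) {
  stopifnot(n_modules * genes_per_module <= n_genes)
  set.seed(seed)
  gene_names <- sprintf("MG%04d", seq_len(n_genes))
  for (m in seq_len(min(n_modules, length(MODULE_GENE_SEEDS)))) {
    seeds <- MODULE_GENE_SEEDS[[m]]
    gene_names[(m - 1) * genes_per_module + seq_along(seeds)] <- seeds
  }
  W <- matrix(stats::runif(n_genes * n_modules, 0, background),
              n_genes, n_modules,
              dimnames = list(gene_names, paste0("M", seq_len(n_modules))))
  for (m in seq_len(n_modules)) {
    idx <- (m - 1) * genes_per_module + seq_len(genes_per_module)
    W[idx, m] <- stats::runif(genes_per_module, 0.6, 1.2)
    if (overlap > 0 && n_modules > 1) {
      nxt <- (m %% n_modules) + 1
      W[idx, nxt] <- W[idx, nxt] +
        overlap * stats::runif(genes_per_module, 0.3, 0.6)
    }
  }
  z_sev <- rep(0, n_cells)
  if (!is.null(sample_ids) && !is.null(severity)) {
    sv <- severity[sample_ids]
    z_sev <- as.numeric(scale(sv))
  }
  p_dom <- stats::plogis(stats::qlogis(1 / n_modules) + coupling * z_sev)
  dominant <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    pr <- rep((1 - p_dom[i]) / (n_modules - 1), n_modules)
    pr[coupled_module] <- p_dom[i]
    dominant[i] <- sample.int(n_modules, 1, prob = pr)
  }
  alpha <- matrix(alpha_other, n_cells, n_modules)
  alpha[cbind(seq_len(n_cells), dominant)] <- alpha_own
  g <- matrix(stats::rgamma(n_cells * n_modules, shape = as.vector(alpha), rate = 1),
              n_cells, n_modules)
  usage <- g / rowSums(g)
  activity <- stats::rlnorm(n_cells, 0, 0.2) * 10
  H <- t(usage * activity)
  V <- W %*% H
  if (noise_cv > 0) {
    shape <- 1 / noise_cv^2
    V <- V * matrix(stats::rgamma(length(V), shape = shape, rate = shape),
                    nrow = n_genes)
  }
  colnames(V) <- sprintf("MC%05d", seq_len(n_cells))
  list(V = V, W_true = W, usage_true = usage, dominant = dominant,
       sample_ids = sample_ids, severity = severity, seed = seed)
}

#' @export
print.sc_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic single-cell atlas: %d genes x %d cells, %d samples\n",
    nrow(x$counts), ncol(x$counts), nrow(x$samples)))
  tp <- table(x$cells$cell_type)
  cat("Cell types:", paste(sprintf("%s=%d", names(tp), tp), collapse = ", "), "\n")
  invisible(x)
}
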