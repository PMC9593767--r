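# neumod

Neutrophils dominate the nucleated cells of peripheral blood, and in
sepsis their composition shifts: an immature neutrophil subtype expands
with disease severity and predicts septic shock. `neumod` packages the
computational workflow for studying that heterogeneity from single-cell
RNA-seq, end to end and fully testable without patient data:

- **QC and preprocessing** — per-cell feature/UMI/mitochondrial metrics,
  the 200–2500 feature and 10% mito filters, log normalization,
  highly-variable-gene selection.
- **Stability-guided two-step clustering** — Leiden community detection on
  a kNN graph of the PCA embedding, with the clustering resolution chosen
  by a subsampled adjusted-Rand-index (ARI) scan: 90% of cells are redrawn
  20 times, each subsample is reclustered, and the working resolution is
  the highest one before the mean ARI vs the full-data reference starts to
  decline. The procedure is run once over all cells and a second time
  inside the neutrophil compartment to resolve subtypes.
- **Signature scoring and apoptotic calling** — mean-expression functional
  scores, ±1-weighted z-score scores, and a two-component Gaussian mixture
  (EM) on the apoptosis score; the higher-mean component defines apoptotic
  cells by maximum posterior.
- **Consensus NMF metagene modules** — multiplicative-update factorization
  of the immature subtype's expression, rank selected from consensus
  statistics (cophenetic coefficient, RSS, dispersion, silhouette) over 30
  runs, per-cell/per-sample module usage.
- **Bulk deconvolution** — marker-based signature matrix from labeled
  single cells and non-negative least squares estimation of cell-type
  fractions in bulk transcriptomes (`f ≥ 0`, renormalized to sum 1), with
  exact recovery on noiseless mixtures.
- **Association statistics** — Pearson/Welch/Student tests, Bonferroni-Holm
  correction, Mann-Whitney AUC, and an IRLS logistic model of shock with a
  neutrophil × monocyte interaction plus age/sex adjustment.
- **Synthetic cohort generator** — negative-binomial counts over nine major
  cell types with four planted neutrophil subtypes, planted marker and
  program genes, severity-coupled subtype mixing, QC-artifact cells,
  pseudobulk mixtures and a clinical table with a planted shock model —
  every downstream stage is verifiable against ground truth.

Results come back as tibbles, fitted objects have `tidy()`/`glance()`
methods, and each result type has an `autoplot()`/`plot_*()` visualization.

## Worked example

```r
library(neumod)

report <- run_pipeline(example_config(seed = 2))
print(report)
```

```
neumod pipeline run (seed 2, version 0.1.0)
  simulate  ok       n_cells=4800 n_genes=1200 n_samples=12
  qc        ok       cells_in=4800 cells_kept=4454 cells_removed=346
  cluster   ok       n_clusters=5 n_target_clusters=4 target_cells=2403
  subtypes  ok       selected_resolution=0.6 n_subtypes=4 mean_ari_at_selected=0.9987
  scoring   ok       apoptotic_fraction=0.1398 gmm_mean_low=0.8152 gmm_mean_high=1.599
  nmf       ok       selected_rank=2 cophenetic_at_selected=0.4413 usage_sofa_r.A=0.01217 ...
  deconv    ok       mean_rmse=0.02845 target_subtype_r=0.9672
  stats     ok       cor_sofa_circ_r.N0=-0.7179 cor_sofa_circ_r.N1=0.8255 ...
            auc_shock_target=1 day1_vs_day5_p=0.3734
            interaction_beta=-0.4797 interaction_p=0.001117
```

Reading the report: QC removed the planted damaged/debris cells
(`cells_removed`); the first pass found 5 clusters of which 4 carry the
neutrophil marker signature (the planted subtype structure already splits
the compartment); the stability scan kept the highest stable resolution
and resolved `n_subtypes=4` subtypes (mean subsampled ARI ≈ 1). One
subtype's per-sample fraction tracks the cardiovascular severity component
(`cor_sofa_circ_r.N1 = 0.83`) and discriminates shock perfectly at this
small sample count (`auc_shock_target=1` over 12 samples); deconvolution
of noisy pseudobulk recovers that subtype's fraction across samples at
r ≈ 0.97; and the interaction logistic model on a simulated 400-patient
clinical table estimates the planted neutrophil × monocyte coefficient
(−0.6) as −0.48, within its standard error at that n. The consensus NMF
metrics are low at this fixture scale because the atlas generator plants
no metagene structure *within* a subtype — the rank-selection machinery
is exercised against `simulate_module_matrix()`, which does.

Per-object workflows (`compute_qc()`, `stability_scan()`,
`fit_gmm_1d()`, `consensus_metrics()`, `deconvolve()`,
`logistic_irls()`, ...) are documented in the help pages and the methods
vignette (`vignettes/neumod-methods.Rmd`). A thin CLI wrapping the same
functions is installed at `exec/neumod` with subcommands
`simulate | qc | cluster | score | nmf | deconv | stats | run-all`.

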