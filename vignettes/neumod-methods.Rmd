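---
title: "Methods: stability-guided neutrophil subtyping, metagene modules, and severity association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-guided neutrophil subtyping, metagene modules, and severity association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neumod` implements an end-to-end analysis of neutrophil heterogeneity in
sepsis peripheral blood: quality control of gene-by-cell UMI counts,
two-step graph clustering with a subsampling-based stability criterion for
choosing the clustering resolution, functional signature scoring with a
mixture-model apoptotic classifier, consensus non-negative matrix
factorization (NMF) of the immature-subtype transcriptome, signature-based
deconvolution of bulk transcriptomes, and the statistical layer that links
subtype fractions and module usages to severity scores and septic shock.
This vignette documents the models, the defaults, and the design decisions
behind each stage, and states what the synthetic cohort generator does and
does not emulate.

## The synthetic cohort generator

All tests and worked examples run on synthetic data with complete ground
truth; no patient data are used or downloadable by the package.

The generator (`simulate_atlas()`) draws UMI counts
$x_{gc} \sim \mathrm{NB}(\mu_{gc}, \theta)$ with a single shared dispersion
$\theta^{-1}$ (`nb_dispersion`, default 0.5) and
$\mu_{gc} = T_c \, p_{g,t(c)}$, where $T_c$ is a lognormal per-cell
expected library size (log-mean `log(2000)`, log-sd 0.3) and $p_{\cdot,t}$
is the gene-proportion vector of the cell's (sub)type. The proportion
vectors start from a lognormal baseline shared by all types; marker genes
are up-shifted by $2^{\mathrm{marker\_log2fc}}$ in their assigned type, and
functional program genes (maturation, aging, azurophil granule, interferon
response, apoptosis) carry fixed per-subtype log2 shifts that reproduce the
qualitative biology of an immature, severity-associated subtype: the
Neu1-like subtype is low in maturation, aging, azurophil and interferon
programs, while a per-cell apoptosis flag (rarer in Neu1) up-shifts the
apoptosis program.

The cohort structure mirrors a 12-patient, day-1/3/5 design dominated by
neutrophils (>50% of cells; nine major types in total). Severity is
generated *first*: each sample gets a SOFA-like integer (uniform 2-20 plus
a +2 shock bonus, capped at 24), a cardiovascular component
`sofa_circulation` in 0-4, and `shock := sofa_circulation >= 2`. The
probability that a neutrophil belongs to the Neu1-like subtype then follows
a logit model in standardized severity with slope `severity_coupling`
(default 1). Generating severity before composition keeps the direction of
the severity-subtype association free of circularity. Ages are uniform on
52-90 and sex is male-biased, matching the emulated cohort's demography.

QC filters get true positives from two planted artifact populations:
"damaged" cells whose mitochondrial proportion is rescaled to 30% of UMIs,
and "debris" cells at 5% of the normal library size.

What the generator does **not** emulate: batch effects and sample
integration, doublets, read-level noise, within-patient longitudinal
correlation beyond the per-sample severity draw, and realistic gene-gene
correlation beyond the planted block programs. Tests passing on this
generator therefore demonstrate correctness of the algorithms under the
generative model, not robustness to those real-data complications.

`simulate_module_matrix()` plants metagene structure directly:
$V = WH \cdot \varepsilon$ with block-structured non-negative loadings and
per-cell Dirichlet usages concentrated on one dominant module
($\alpha = 4$ vs $0.6$), multiplied by gamma noise (CV 0.35). Adjacent
modules share part of their gene program (each gene block also loads at
about half strength on the next module, cyclically). This overlap matters:
with fully disjoint modules every under-factorization merges the same
blocks in every run, so consensus metrics are as stable at rank 2 as at
the true rank and rank selection is undefined; partial overlap, which is
also how real transcriptional programs behave, makes wrong-rank solutions
initialization-dependent and lets the consensus statistics identify the
planted rank.

## Quality control and normalization

`compute_qc()` reports per-cell feature counts, total UMIs, and the
percentage of UMIs from genes matching `^MT-` (case-insensitive,
configurable). `filter_cells()` keeps a cell iff
$200 \le \mathrm{features} \le 2500$ and $\mathrm{mito\%} \le 10$. The
thresholds are the workflow's standard values; removal is triggered only by
strict violations, so cells exactly at 200, 2500, or 10% are kept — the
boundary convention follows the strict inequalities in which the filter is
conventionally stated. All-zero cells have mito% defined as 0.

Normalization is library-size scaling to $10^4$ counts followed by
$\log(1+x)$, the de facto standard for UMI data. HVG selection ranks genes
by the residual of log variance against a running-median trend over the
mean (window 51), with lexicographic tie-breaks so the ranking is
deterministic. A loess fit would serve equally; the running median was
chosen for having no tuning parameters beyond the window.

## Two-step clustering and the stability criterion

Clustering builds a k-nearest-neighbor graph (exact Euclidean neighbors,
k = 15) on the top 30 principal components of the z-scored HVG matrix
(values clipped at ±10) and optimizes modularity with the Leiden algorithm
at a given resolution. Labels are relabeled 0-based by decreasing cluster
size. All stochastic steps take explicit seeds.

The working resolution is chosen by the subsampled adjusted-Rand-index
(ARI) procedure: for each candidate resolution the full data set is
clustered once as the reference; then 90% of cells are drawn without
replacement 20 times, each subsample is reclustered from its own kNN
graph, and the ARI is computed between the subsample solution and the
reference labels restricted to the same cells. The restriction-based
comparison (rather than subsample-vs-subsample pairs) is the literal
reading of comparing "the original and subsampled data"; subsample size is
`floor(0.9 n)`, and iteration $i$ uses seed `base + i`, which also means
one subsample serves every resolution. `select_resolution()`
operationalizes "the highest resolution at which the index begins to
decline" as the first drop of the mean ARI by more than δ = 0.05 — raw
first differences are noise-dominated at 20 iterations. Two refinements
are worth stating explicitly:

* A resolution whose *reference* partition is a single cluster is excluded
  from the decline rule. Any subsample reproduces a one-block partition
  trivially (the ARI convention for two one-block partitions is 1), so
  such resolutions would register the first informative resolution as a
  "decline" and select an under-resolved solution.
* If the mean ARI never drops by more than δ, the last (highest) scanned
  resolution is returned.

The second clustering step reruns the whole pipeline — HVG selection, PCA,
stability scan, clustering — inside the neutrophil compartment only. The
compartment itself is identified from the first-pass clusters by a
configurable marker-signature score (packaged default: canonical
neutrophil markers): every cluster whose mean score lies in the upper half
of the per-cluster score range belongs to the compartment. A single
"largest cluster" rule was rejected because a strongly structured
compartment can already split at the first pass; cell-type *naming* beyond
this score rule is intentionally out of scope.

The ARI itself is the Hubert-Arabie adjusted form computed from the
contingency table. Marker genes are found per cluster by one-vs-rest
Wilcoxon rank-sum tests (exact distribution for small tie-free groups,
normal approximation with tie and continuity corrections otherwise),
log2 fold changes on `expm1` means with pseudocount 1, and
Benjamini-Hochberg adjustment across the whole table.

## Signature scoring and the apoptotic mixture

Plain signatures are scored as the mean normalized expression of their
present genes (absent genes dropped with a warning). The aging-style score
is a weighted average of per-gene z-scores with weights ±1 encoding the
direction of the relationship; zero-variance genes are dropped. Weighted
scores are divided by the number of genes (a plain mean), the simplest
reading of a "weighted average".

The apoptotic classifier fits a two-component univariate Gaussian mixture
to the apoptosis score by EM: five starts (a median split first, random
responsibilities otherwise), variances floored at $10^{-6}\mathrm{var}$,
convergence at a log-likelihood gain below $10^{-8}$, components
canonicalized by mean. The component with the higher mean is the apoptotic
group and a cell is called apoptotic when its posterior exceeds 0.5 —
maximum-posterior assignment, with the tie at exactly 0.5 resolved as
non-apoptotic. On unimodal data the two components nearly coincide and the
split is near chance; this is documented behavior, not an error.

## Consensus NMF and rank selection

The factorization minimizes the Frobenius error $\|V - WH\|_F^2$ by
multiplicative updates from uniform random starts, stopping when the
relative RSS change falls below $10^{-6}$ (consensus runs use $10^{-5}$
and 150-200 iterations: many moderately converged runs characterize
stability better per unit time than few fully converged ones). The input
$V$ is the log-normalized expression of the target subpopulation
restricted to its top 500 HVGs, hence non-negative by construction.
Frobenius updates were preferred to divergence-based ones for numeric
robustness. Fits are canonicalized by scaling columns of $W$ to unit L1
norm, which leaves $WH$ unchanged.

For each candidate rank, 30 runs (seeds `base + run`) assign each cell to
its argmax metagene; the consensus matrix $C$ holds the co-assignment
frequency of every cell pair. Reported metrics: the cophenetic
coefficient (correlation between $1-C$ and the cophenetic distances of
average-linkage clustering of $1-C$), dispersion $\overline{4(C-1/2)^2}$,
the mean silhouette width of the consensus clustering under $1-C$, and the
best-run RSS. `select_rank()` takes the cophenetic argmax with
dispersion-then-smaller-rank tie-breaks, and the full table is always
emitted so the collective judgment over all four statistics stays
auditable. Module usage is the column-normalized $H$; per-sample usage is
the mean over the sample's cells (severity scores are per sample-day, so
sample level is the natural unit for usage-severity correlation), and
reporting letters A, B, C, ... are assigned by descending total usage.

## Deconvolution

The signature matrix takes the union of the top 50 markers per labeled
type (ranked by log2 fold change) and stores each type's mean
linear-scale (`expm1`) expression; a condition number above $10^6$ raises
a warning. Bulk profiles are restricted to the shared genes (at least 50%
of signature genes must be present), each bulk column and signature column
is total-sum scaled, and fractions are estimated by non-negative least
squares. The NNLS coefficients live in scaled-column units, so they are
divided by the original column totals before renormalizing to sum 1 —
this is what makes noiseless mixtures recover cell-count fractions
exactly. NNLS replaces the ν-SVR of the original deconvolution algorithm
deliberately: deconvolution is a means here, not a contribution, and the
exact-recovery property of NNLS on linear mixtures is what the tests rely
on. Log-scale bulk input (max < 50) is detected and reversed with a
warning.

## Statistics

Pearson tests use the exact $t$-transform on $n-2$ degrees of freedom;
day-wise comparisons use the Student t test and condition comparisons the
Welch test, following the conventions of the analysis being reproduced
(note these treat repeated samples of a patient as independent — a known
limitation replicated as-is). Multiplicity is handled by Bonferroni-Holm.
The AUC is the Mann-Whitney U-statistic with half-credit for ties,
identical to the trapezoidal ROC area, with an optional stratified
percentile bootstrap CI. The shock model is logistic regression fitted by
IRLS (Newton-Raphson on the binomial likelihood, convergence at gradient
norm $10^{-8}$, explicit errors on non-convergence or separation) with an
exposure-modifier interaction: continuous covariates are standardized, so
the interaction column is a product of centered fractions and the main
effects remain interpretable at covariate means; p-values are Wald.
`stratified_effect_curve()` evaluates predicted shock probability along
the exposure at modifier quantiles 10/50/90% with adjustment covariates at
reference values.

## Problem sizes and reproducibility

Every stochastic function takes a seed; the pipeline fans one global seed
into fixed per-stage offsets, so a stage can be re-run in isolation and a
full rerun is bit-identical. The packaged example configuration
(`example_config()`) runs 12 samples x 400 cells at 1200 genes with NMF
ranks 2-5 at 15 consensus runs — a desk-scale cohort chosen so a complete
pipeline run finishes in a few minutes on one core. The test suite uses
larger dedicated cohorts where a property demands them (e.g., ~8000
neutrophils for subtype recovery, 500 x 2000 for consensus rank
selection, n = 5000 for mixture and logistic recovery) and smaller ones
elsewhere; all sizes are stated in the tests themselves.

## Known limitations

Integration across batches, doublet handling, and cell-type annotation are
out of scope. The day-wise tests ignore within-patient pairing. The
consensus NMF of an unstructured subpopulation (no planted modules) has no
well-defined rank; on such data the rank metrics are low across the grid
and the selected rank is arbitrary — the metrics table, not the single
selected number, is the meaningful output. The deconvolution model assumes
bulk profiles are non-negative linear mixtures of the reference profiles;
platform effects between single-cell references and bulk assays are not
modeled.
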