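---
title: "Predicting diet-induced weight-loss class from baseline adipose RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting diet-induced weight-loss class from baseline adipose RNA-seq: methods and design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In dietary intervention cohorts, participants lose weight during a
low-calorie-diet (LCD) phase and then diverge widely during a maintenance
phase. `wlsig` implements a complete, testable pipeline for asking whether
*baseline* subcutaneous adipose tissue gene expression predicts who ends up
in the high versus low half of overall weight loss, and for characterizing
the gene signatures that carry that prediction.

The pipeline is a resampling architecture. For each of 100 Monte-Carlo
splits into 80% training / 20% testing subsamples:

1. **Labels.** Within each subsample separately, overall weight-loss
   percentage `100 (w0 - w8) / w0` is computed and samples strictly above
   the subset median are labeled high-WL, the rest low-WL. Labels are
   defined *after* splitting, so splits cannot be stratified by class.
2. **Feature discovery** (training side only): per-gene negative-binomial
   Wald tests of high-WL vs low-WL adjusted for sex, age and study center;
   genes at nominal P < 0.01 form the DEG set; hypergeometric
   over-representation of the DEG set against biological-process gene sets
   with Benjamini-Hochberg control (kept at P < 0.05, q < 0.2 and
   FDR < 0.05); an enrichment map connecting significant terms whose gene
   sets have Jaccard similarity >= 0.2, after collapsing redundant pairs at
   similarity >= 0.7 (the smaller-P term survives); connected components are
   pathway classes, labeled by keyword match (Lipid / Mitosis / Virus);
   from each labeled component's gene union, PCA on the training log-CPM
   selects the ten genes contributing most to the leading components that
   explain >= 70% of the variance.
3. **Aggregation.** Across the 100 runs, each class's signature is the ten
   genes most frequently selected; the discovery frequency (percent of all
   runs) travels with the signature.
4. **Evaluation.** A linear support-vector machine (cost 1) on the
   signature genes' log-CPM features, trained on the training subsample and
   scored by test-set ROC AUC. Counts are batch-adjusted and
   TMM/log-CPM-normalized *independently* within the training and testing
   subsamples — an unusual but deliberate design (no statistic crosses the
   split). The report contains the median and maximum AUC over runs and the
   DeLong 95% CI at the best run.
5. **Null reference.** 100 models built on random 10-gene sets drawn from
   the genes with more than 5 total reads, evaluated on the *same*
   resampling plan. The empirical P of a signature is the fraction of null
   models with a strictly higher median AUC; no continuity correction is
   applied, so P can be exactly 0.

Signature set algebra (union and differences of the first two classes),
clinical-factor models (alone and appended to a signature, with paired
t-tests and the |dAUC| < 0.1 run classification), and weight-trajectory
diagnostics (regainer identification, Jonckheere-Terpstra trend of
regainer burden across AUC strata) complete the pipeline.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha_nominal` | 0.01 | DEG cutoff (nominal, not FDR) feeding enrichment |
| `p_cut`, `q_cut`, `fdr_cut` | 0.05, 0.2, 0.05 | enrichment gates; all three are applied, so the effective FDR gate is 0.05 |
| `redundancy_cut` | 0.7 | Jaccard level at which near-duplicate terms collapse |
| `edge_cut` | 0.2 | Jaccard level at which terms are connected in the map |
| `variance_threshold` | 0.70 | cumulative PC variance defining the contribution subspace |
| `n_genes` (signature) | 10 | fixed signature size |
| `n_runs`, `train_fraction` | 100, 0.8 | Monte-Carlo resampling design |
| SVM `cost` | 1 | soft-margin cost; linear kernel only |
| null `n_sets`, `set_size`, `min_total_reads` | 100, 10, 5 | random-gene null ensemble |
| regainer threshold | 4% of baseline weight | maintenance-phase regain defining anomalous high-WL samples |
| AUC stratification | 0.6 | low/high run split for the regainer trend test |

Every threshold is an explicit function argument; the defaults are the
published operating point of the procedure.

## The synthetic cohort generator

Nothing in the pipeline requires external data: `generate_cohort()` draws
cohorts with the statistical structure the analysis assumes, and carries
ground truth for recovery tests.

* **Counts.** NB counts with a gene-wise dispersion trend
  `a0 + a1 / mean` (default `0.05 + 2/mean`), log-normal baseline
  expression, per-sample library-size factors (log-SD 0.2),
  per-center batch effects (log2-SD 0.15) and small sex effects.
* **Planted modules.** Gene modules whose log2 mean shifts by a configured
  effect size in the high-WL class (defaults: a 20-gene "lipid" module and
  a 10-gene "virus" module at effect 1, sharing half the virus genes, plus
  a weaker 15-gene "mitosis" module). Module genes additionally share a
  latent per-sample activity factor (log2-SD 0.8 by default): pathway genes
  in real tissue are co-regulated well beyond any outcome effect, and the
  PCA contribution rule — which retains the leading 70% of variance —
  behaves very differently on co-regulated blocks than on independent
  genes. With independent module genes the retained subspace is dominated
  by sampling-noise components and the selection cannot distinguish module
  genes from bystanders; with realistic co-regulation the module forms the
  leading component and is selected. This constant is therefore a
  structural assumption of the generator, not a tuning knob of the method.
* **Annotation.** `generate_annotation()` builds >= 50 flat gene-set terms:
  one core term per module — the module genes plus roughly 25% additional
  genes without planted effects, because real gene-set terms are larger
  than the differentially expressed core (the dilution also keeps two
  gene-sharing modules' term similarity below the map's edge threshold, so
  their components stay distinct, as in real enrichment maps) — three
  high-similarity siblings (Jaccard >= 0.7, exercising the redundancy
  collapse), two medium-similarity relatives (~40% of the core plus a
  random fill half that size, landing in the edge band), and random
  background terms. Term names embed the module name so keyword labeling
  works on synthetic data.
* **Trajectories.** Baseline weight ~ Normal(100, 15) kg truncated at 50;
  LCD loss percentage per class Normal(12.3, 2.9) / Normal(10.0, 1.9);
  maintenance change Normal(4.0, 2.5) for high-class non-regainers and
  Normal(-4.2, 2.8) for the low class, so the overall class means land near
  15.4% and 5.8%. A configurable fraction (default 0.2) of high-class
  samples gets a regainer mixture component Normal(-3, 1.5) truncated
  below 0, reproducing the order of magnitude of anomalous regainers
  (roughly a quarter of them exceed the 4% regain threshold).
* **Clinical factors.** 30 covariates; 4 informative ones correlate with
  the class at r = 0.3, 8 are log-normal (exercising the |skewness| > 1
  log-transform rule), the rest are noise.
* **Null cohorts.** `generate_null_cohort()` is identical except the
  trajectories are driven by a class label drawn independently of the one
  shaping expression, so expression-label associations are spurious by
  construction.

What the generator does **not** emulate: adipose biology, diet arms,
realistic GO topology (terms are flat sets with planted overlap only),
count outliers, sample swaps, or missing data. Passing recovery tests on
these cohorts demonstrates that the pipeline's machinery is correct and
calibrated, not that real adipose data carries this much signal.

## Numerical and design choices

* **TMM.** Factors use the published trimmed-mean-of-M-values procedure
  (log-ratio trim 0.3, intensity trim 0.05, inverse-asymptotic-variance
  weights, reference sample by upper-quartile closest to the mean),
  rescaled to geometric mean 1. The package's vectorized implementation
  reproduces `edgeR::calcNormFactors` to machine precision, which is pinned
  by a test, alongside an independent step-by-step spreadsheet-style
  oracle.
* **Log-CPM.** `log2((count + 0.5) / (lib * tmm + 1) * 1e6)`; the doubled
  prior in the denominator keeps the transform finite and monotone.
* **Batch adjustment** is a simplified NB-quantile scheme: per gene, a
  log-link NB regression on batch indicators plus sex and age (moment
  dispersions, edgeR's GLM fitter), then a mid-P quantile map from the
  batch-specific fitted NB to the fitted NB whose batch coefficients are
  replaced by their sample-size-weighted mean. It is not a port of
  ComBat-seq, but agrees with it on planted-effect recovery (a test pins
  this). Note that a batch effect shared by *every* gene is
  indistinguishable from sequencing depth — both this scheme and
  ComBat-seq model depth separately — so recovery is defined, and tested,
  on the depth-normalized scale.
* **Per-run normalization fast path.** Inside the resampling loop the
  exact integer quantile map is applied to the feature genes only; TMM
  factors and library sizes come from the expected-value-adjusted matrix
  (counts scaled by fitted mean ratios, correction factors bounded to
  32-fold). The public `batch_adjust_counts()` maps every gene exactly.
* **Differential expression** replaces the usual external DE tool with a
  native NB Wald test: moment dispersions shrunk 25% toward a fitted
  `a0 + a1/mean` trend, log-link NB GLM with median-of-ratios size-factor
  offsets, two-sided Wald P from the observed Fisher information. There is
  no fold-change shrinkage, independent filtering, or outlier replacement:
  the pipeline uses DE purely as a nominal-P gene filter, and the tests
  pin type-I calibration (null fraction at P < 0.01 within [0.005, 0.02])
  and effect recovery instead of bit-equality with any tool.
* **Enrichment** universe = genes surviving the low-count filter in the
  training subsample; term similarity uses full annotated gene sets (not
  DEG-restricted overlaps). Both choices are configurable; the published
  description is silent on them.
* **PCA contributions** are eigenvalue-weighted squared loadings over the
  retained components, normalized to sum to 1; genes are standardized
  first (log-CPM scales differ across genes). Ties break by gene id.
* **Aggregation** frequencies divide by *all* runs, including runs where
  the class was not discovered; ties break by better mean within-run rank,
  then gene id.
* **Degenerate runs** (a subsample whose labels are single-class) are
  skipped and counted, never imputed.
* **Jonckheere-Terpstra** uses exact permutation enumeration for total
  n <= 12 and a tie-corrected normal approximation with a 0.5 continuity
  correction otherwise; the regain denominator is baseline weight
  (configurable to the 2-month weight).
* **Seeds.** A single global seed fans out to stage seeds via a fixed
  affine map (`derive_seed`), so simulation, resampling and null sampling
  are independently reproducible.

## Problem sizes

The test suite and the acceptance script exercise the pipeline at desk
scale, chosen as the package's own working sizes: null-calibration cohorts
of 200 samples by 2,000 genes; recovery cohorts of 200 samples by 2,000
genes with a single center and one planted 20-gene module at log2 effect
1.0 (ten seeded replicates); DE calibration on 3,000 null genes by 100
samples; DeLong coverage on 500 simulations of 50 + 50 scores. The
analysis scripts run the full cohort analogue (281 samples, 8 centers,
3,000 genes, all three modules). A genome-scale matrix (50,000+ genes)
changes none of the algorithms, only the running time. The gene pool size
does matter for one quantity: with very small pools, random null sets
frequently contain planted signal genes, which legitimately inflates the
empirical P — on real genome-scale data signature genes are a vanishing
fraction of the pool.

## Limitations

* Class labels derive from a strict median split; cohorts with many tied
  weight-loss percentages can produce degenerate subsets.
* The empirical null P has resolution 1/100 and no continuity correction,
  exactly as specified; P = 0 means "better than all 100 null models", not
  "infinitely significant".
* The batch adjuster assumes at least two samples per center within every
  subsample; inside the resampling loop, smaller centers are pooled before
  adjustment.
* Only weight at 0, 2 and 8 months is modeled; regain dynamics between
  time points are out of reach of the three-point trajectories.
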