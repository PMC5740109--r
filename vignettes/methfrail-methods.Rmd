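---
title: "Methods: control-probe-adjusted EWAS, DMR detection, and methylation-based frailty discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-probe-adjusted EWAS, DMR detection, and methylation-based frailty discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

methfrail implements a complete desk-scale pipeline for epigenome-wide
association analysis of array DNA methylation with downstream frailty
discrimination: quality control and normalization, reference-based blood
cell-type deconvolution, a two-stage PCA-adjusted association scan,
bump-hunting detection of differentially methylated regions (DMRs),
fixed-effect meta-analysis across cohorts, a cumulative methylation risk
score, and a support-vector model that discriminates clinical frailty from a
probe panel. Every stage is exercisable on synthetic cohorts whose generative
truth is recorded, so the pipeline's statistical behaviour — calibration,
effect recovery, detection rates, permutation nulls — is testable without any
external data.

## The association model

For each CpG probe the methylation fraction (beta value, in `[0, 1]`) is
regressed by ordinary least squares on a binary exposure indicator plus
nuisance terms:

```
beta ~ group + age + smoking + alcohol + adherence + log10 viral load + WBC
       + CD4T + CD8T + NK + Bcell + Mono + Gran
       + control-probe PC1..30 + residual PC1..5
```

Estimation is on the beta scale, so the group coefficient reads directly as a
methylation difference (delta beta). Two-sided p-values use the t
distribution with the model's residual degrees of freedom. An M-value
analysis is not offered: the printed effect sizes this design targets are
delta-beta units, and the bounded scale is handled by the generator's
logit-normal noise model rather than by transforming the response.

The two PCA stages absorb confounding in sequence:

1. **Control-probe PCs.** Array control probes carry no biology, so principal
   components of their log intensities (per-probe centred, top 30 by default)
   capture technical structure — batch, staining, plate. Including them as
   covariates removes technical confounding even when it correlates with the
   exposure.
2. **Residual PCs.** After regressing beta on covariates, cells and control
   PCs (no group term), the top 5 principal components of the residual matrix
   stand in for global biological confounders the measured covariates miss.

PC signs are fixed by making the largest-magnitude loading positive, so runs
are deterministic across platforms. Calibration is monitored by the genomic
inflation factor `lambda = median(chi2)/0.4549`, computed on the group-term
p-values; values in `[0.9, 1.1]` indicate calibrated tests. Discovery-level
significance defaults to `p < 5e-7` with Benjamini–Hochberg q-values
attached; a replication scan is read at nominal 0.05. Samples with any
missing model term are dropped listwise with a logged count.

**A hazard worth knowing.** The residual-PC stage assumes true signal is
sparse. If a large fraction of probes carries a strong, shared
exposure-associated effect, the residual PCA can lock onto that direction and
absorb the signal itself. At real array scale (hundreds of thousands of
probes, a handful of genuine hits) the absorbed fraction is negligible; at
desk scale it is not, which is why the synthetic study designs here keep
spiked probes below ~0.3% of the array with the spike-factor variance under
the residual noise bulk. The package does not try to defend against dense
signal — that is a property of the method being reproduced.

## Quality control and normalization

Probes are removed in a fixed precedence order — control, sex-chromosome
(X/Y), SNP-proximal (within 10 bp), then detection failures — so every probe
has exactly one removal reason and the filter report reconciles:
`n_input = n_retained + sum(removals)`. Detection p-values score each
intensity against a normal background estimated per sample from a designated
background probe set; the conventional threshold is `p < 1e-12`, and samples
with call rate strictly below 98% are excluded. In an all-male cohort the
Y-chromosome probes conventionally serve as the background set; because the
mechanism (background vs. signal) is genuinely ambiguous in that design, the
background set is always a caller-supplied argument with Y probes as the
documented fallback rather than a hard-wired choice.

Sex is predicted from mean Y-probe beta: a two-cluster split (largest 1-D
gap, clusters called male/female when their means differ by more than 0.15)
with an absolute fallback threshold of 0.2 for single-sex cohorts; mismatches
against self-report are flagged, never auto-dropped. Quantile normalization
(via limma, stratified by probe design type by default) maps each sample's
sorted intensities to the cross-sample mean of sorted intensities and is
idempotent.

Cell-type proportions for the six leukocyte types (CD4T, CD8T, NK, B cells,
monocytes, granulocytes) are estimated by constrained least squares against a
purified-cell reference at its marker probes. The default constraint is
`w >= 0` with `sum(w) <= 1` — whole-blood fractions need not be exhaustive,
and published composition tables rarely sum to exactly 1 — with an equality
option behind a flag. The constraint is imposed by a slack variable and a
penalty row (weight 50) on top of non-negative least squares, which keeps the
solver dependency-free and is exact to about 1e-3 on the sum.

## DMR detection by bump hunting

Probes are grouped into clusters (maximal runs with inter-probe gaps at most
`max_gap = 500` bp), the covariate-adjusted per-probe group coefficients are
smoothed within clusters by a centred running mean (`window = 3`, shrinking
at edges), and candidate regions are maximal same-sign runs of at least
`min_probes = 3` probes whose `|smoothed|` exceeds the `cutoff_quantile =
0.99` quantile. A region's area is the sum of `|smoothed|` over its run.
These defaults are deliberately desk-scale and fully exposed as arguments;
no parameter set here claims to reproduce any specific cohort's region
count.

The null is built by permuting case/control labels `B = 100` times and
rerunning the full coefficient–smoothing–candidate pass, re-deriving the
cutoff each time, with all resulting region areas pooled across permutations
and clusters (per-region nulls at B = 100 are far too coarse). A region's
p-value is `min(1, (1 + #{pooled null area >= observed area}) / (1 + B))`.
The denominator is the number of permutation passes, not the pooled
null-area count: at a 0.99 cutoff a permutation pass yields on the order of
0.02 qualifying null runs, so dividing by the pooled count would floor
p-values near 1/3 and make the test unable to reject; dividing by passes
gives the natural floor `1/(B+1)`, which a region larger than every null
area attains even when permutations produce no null areas at all. BH
adjustment across candidates follows. The cost is that a null candidate —
itself a ~0.02-per-dataset event — receives a small p-value when it does
occur; the expected number of false-positive regions per null dataset stays
at that candidate rate, which the acceptance suite checks.

## Meta-analysis

Two schemes, both fixed-effect (random effects are deliberately out of
scope): inverse-variance pooling (`w = 1/SE^2`, pooled coefficient
`sum(wb)/sum(w)`, pooled SE `1/sqrt(sum(w))`) and the METAL-style
sample-size scheme (`Z = sum(sqrt(n) z)/sqrt(sum(n))` from signed probits of
the study p-values). Heterogeneity is Cochran's Q with
`I^2 = max(0, 100 (Q - (k-1))/Q)`. Probes present in only one cohort — the
practical consequence of combining array generations with partially
overlapping content — pass through flagged `pooled = FALSE` so the overlap
is always explicit. Pooled p-values receive their own BH pass. Where both
printed coefficients and SEs are available the inverse-variance scheme is
the default reading; both are implemented.

## Panel, score, clustering, and frailty discrimination

The probe panel is everything at association `p < 1e-3`, weighted by the
group coefficients, with a smallest-p-per-gene representative map. Panel
methylation is residualized against the nuisance design before scoring and
classification; the published description is internally inconsistent on
whether raw beta or residuals feed the score (its methods text says beta,
its results text says residuals), so `cumulative_score()` accepts either
value matrix and the pipeline defaults to residuals. The score is
`sum(w_i v_i)/|panel|` per sample, and its association with the frailty
index is a Pearson correlation with a t-based p-value.

Residualization fits per-probe OLS coefficients on the training samples and
stores them as a recipe; held-out samples are residualized with
training-fitted coefficients only, so no test information reaches training.
Across *cohorts*, however, the pipeline residualizes each cohort against its
own biological covariates, estimated cells, and — importantly — its own
control-probe PCs: technical axes are cohort-specific and cannot be
transferred from one array batch to another, and leaving batch variance in
the panel residuals measurably degrades any downstream model. Neither path
uses outcome labels, so neither leaks.

Unsupervised structure is assessed by complete-linkage hierarchical
clustering on Euclidean distances over panel residuals, cut at k = 2, with
chi-square tests (categorical) and one-way ANOVA (continuous) relating
cluster membership to phenotypes.

The frailty index (range 0–120, higher = more frail) defines a 5-band
partition (`<16, 17-24, 25-34, 35-50, >50`) and two binary tasks: high
frailty (`> 50`, the upper-quintile cut) and low frailty (`< 16`, the lower
quintile). The printed band labels leave edge values ambiguous; the
convention here assigns 16 to the second band while the binary cuts, which
are unambiguous, carry all quantitative claims. The classifier is a linear
support vector machine (radial available) with the cost chosen by stratified
10-fold cross-validation. Its default training target is the *index itself*
(epsilon-regression): a single predictive function predicts each test
subject's index, and both binary tasks are then evaluated by ROC on that
predicted score (the low task with the a-priori orientation that lower
predicted index means low-frailty). Training directly on a binary task is
supported (class-weighted C-classification with CV over AUC) but is not the
default: dichotomising the index at an ~80/20 split discards most of the
label information, and at these sample sizes the hinge loss on the rare
class recovers visibly less of the achievable discrimination than the
regression path. Test AUC comes with a stratified-bootstrap 95% CI (2000
replicates by default); no analytic variance is asserted.

The panel's specificity is checked by a random-panel permutation null:
panels of the same size drawn uniformly without replacement from all
analysed probes, each run through the identical residualize–train–test
pipeline (at a fixed SVM cost, so the null pipeline is the same function for
every draw), giving a null AUC distribution and
`p = (1 + #{null AUC >= observed}) / (B + 1)`.

## The synthetic-cohort generator

`generate_cohort()` builds a case/control whole-blood methylation study with
exactly the structure the pipeline assumes:

* **Baseline methylation** per probe is drawn on the logit scale from a
  three-component mixture (hypo / hemi / hyper-methylated, weights
  0.35/0.15/0.50 at logits −2.2/0/+2.2), reproducing the bimodal beta
  distribution of real arrays and its bounded, heteroscedastic noise once
  inverse-logit is applied.
* **Cell mixtures**: each sample's six leukocyte proportions come from a
  Dirichlet with mean (Gran .50, CD8T .17, Mono .11, B .09, NK .08, CD4T
  .05) and concentration 14, matching granulocyte-dominated whole blood with
  a granulocyte SD near 0.13; published composition tables print fractions
  for five types only, so CD4T absorbs the remainder. Reference marker
  probes follow the purified-cell profile; all other probes are cell-type
  invariant.
* **Covariate effects**: small per-probe age and smoking effects (logit-scale
  SDs 0.005/yr and 0.05) in age- and smoking-imbalanced groups, mirroring
  the measured confounding the model must adjust away.
* **Technical batch**: a per-sample factor with probe-specific N(0,1)
  loadings on the logit scale, optionally correlated with the group, and
  carried multiplicatively by the control-probe intensities — exactly the
  recoverability assumption behind control-probe adjustment. `batch_sd = 0`
  removes the signal entirely.
* **Spikes**: case-minus-control effects added on the beta scale at chosen
  probes or whole genes (contiguous runs, hence true DMRs), with spiked
  baselines forced hemi-methylated so the effect stays inside (0, 1). The
  manifest lays autosomal probes in gene runs of 3–10 probes spaced
  20–200 bp, so region structure exists by construction.
* **Frailty coupling**: the true burden is the spike-weighted sum of
  *biological* methylation — baseline, covariate effects, biological noise
  and spikes, but not the technical batch component. The index is a rounded,
  clipped linear transform (`33 + 20 z`) of `r z_burden + sqrt(1-r^2) e`, so
  its correlation with the burden equals `score_index_r` in expectation and
  its upper-quintile sits near the high-frailty cut of 50. Coupling frailty
  to the batch-contaminated observed values instead would make part of the
  burden unrecoverable by any batch-adjusted pipeline — an artefact of the
  simulation, not a property of the method.

One seed argument controls everything through R's default Mersenne–Twister
generator (restored afterwards via `withr`), giving bit-identical studies
per seed and no global-state side effects. The `truth` block (spiked probes
and regions with effect sizes, true cell proportions, batch factor, burden,
coupling) is sufficient to score every downstream stage.

What the generator does **not** emulate: probe-level chemistry (type I/II
dye bias beyond a design-type flag), IDAT-level artefacts, genomic
correlation of methylation beyond the spiked regions, population structure,
age-dependent drift of the methylome, or the real composition of a clinical
frailty index. Passing tests therefore demonstrate that the pipeline's
statistics behave as designed under the stated model — calibrated nulls,
recovered effects, controlled region-level FDR, chance-level random panels —
not that any specific biological finding would replicate.

## Numerical and design choices

* Mass-univariate OLS is solved once per design via QR with aliased columns
  dropped by name; standard errors come from `(X'X)^{-1}` diagonals. `t =
  coef/SE` holds to 1e-8 by construction and is asserted in tests.
* Power for a single-probe two-group design is Monte-Carlo (equal-variance t
  test per replicate) with its MC standard error reported. The within-group
  SD is a **required** argument: it is a property of the data that published
  power statements typically leave implicit, and defaulting it silently
  would manufacture a precision the user never stated.
* Probe-cluster tie-breaks (duplicate positions) are stable by probe id,
  with a warning.
* Degenerate inputs fail loudly and early: zero-variance control matrices,
  single-sample sex calls, one-class test sets, empty panels, all-removed
  samples.
* The pipeline caches each stage keyed by a hash of its parameters and its
  upstream hash; identical configs re-run byte-identically (asserted on
  output MD5s) and completed stages are skipped on resume.
* Demo and test problem sizes (a few thousand probes, cohorts of a few
  hundred) are chosen so the full synthetic study — two EWAS cohorts, DMR
  permutations, meta-analysis, classifier and permutation nulls — completes
  in well under a minute while keeping spiked signal sparse enough for the
  residual-PC stage to behave as it does at array scale; the acceptance
  checks state their sizes explicitly in `scripts/acceptance.R`.

## Known limitations

* Fixed-effect meta-analysis only; no random-effects, no genomic-control
  correction of study inputs.
* The bump-hunter uses a running mean, not loess, and a label-permutation
  null, not a bootstrap; comb-p/DMRcate-style alternatives are out of scope.
* The deconvolution reference is synthetic and six-type; it does not model
  reference-free settings or finer subsets.
* Real IDAT parsing is out of scope; the pipeline starts from intensity or
  beta matrices.
* The residual-PC hazard above applies to any application with dense strong
  signal.
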