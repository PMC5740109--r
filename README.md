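# methfrail

Epigenome-wide association analysis (EWAS) of array DNA methylation with
control-probe principal-component adjustment, and downstream discrimination
of clinical frailty from a methylation probe panel.

The package is aimed at analysts working with Illumina-style methylation
arrays in case/control designs where technical batch and cell-type
composition are serious confounders — for example, comparing exposed and
unexposed groups within an infectious-disease cohort and then asking whether
the exposure's methylation signature tracks a clinical outcome index. It
implements the full chain as composable, pipe-friendly functions, and ships
a synthetic-cohort generator with a recorded truth block so the entire
pipeline can be exercised, tested, and benchmarked without any external
data.

## The model

For each CpG probe, methylation beta (in `[0, 1]`) is modelled by OLS as

    beta ~ group + age + smoking + alcohol + adherence + lgVL + WBC
           + CD4T + CD8T + NK + Bcell + Mono + Gran
           + PC1-30(control probes) + PC1-5(stage-1 residuals)

where the two PC blocks come from (1) a PCA of log control-probe
intensities, absorbing technical batch, and (2) a PCA of the residuals of
beta on all nuisance terms, absorbing global biological confounding. Test
calibration is summarised by the genomic inflation factor
λ = median(χ²)/0.4549. Downstream stages:

* **DMRs** by bump hunting: cluster probes (gap ≤ 500 bp), smooth adjusted
  group coefficients (running mean, window 3), call maximal same-sign runs
  above the 0.99 |coefficient| quantile, and assign permutation p-values
  against pooled null areas from label permutations, p floored at 1/(B+1).
* **Meta-analysis**: fixed-effect inverse-variance pooling
  (w = 1/SE², pooled SE = 1/√Σw) and METAL-style sample-size weighting
  (Z = Σ√n·z/√Σn), with Cochran's Q and I² = max(0, 100(Q−(k−1))/Q).
* **Methylation risk score**: score = Σ wᵢvᵢ / |panel| over the p < 1e-3
  panel, weights = EWAS coefficients, correlated with the frailty index.
* **Frailty discrimination**: linear SVM on panel residuals, cost chosen by
  stratified 10-fold CV, trained against the frailty index itself; ROC/AUC
  with stratified-bootstrap 95% CI on the high- (> 50) and low- (< 16)
  frailty tasks, plus a random-panel permutation null.

See `vignettes/methfrail-methods.Rmd` for assumptions, parameter defaults,
and the generator's design.

## Worked example

The one-call demonstration runs the whole synthetic study — simulate three
cohorts, QC, discovery + replication EWAS, DMR calling, meta-analysis, panel
selection, clustering, scoring, and frailty prediction:

```r
library(methfrail)
out <- run_pipeline(demo_config(seed = 42), out_dir = "demo_run")
str(out$report)
#> $ qc_n_retained_probes   : int 7048
#> $ qc_n_sex_mismatches    : int 0
#> $ lambda_discovery       : num 1.01
#> $ lambda_replication     : num 0.944
#> $ n_significant_discovery: int 2
#> $ n_dmr_q05              : int 2
#> $ n_significant_meta     : int 9
#> $ panel_size             : int 21
#> $ cluster_group_p        : num 8.78e-14
#> $ score_index_r          : num 0.44
#> $ score_index_p          : num 1.26e-15
#> $ auc_high_frailty       : num 0.806
#> $ auc_low_frailty        : num 0.729
#> $ null_auc_mean          : num 0.503
#> $ permutation_p_high     : num 0.0196
```

Reading these numbers: both EWAS scans are calibrated (λ ≈ 1.0 despite an
injected batch factor, absorbed by the control-probe PCs); 2 probes reach
the discovery threshold p < 5e-7 and 9 reach it after meta-analysis with the
replication cohort; both spiked gene regions are recovered as DMRs at
q < 0.05; the 21-probe panel splits the samples into two clusters that align
with exposure (χ² p ≈ 9e-14) but not with other phenotypes; the cumulative
methylation score correlates with the frailty index (r = 0.44, p ≈ 1e-15);
and the panel predicts high frailty in the held-out test cohort with
AUC = 0.81 while random panels of the same size average AUC 0.50, putting
the true panel's permutation p at the 1/(B+1) floor (0.0196 at B = 50).

Individual stages compose with the pipe, e.g.

```r
man   <- generate_manifest(seed = 1)
ref   <- generate_cell_reference(seed = 2)
study <- generate_cohort(man, ref, n_case = 150, n_control = 150,
                         batch_sd = 0.3, seed = 3)
fit   <- run_ewas(study, reference = ref)
tidy(fit)      # per-probe coefficients, t, p, q
glance(fit)    # lambda, counts
autoplot(fit, type = "qq")
```

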