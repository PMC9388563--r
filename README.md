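# tiicsig

Multi-dimensional analysis of tumour-infiltrating immune cells (TIICs) in
multiplex-immunohistochemistry (m-IHC) data, built around the study design
used for predicting response to anti-PD-1/PD-L1 immunotherapy in gastric
cancer.

## Who this is for

Computational pathology and tumour-immunology groups who have per-cell
tables exported from an m-IHC image-analysis pipeline (inForm-style: one
row per segmented nucleus with centroid coordinates and binary marker
positivity, annotated with region of interest — tumour core TC, invasion
margin IM, adjacent normal N — and tumour-nest/stroma compartment) and
want reproducible density, spatial, predictive and prognostic statistics
on top of them.

## What it computes

- **Phenotyping** — boolean marker-combination rules
  (`CD8+PD-1+LAG-3-`, `CD68+STING+`, ...) applied cell-wise from a
  configurable registry; full-sign rule families are mutually exclusive
  and exhaustive over a lineage.
- **Densities** — per patient, phenotype, ROI class and compartment:
  pooled count over pooled area (cells/mm²), with the two-thirds-quantile
  high/low split used for survival stratification.
- **Spatial statistics** — nucleus-to-nucleus distances between immune
  and tumour cells. For a phenotype with cells *i = 1..n* in a patient's
  TC fields, the *effective score* at radius *r* is

  ```
  ES(r) = #{ i : min_j d(i, tumour_j) <= r } / n
  ```

  i.e. the fraction of immune cells "paired" with at least one tumour
  cell within *r* (10/20/30 µm), pooled over the patient's fields before
  the division; the *effective density* is the paired count per mm²
  (20 µm radius); nearest-tumour-cell distances are summarised per cell.
- **TIIC signature** — the 4-feature vector: densities of
  CD4+FoxP3-PD-L1+, CD8+PD-1-LAG-3- and CD68+STING+ cells plus the
  effective score of CD8+PD-1+LAG-3- T cells; optionally combined with
  EBV status, MMR status and PD-L1 CPS.
- **Response prediction** — four classifier families (extremely
  randomised trees, gradient boosting, AdaBoost, multi-layer perceptron)
  under repeated stratified 3-fold cross-validation with inner
  grid-search, reporting the AUC distribution over repetitions, its mean
  and 95% percentile interval, and per-feature importances.
- **Prognostic score** — univariate Cox hazard ratios as weights:
  `score = Σ HR_k · x_k`, median-split into high/low and compared by
  log-rank on irPFS/irOS.
- **Survival & cohort statistics** — Kaplan–Meier, log-rank, Cox
  (Efron ties, Wald CIs), a proportional-hazards check via a
  covariate × time cross-product, uncorrected Pearson chi-square,
  exact Mann–Whitney, Kruskal–Wallis with Dunn post-hoc tests, PD-L1
  combined positive score, reproducibility coefficient of variation.
- **Synthetic studies** — the source cohort is not deposited, so
  `simulate_cohort()` generates complete studies (Poisson or
  Thomas-clustered spatial patterns, tumour-proximity attraction with
  known true effective score, planted response and survival effects)
  against which every stage is tested.

## Worked example

```r
library(tiicsig)

cfg   <- simulation_config(n_patients = 12,
                           rois_per_patient = c(TC = 3, IM = 1, N = 1),
                           seed = 7)
study <- simulate_cohort(cfg)
study
#> <tiic_study> 12 patients, 60364 cells, 8 responders

head(study$signature[, 1:5], 4)
#>   patient_id d_cd4_foxp3neg_pdl1pos d_cd8_pd1neg_lag3neg d_cd68_stingpos
#> 1       P001                   77.3                  122            74.8
#> 2       P002                   90.1                  110            69.1
#> 3       P003                   79.4                  133            70.7
#> 4       P004                   86.0                  131            67.1
#>   es_cd8_pd1pos_lag3neg
#> 1                 0.395
#> ...
```

The densities are cells/mm² (the generator plants 80, 120 and 70 for the
three populations in TC fields); the effective score is the paired
fraction at 20 µm. Response prediction and prognosis:

```r
y   <- as.numeric(study$clinical$responder)
rep <- fit_predict_cv(as.matrix(study$signature[, 2:5]), y,
                      "extra_trees", repetitions = 50, seed = 7)
rep
#> <tiic_model_report> extra_trees - 50 repetitions
#>   mean AUC 0.919 (95% CI 0.726-1.000)

surv <- data.frame(patient_id = study$clinical$patient_id,
                   time  = study$clinical$os_months,
                   event = study$clinical$os_event)
ps <- prognostic_score(study$signature, surv)
ps
#> <tiic_prognostic_score> HR weights:
#> d_cd4_foxp3neg_pdl1pos  d_cd8_pd1neg_lag3neg  d_cd68_stingpos
#>                  0.970                 0.996            1.451
#>  es_cd8_pd1pos_lag3neg
#>                  0.140
#> cut: 301.9 - 6 high / 6 low
```

The AUC is far above 0.5 because the generator plants logistic response
coefficients on the signature features; the highest fitted HR weight sits
on the CD68+STING+ density, the feature the generator's survival model
penalises. The log-rank test on the high/low score groups gives
chi-square 4.15, p = 0.042 for this seed.

## Command line

```sh
Rscript inst/cli/tiicsig.R run-all --out out/ --seed 1 --fast
Rscript inst/cli/tiicsig.R simulate --config my_config.yaml --out out/
```

Stages: simulate, phenotype, density, spatial, signature, predict,
survive, stats. Each run writes a `manifest.json` with the config hash
and md5 of every output; identical seeds reproduce identical outputs
byte for byte.

## Documentation

The methods vignette (`vignettes/tiic-methods.Rmd`) describes the model
and its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the numerical design choices.
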