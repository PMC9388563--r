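---
title: "Methods: multi-dimensional TIIC analysis of multiplex-IHC data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-dimensional TIIC analysis of multiplex-IHC data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiicsig)
```

## The problem

Single biomarkers (PD-L1 combined positive score, EBV status, mismatch
repair status) stratify gastric-cancer patients for anti-PD-1/PD-L1
therapy poorly. Multiplex immunohistochemistry (m-IHC) provides per-cell
marker readouts in situ, so both the *density* and the *spatial
organisation* of tumour-infiltrating immune cells (TIICs) can be
quantified and combined into a predictive signature. This package
implements that analysis as a reusable pipeline over per-cell tables
exported from an image-analysis system: phenotyping, densities, spatial
statistics, a four-feature signature, a repeated cross-validated
response-prediction harness, an HR-weighted prognostic score, and the
supporting cohort and survival statistics.

Everything upstream of the per-cell table — staining, spectral unmixing,
tissue and cell segmentation, intensity thresholding — is out of scope:
marker positivity arrives already binarised and we do not re-threshold.

## Input model and assumptions

A *cell* is a segmented nucleus with centroid coordinates (µm, origin at
the field's top-left corner, y increasing downward; only intra-field
distances are ever used, so the frame convention is inconsequential as
long as it is consistent). Each cell belongs to one ROI (class TC =
tumour core, IM = invasion margin, N = adjacent normal; default field
930 × 700 µm = 0.651 mm²) and one tissue compartment (tumour nest or
stroma, assigned upstream by segmentation — cells straddling the
boundary must arrive with an assignment). Cells in overlapping fields
are deduplicated only by colliding ids; no geometric deduplication is
attempted (a documented limitation of the input contract).

## Phenotyping

A phenotype rule is a set of required-positive and required-negative
markers; a cell carries every rule it satisfies, so parent lineages
(`CD8+`) coexist with full sub-types (`CD8+PD-1+LAG-3-TIM-3-`). Within a
"full-sign" family (all sign assignments over a fixed marker set),
assignment is mutually exclusive and exhaustive over lineage-positive
cells — the property the test suite verifies by enumerating all 256
marker states. Tumour-flagged cells never receive an immune phenotype.

The shipped registry contains the populations named in the main analysis
(CD8 checkpoint combinations over PD-1/LAG-3/TIM-3; CD4 combinations
over FoxP3/CTLA-4/PD-L1; macrophage CD68/CD163/HLA-DR/STING states; CD20
B cells; CD66b neutrophils). The full 26-population panel of the source
design is supplementary-only material, so the registry is deliberately
user-extensible (YAML) rather than pretending to completeness. One
naming quirk is preserved on purpose: the source usage labels
CD68+CD163+HLA-DR- as "M1" and CD68+HLA-DR+CD163- as "M2", inverting the
common convention; the canonical marker strings are primary and M1/M2
are mere aliases.

## Densities and the tertile split

All of a patient's ROIs of one class form a cluster: the density is the
pooled count divided by the pooled area (cells/mm²), never an average of
per-ROI densities — the distinction matters when field areas differ.
For the "all" compartment the segmented tumour + stroma area is used
when provided, falling back to the nominal stamp area otherwise (the
fallback is flagged in QC; whether the source analysis used nominal or
segmented areas is not stated, so the package makes the choice explicit
and visible).

Patients are dichotomised at the empirical two-thirds quantile
(type-1/inverse-CDF, so no interpolation): strictly above the cut is
"high", ties at the cut go "low", matching the "≤ two-thirds" wording of
the design and making the split reproducible. For distinct values the
high group has `n - ceiling(2n/3)` members.

## Spatial statistics

For immune cells of one phenotype and tumour cells in the same field,
the *effective score* at radius r is the fraction of immune cells with
at least one tumour cell within distance ≤ r; the *effective density* is
the absolute count of those paired cells per mm². Radii follow the
0–10/0–20/0–30 µm design; the signature and the effective density use
20 µm, the scale of direct cell-to-cell contact.

Numerical choices:

- the pairing interval is **closed** (d ≤ r). Half-open pairing differs
  only on measure-zero events, but the convention must be fixed for the
  accelerated route to equal the brute force exactly;
- scores are computed on tumour-core ROIs, pooling paired and total
  counts across a patient's fields before one division;
- pairs are never formed across fields, and **no edge correction** is
  applied for cells near field borders — the upstream design applies
  none, and the resulting downward bias is shared by all patients;
- a patient with zero immune cells of a phenotype has a missing score
  (never 0), excluded pairwise downstream;
- the fast route is an exact KD-tree nearest-neighbour search (FNN); an
  O(n·m) brute force is retained and the two are required to agree
  exactly on random instances (an acceptance criterion).

## The TIIC signature and prognostic score

The signature is the fixed-order vector (density of CD4+FoxP3-PD-L1+,
density of CD8+PD-1-LAG-3-, density of CD68+STING+, effective score of
CD8+PD-1+LAG-3-); the combined form appends EBV (0/1), MMR (dMMR = 1)
and CPS. The effective-score radius is not printed in the source design;
20 µm is the default (consistent with the effective-density radius) and
is configurable.

The prognostic score multiplies each feature by its univariate Cox
hazard ratio and sums: `score = Σ HR_k x_k`, on raw feature scales (an
optional z-scaling switch exists, default off, because the design
multiplies "the value of the indicator itself"). Two points were
genuinely open and are resolved as explicit defaults:

- the high/low cut-point is unstated; the median of the scoring cohort
  is the least-arbitrary unsupervised choice and is configurable;
- which cohort the HR weights come from is ambiguous; by default they
  are fitted on the cohort being analysed, and `prognostic_score()`
  accepts externally fitted weights to fit-on-training/apply-on-
  validation instead.

## Response-prediction harness

Four classifier families mirror the published set: extremely randomised
trees, gradient boosting, AdaBoost and a multi-layer perceptron. No
suitable tree-ensemble or neural-network package is available in the
target runtime, so the families are implemented in the package: a
compiled CART learner (gini/variance impurity, weighted samples,
exhaustive or random-threshold splits) shared by the three tree
ensembles, and a tanh MLP with logistic output trained by BFGS on
analytic gradients with L2 penalty. Defaults mirror common published
defaults (100 unpruned extra-trees with √p features per split; 100
depth-3 boosted trees at learning rate 0.1; 50 AdaBoost stumps; one
16-unit hidden layer).

One repetition of the prediction process is: reshuffle stratified 3-fold
splits with a repetition seed derived from the master seed; within each
training split select hyper-parameters by inner 3-fold grid search (AUC
as the inner metric — unstated in the source, chosen to match the outer
metric); refit and score the held-out fold; pool the held-out
predictions into one AUC. The published design uses 5000 repetitions;
the shipped config keeps that default with a 200-repetition fast mode.
The report carries the full AUC distribution, its mean, and the
2.5/97.5 percentile interval (the CI method is unnamed in the source;
the percentile interval over repetitions is the natural choice for a
distribution the harness already owns). The hyper-parameter grids
themselves are supplementary-only; small published-style grids are
shipped and fully exposed in the config — the harness, not the grid, is
the method.

Feature importance: tree families expose impurity-decrease importances
normalised to sum 1 (AdaBoost weights per-tree importances by the
estimator weights). The perceptron has no impurity notion; it uses
permutation importance, labelled as an extension since the published
importances cover only the tree models.

Univariate logistic screening reports odds ratios with Wald intervals;
complete separation is detected and re-fitted with a weak ridge penalty,
labelled `penalised` with no p-value rather than reporting an infinite
estimate.

## Survival and cohort statistics

Kaplan–Meier, log-rank and Cox fits are backed by the survival package
behind the module's own interfaces; the test suite checks them against
hand-coded oracles (product-limit by hand, the observed-minus-expected
log-rank formula, a hand-maximised Efron partial likelihood). Ties use
the Efron approximation (unstated in the source; the least-biased common
default), confidence intervals are Wald on the log-HR scale. The
proportional-hazards check interacts the covariate with analysis time
literally — episode-splitting at event times and testing the
covariate × t product term — and flags the assumption satisfied at
p > 0.05.

Pearson chi-square is computed **without** continuity correction: the
printed baseline-table p-values (0.31 sex, 0.71 ECOG, 0.37 MMR, 0.28
EBV, 0.019 differentiation, 0.003 Lauren) match the uncorrected
statistic, which the acceptance suite verifies. Mann–Whitney uses the
exact distribution for small tie-free samples and the tie-corrected
normal approximation otherwise. Dunn's post-hoc z-tests adjust over all
pairs with Bonferroni by default (the adjustment family is unnamed in
the source; Dunn–Bonferroni is the conventional reading, and the method
is configurable). The PD-L1 CPS counts PD-L1-positive tumour cells,
lymphocytes (CD8/CD4/CD20) and macrophages (CD68) over viable tumour
cells × 100; neutrophils are excluded from the numerator by definition.

## The synthetic cohort: what a green test establishes

The source cohort (80 patients, 60 treated; 6488 fields) is not
deposited, so the package ships a generator whose defaults are the
stated world of the tests:

- 60 patients, training fraction 44/60, fields of 930 × 700 µm; 4 TC,
  1 IM and 1 N field per patient — the real design averaged ~56 TC
  fields per patient, which is computationally pointless for
  correctness testing, so field counts are desk-scale;
- nine generating immune populations at 30–120 cells/mm² in TC
  (literature-plausible m-IHC densities), region multipliers TC 1.0 /
  IM 1.2 / N 0.6, each population a full marker state so phenotyping
  recovers the generating label exactly;
- tumour cells at 1500/mm² in TC, Thomas-clustered by default (tumour
  nests are aggregated in real tissue; parent intensity 30/mm²,
  dispersion σ = 30 µm) with a Poisson mode retained because it admits
  the closed-form effective score 1 − exp(−λπr²) used as an acceptance
  oracle;
- optional tumour-proximity attraction: a fraction β of a population is
  displaced to a uniform point in the 20 µm disk around a random tumour
  cell (re-drawn to stay inside the field), so β directly controls the
  true effective score — β = 1 pins it at 1;
- responder labels from a logistic model and OS/irOS/irPFS from
  exponential models, both on within-cohort z-scored realised features
  (coefficients read as per-SD effects independent of density scales);
  default response directions match the published associations
  (CD4+FoxP3-PD-L1+ density and the CD8+PD-1+LAG-3- effective score
  positive; CD8+PD-1-LAG-3- and CD68+STING+ densities negative) with
  the intercept set to the published ~32% responder rate, and the
  default survival model penalises CD68+STING+ density;
- CPS is computed from the simulated cells themselves (tumour cells
  PD-L1-positive with probability 0.2); EBV/MMR/HER2 frequencies match
  the published cohort (15%/14%/25%).

The generator does **not** emulate staining artefacts, segmentation
errors, intensity distributions, spatial interactions between immune
populations, inter-field heterogeneity within a patient, or EBV biology.
A green test therefore establishes that the *computations* are correct
and calibrated on data with known truth — not that the published
cohort-level effect sizes (validation AUCs of 0.75–0.85, cohort HRs)
are reproduced; those depend on the undeposited data and are outside
what any reimplementation can verify.

One calibration design choice deserves a note. The null check of the
harness ("labels independent of features, mean AUC near 0.5") is run on
repetitions spread over 20 independent null draws rather than one fixed
dataset: the repetition-averaged CV AUC on a *single* n = 60 null
dataset retains dataset-level noise of roughly ±0.08 (one standard
deviation, measured with this package's own harness), which would make
a pass/fail band of 0.5 ± 0.08 uninformative about the harness itself.
Averaging over independent draws removes the dataset effect while
keeping the total repetition count; the band is untouched.

## Reproducibility

Every stochastic component is driven by one master seed: the simulator
fixes the full study; the harness derives per-repetition seeds from the
master seed; compiled tree learners use their own counter-based RNG
seeded per fit; MLP fits save and restore the global RNG state. The
pipeline writes a manifest with the config hash and the md5 of every
output; identical configs and seeds reproduce outputs byte for byte (an
acceptance criterion on a 20-patient smoke study).

## Known limitations

- No geometric deduplication of cells in overlapping fields.
- No edge correction for border cells in the spatial statistics.
- Immune–tumour pairs spanning adjacent fields are never counted.
- The perceptron importance is permutation-based, an extension beyond
  the published tree importances.
- The registry ships main-analysis populations only; the full
  26-population panel is not printed and must be user-supplied.
- Compartment densities require segmented areas; the nominal-area
  fallback applies only to the "all" compartment.
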