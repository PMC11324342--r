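---
title: "Stability-selected gradient boosting for blood methylation biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected gradient boosting for blood methylation biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Peripheral-blood DNA methylation is an attractive substrate for
treatment-response biomarkers: it is minimally invasive to sample, stable
over time for many CpG sites, and measurable genome-wide on standard
arrays. The statistical setting is hostile, however: a typical discovery
cohort has a few dozen patients and hundreds of thousands of beta values
(methylation fractions in [0, 1]), so any single model fit is dominated by
selection noise. `stabmeth` implements a discovery workflow built for
exactly this regime:

1. label patients responder (R) / non-responder (NR) with a strict
   composite endpoint (endoscopic response AND clinical and/or biochemical
   response, from paired baseline/week-8 scores);
2. remove probes whose beta distribution is multi-modal with well-separated
   clusters ("gap signals", which usually track genetic variants rather
   than methylation), plus any externally supplied drop-list;
3. select predictor CpGs by stability-selected gradient boosting with a
   permutation shadow-variable threshold;
4. evaluate the selected panel with a recalibrated ensemble on a withheld
   holdout, reporting mean ROC, AUROC, precision/recall/F1 and likelihood
   ratios;
5. quantify longitudinal stability of the panel (per-CpG intraclass
   correlation with Koo–Li interpretation bands; persistence of the group
   contrast across timepoints);
6. check composition confounding by reference-based cell-type
   deconvolution, and run per-CpG covariate regressions and gene-set
   over-representation as follow-up.

Because real cohorts of this kind are controlled-access, the package ships
a synthetic-data module that emulates the statistical structure the
analysis assumes; every stage is exercised end to end on generated data.

## The selection model

Let `X` be the samples-by-probes matrix of beta values and `y` the binary
response. One *repeat* draws a stratified 70/30 split, fits a gradient
boosted tree classifier (binomial deviance, exact greedy splits,
trees of depth 3, learning rate 0.1, row subsampling 0.8, up to 200
rounds chosen by 10-fold cross-validated early stopping on the training
split) and records

* the per-probe total-gain importance, min–max normalised within the
  repeat so the top probe scores 1; and
* the AUROC on the held-out 30%.

This is repeated `n_repeats` times (default 100) over re-drawn splits; a
probe's **aggregated importance** is the mean of its normalised
importances over repeats. Probes that matter only in one lucky split
aggregate to a small value; probes that the booster uses in most resamples
aggregate high — that is the stability-selection idea.

The selection bar comes from a **shadow variable**. For each of
`n_permutations` refits (default 1000) we drop one randomly chosen real
probe, append a shadow probe — a random permutation of another randomly
chosen probe's values across samples, so it has a realistic marginal
distribution but is independent of the labels by construction — and refit
a reduced-cost booster (fewer rounds; only the importance is read off,
not predictive accuracy). The shadow's normalised importance is recorded
each time, and the bar is a summary of that distribution. Probes whose
aggregated importance strictly exceeds the bar form the predictor set.

### Why the maximum shadow summary

The default summary is the *maximum* shadow importance over all refits
(the maximal-shadow rule familiar from Boruta-style wrappers). The
rationale: under a global null every probe behaves like the shadow, so the
maximum over ~1000 shadow draws sits far above the aggregated importance
of any typical null probe, and essentially nothing is admitted; under
genuine signal the boosters spend their splits on informative probes, the
shadow is rarely used, the bar drops towards zero and consistently
selected probes clear it. A quantile summary (`shadow_summary =
"quantile"`) is available for a less conservative bar. Two further
semantics are deliberately configurable because the verbal description of
the procedure admits both readings: whether the dropped probe is the same
one whose permutation is appended (`shadow_drop`), and whether the shadow
is a permuted real probe or i.i.d. noise (`shadow_mode`).

### Recalibration and evaluation

Given the predictor set, one stratified 20% holdout is withheld once (the
definite "the 20% withheld test set" — an alternative per-model re-split
is available behind `per_model_split`). `n_models = 50` boosters are then
trained on stratified resamples of the remaining 80%, restricted to the
predictor probes, and each is scored on the same holdout. The reported
ROC curve is the vertical average of per-model curves on a 101-point
false-positive-rate grid; AUROC, precision, recall and F1 are arithmetic
means over models, with the decision threshold for the confusion-based
metrics at predicted probability 0.5 (no other threshold is implied by
the procedure). `likelihood_summary()` converts an operating point into
positive/negative likelihood ratios and a post-test probability; at
sensitivity = specificity = 0.70 the positive likelihood ratio is 2.33,
and with a pre-test probability of 0.53 the post-test probability is
72.5%.

Precision and recall are reported per model and averaged; note that mean
precision, mean recall and mean F1 are each averages, so they need not
satisfy the F1 identity exactly.

## Longitudinal stability

For each probe, the subjects-by-timepoints matrix feeds a two-way ANOVA
decomposition and the intraclass correlation ICC(A,1) — two-way model,
absolute agreement, single measurement:

    ICC(A,1) = (MSR − MSE) / (MSR + (k−1) MSE + k/n (MSC − MSE))

with the consistency form ICC(C,1) selectable. Absolute agreement is the
default because test–retest stability of a biomarker should penalise
systematic shifts between occasions, not only reordering. Estimates are
banded by the Koo–Li thresholds (poor < 0.5 ≤ moderate < 0.75 ≤ good
< 0.9 ≤ excellent), boundary values going to the higher band. Subjects
missing a timepoint are listwise-deleted per probe.

`delta_correlation()` measures persistence of the differential-methylation
landscape: per probe, the responder-minus-non-responder mean contrast at
two timepoints, the Spearman correlation of the two contrast vectors over
probes, and a sign-quadrant per probe (hyper–hyper and hypo–hypo quadrants
indicate time-stable effects). A contrast of exactly zero is counted as
hypermethylated; with continuous beta values this is a measure-zero
tie-break.

## Cell-type deconvolution

Whole-blood methylation differences can reflect cell-composition shifts
rather than per-cell methylation change. `estimate_proportions()` performs
the classical reference-based projection: for each sample's beta vector
`b` over the signature probes, solve

    min_w || b − F' w ||²   s.t.  w ≥ 0, Σw ≤ 1

by quadratic programming (`quadprog`), where `F` is the cell-type-by-probe
signature. The inequality form is the standard projection convention;
`sum_to_one = TRUE` switches to the simplex equality. No real reference is
shipped — the generator builds a synthetic six-cell-type signature
(CD8T/CD4T/NK/B/Mono/Neu, 50 discriminating probes per type), and a TSV
slot accepts user-provided references. Group comparison per cell type uses
the Mann–Whitney test by default (robust at ~15 per group), Welch t behind
a flag, BH-corrected across the six types.

## Covariates and enrichment

Per predictor CpG, methylation is regressed on baseline SCCAI
(continuous) and corticosteroid use (binary) in marginal ordinary
least-squares models with two-sided slope t-tests, BH-corrected within
each covariate family; a joint model is available behind `joint = TRUE`.
At ~31 samples, plain OLS rather than an empirical-Bayes moderated fit is
defensible; moderation is a noted extension. Gene-set over-representation
is the one-sided upper-tail hypergeometric test against a universe that
defaults to all genes annotated to probes surviving filtering (not the
whole genome), BH across sets.

## The synthetic-data generator

The generator reproduces the *statistical shape* of a small two-arm
longitudinal methylation study; the study conditions are its defaults:

* **Cohort**: 31 subjects, 16 responders; 2000 probes of which 20 are
  informative with a ±0.15 beta-unit group shift (sign random per probe,
  mirroring a near-even hyper/hypo split). Real panels live on arrays with
  ~850k probes; 2000 keeps the p≫n geometry while remaining tractable,
  and the planted effect size is plausible for whole-blood response
  signatures rather than calibrated to any particular cohort (the real
  per-CpG effect sizes are not published at probe resolution).
* **Noise**: beta values are Beta-distributed with the mean/precision
  parameterisation `Beta(m·k, (1−m)·k)`, precision `k = 30` (within-group
  SD ≈ 0.09 at m = 0.5, typical of array beta values away from the
  boundaries).
* **Longitudinal replicates**: on the logit scale, each probe's observed
  between-subject spread is split into a persistent subject component
  (fraction `icc_target`) and an occasion component, then squashed back —
  so the target ICC is exact on the latent scale and approximately
  recovered on the beta scale (the logistic squashing is locally linear,
  and parameter-recovery tests confirm ±0.05 at targets 0, 0.5, 0.9).
* **Cell mixtures**: Dirichlet proportions times the signature plus
  clipped Gaussian noise.
* **Clinical records**: drawn so that the composite endpoint reproduces
  the assigned label by construction, with non-responders split between
  failing the endoscopic criterion and failing both the clinical and
  biochemical criteria.

What the generator does **not** emulate: probe-probe correlation (CpG
islands, co-methylated blocks), batch effects, array chemistry (detection
p-values, two probe designs), cell-composition-driven confounding of the
response effect, or missingness patterns. Passing tests on generated data
therefore demonstrate that the machinery is correct and calibrated under
the assumed model, not that any particular panel will validate clinically.

## Numerical choices and degenerate inputs

* The gradient-boosting machine is implemented in the package's compiled
  code (`gbm_fit()`): second-order boosting on the logistic loss with
  exact greedy split finding, L2-penalised leaf weights (lambda = 1), a
  minimum child hessian weight of 1 and per-tree row subsampling. At a
  few dozen samples there is nothing for histogram approximations to bin
  away, and exact splits depend only on the data; split-gain ties break
  deterministically on feature index then threshold.
* Gradient boosting runs single-threaded with an explicit per-fit seed;
  all repeat/permutation seeds derive from one master seed by counter, so
  a run is reproducible end to end and invariant to probe row order
  (probes are canonically ordered internally before fitting).
* The 2×2 chi-square uses no continuity correction; this is validated
  against the published cohort-characteristics table in the test suite.
* Mann–Whitney p-values are exact for small tie-free samples, otherwise
  normal approximation with tie correction; the output records which.
* Probes with any missing value are excluded from selection (the booster
  contract assumes complete features) but pass through I/O untouched.
* Zero-variance probes cannot receive an ICC (flagged as NA in reports)
  and constant vectors are rejected by the Spearman and gap-call
  routines (`gap_call` needs ≥ 3 non-missing values; groups smaller than
  `max(1, ceil(out_cutoff·n))` count as outliers, not modes, with
  `out_cutoff = 0.01` matching the upstream tool's semantics since the
  published setting "0.1" names the gap threshold only).
* Aggregated-importance ties (rare with continuous importances) break
  deterministically by probe id.

## Problem sizes used in the shipped simulation studies

The package's own calibration and recovery studies (test suite and
`scripts/acceptance.R`) run the full procedure at 2000 probes × 31
subjects with 15 selection repeats, 400 shadow refits at 40 rounds, fixed
150-round boosters (no CV early stopping), and 10-model ensembles —
20 replicates for null calibration, 10 for signal recovery at shift 0.15
plus 5 each at 0.10 and 0.05 for the monotonicity check. The shadow-refit
count is the binding choice: with ~1–2% shadow-usage probability per
refit, 400 refits keep the chance of a degenerate (never-used, zero) bar
below a couple of percent per replicate, and the median over replicates
absorbs the remainder. These sizes are the package's desk-scale defaults
for simulation studies; the procedure's defaults (100 repeats, 1000
permutations, 50 models, 10-fold CV) remain what an analysis of a real
cohort would use.

## Known limitations

* Pairwise imputation of missing betas is not implemented; complete-case
  features are required at selection.
* The enrichment step has no GO-graph-aware redundancy removal.
* No IDAT/array import or normalisation: the entry point is a normalised
  beta matrix.
* The recalibrated evaluation is internal validation on one holdout; with
  ~31 subjects its variance is substantial, which is exactly why the
  ensemble spread is reported alongside the means.

## A worked example

```{r, eval = FALSE}
library(stabmeth)

sim <- sim_cohort(n_probes = 2000, n_informative = 20,
                  effect_delta = 0.15, seed = 1)
ctrl <- stabsel_control(n_repeats = 15, cv = FALSE, nrounds = 150,
                        n_permutations = 400, shadow_nrounds = 40)
fit <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 1)
print(fit)
length(intersect(fit$predictor_set, sim$truth))  # recovered planted probes

ens <- recalibrate(fit, sim$betas, sim$sheet$response, n_models = 10,
                   seed = 2)
print(ens)
plot(ens)
```
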