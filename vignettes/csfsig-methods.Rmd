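---
title: "Methods: blood-based prediction of CSF amyloid-beta status"
author: "csfsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-based prediction of CSF amyloid-beta status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cerebrospinal-fluid amyloid-beta 1-42 (CSF Aβ1-42) is among the earliest
measurable indicators of Alzheimer's disease risk: levels below a
platform-specific clinical threshold (192 pg/ml for the Luminex assay that
this package's defaults emulate) are "abnormal" and mark incipient amyloid
pathology, often a decade before PET imaging turns positive. Lumbar
puncture is invasive and expensive, so a model that estimates CSF status
from a blood draw — plasma protein and metabolite panels plus age and
APOEε4 carrier status — is clinically valuable for trial screening.

`csfsig` implements that modeling pipeline end to end: cohort simulation,
missingness quality control with iterative random-forest imputation,
random-forest regression/classification under nested cross-validation with
data-driven ROC cutoff selection, recursive feature elimination with a
parsimony rule, and clinical validation by survival stratification and PET
concordance. Because real cohorts of this kind live in
access-restricted clinical registries, the package ships a synthetic cohort generator that
reproduces the *statistical structure* of such a cohort, so every stage is
testable without any download.

## The generative model

Each subject carries a latent CSF level

$$
L_i = \mu + \alpha C_i + \sum_j \beta_j s_j z_{ij} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),
$$

where $C_i \in \{0,1\}$ is APOEε4 carrier status, $z_{ij}$ are the
standardized informative analytes, $s_j \in \{-1,+1\}$ their effect signs
and $\beta_j > 0$ their sizes in pg/ml per SD. All remaining analytes are
independent standard-normal noise. True status is *abnormal* iff
$L_i < 192$ pg/ml (strictly below). Defaults:

* four informative plasma proteins with the effect directions established
  for this problem — chromogranin-A (+15), plasma Aβ1-42 (+18), plasma
  apolipoprotein E (+15) and eotaxin-3 (−12) pg/ml per SD;
* $\alpha = -50$ pg/ml for carriers, carrier prevalence 0.511;
* $\mu = 193$, $\sigma = 38$ pg/ml.

The last two values were calibrated once, numerically, so that (i) the
oracle linear score $-(\alpha C_i + \sum_j \beta_j s_j z_{ij})$
discriminates abnormal from normal subjects with AUC ≈ 0.85 — planted
signal that is neither trivial nor hopeless to recover — and (ii) the
abnormal prevalence among subjects with CSF measures is ≈ 0.67, matching a
memory-clinic training cohort. They are fixed package defaults, not tuning
knobs.

Around the latent level the generator draws:

* **cohorts** — a fraction (default 210/566) of subjects has the CSF
  measure withheld; they form the held-out validation cohort and are
  labeled MCI at baseline. Subjects with CSF get CN/MCI/AD diagnoses in
  58:198:100 proportions. Diagnosis is drawn *independently* of CSF status;
  the diagnosis–status association of real cohorts (CN almost never
  abnormal, AD nearly always) is deliberately not emulated, since CN
  subjects are excluded from the survival analyses anyway.
* **PET** — a subject's PET status equals the true CSF status except for a
  Bernoulli flip at the discordance rate (default 7/108 ≈ 0.065, the rate
  observed between the modalities in practice); SUVR values are drawn
  uniformly within ±0.5 of the tracer threshold (PiB 1.5, AV45 1.11) on
  the side realizing the status. Only the dichotomized status matters
  downstream.
* **conversion** — time to clinical AD diagnosis is exponential with
  per-month hazard 0.004 for CSF-normal subjects, multiplied by a hazard
  ratio (default 2.5) for abnormal subjects, administratively censored at
  120 months. Real conversion hazards are not constant, but every
  downstream method (Kaplan-Meier, Cox, log-rank) only assumes
  proportional hazards, so an exponential generator suffices. The default
  hazard ratio is a free parameter chosen to be a clinically plausible
  mid-range value; no published point estimate exists to calibrate it.
* **missingness** — MCAR at 2% per analyte cell by default. Real assay
  missingness is probably not completely at random; MNAR mechanisms are out
  of scope, so passing imputation tests here says nothing about
  informative missingness.

## Quality control and imputation

Analytes with a missing fraction **strictly greater than** 15% are removed
("more than 15%" read literally); samples with strictly more than 5%
missingness are flagged but never dropped automatically. Remaining gaps are
filled with chained regression forests in the missForest style: initialize
with column medians, visit variables in order of increasing missingness
(ties by column order), regress each on all others over its observed rows
with a 100-tree forest, and sweep until the sum of squared changes in the
imputed values increases (the previous sweep is then kept) or 10 sweeps
elapse. Observed cells are never altered. Imputation runs inside the
training cohort and, separately, inside the validation cohort restricted to
the analytes the training QC retained — no information flows between
cohorts. Whether the original analyses imputed before or after splitting is
unknowable from the outside; imputing within cohorts is the conservative
(leak-free) choice.

## Forests, metrics and the cutoff machinery

Both tasks use 2000-tree forests with `mtry = floor(p^0.75)` (the floor is
a convention choice; the exponent follows the recommendation for many
weakly informative features) and all other tree parameters at the
`ranger` backend defaults. The binary task scores subjects by the fraction
of tree votes for the abnormal class; the regression task predicts the
continuous level, and all its ROC analyses use the negated prediction so
that higher score = more abnormal. Permutation importance is the increase
in out-of-bag error when one feature is shuffled.

Dichotomizing regression predictions needs a threshold. `select_cutoff`
scans every candidate — midpoints of adjacent distinct predicted levels
plus ±∞ — under the orientation "level < threshold ⇒ abnormal" and
optimizes one of six standard criteria: Youden, ROC01, MaxSpSe,
MaxProdSpSe, MaxEfficiency, MaxKappa (the classical sextet of the
cutoff-selection literature; the original analysis named its six criteria
only in an unavailable supplement, so this closed set is an explicit
package assumption isolated behind `cutpoint_criteria()`). Ties break
toward the threshold closest to the median predicted level, then toward
the smaller threshold, making selection deterministic and invariant to
increasing affine transforms of the predictions.

## Nested cross-validation

The outer loop (10 repetitions × 10 folds by default) estimates
generalization performance; the inner loop (3 × 3) selects the only free
parameter, the cutoff criterion, as the one maximizing the mean accuracy
over all inner test folds (averaging per fold; exact ties resolve in the
fixed criterion order). The outer-train forest is then refit and its
threshold derived from **out-of-bag** predictions under the winning
criterion — resubstitution predictions of a forest are nearly perfect and
would push thresholds to degenerate values. Folds are stratified by CSF
status by default (a stability choice at n ≈ 356; `stratified = FALSE` is
one switch away). Per-fold AUC/accuracy/sensitivity/specificity/R² are
summarized as mean (SD), pooled outer-test predictions feed the aggregate
ROC, and models are compared by one-tailed Wilcoxon signed-rank tests on
paired per-fold AUCs at a Bonferroni-corrected 0.05/5 threshold. The
signed-rank p-value is computed exactly (by convolution of the sign-flip
distribution, valid under tied differences) up to 50 non-zero differences,
and by a tie-corrected normal approximation beyond.

## Recursive feature elimination

Within each inner fold, features are ranked by permutation importance,
the lowest-ranked dropped to the next schedule size, the forest refit, and
the test AUC recorded — importances are recomputed after every step
("recursive" in the strict sense). The schedule drops 20% of the remaining
features per step while more than 30 remain, then one at a time to a single
feature: single-feature resolution where it matters, bulk moves where it
does not. The subset size is the smallest whose mean inner-CV AUC is within
4% of the maximum; "within 4%" is read **relatively**
(≥ 0.96 × max), with the absolute reading (≥ max − 0.04) available behind
`relative = FALSE` since either is defensible. Applying the same procedure
once to the full training cohort yields the production feature subset —
the analog of reducing a ~150-analyte panel to a handful of markers plus
APOEε4. Outer-fold metrics for the reduced models derive their thresholds
from OOB predictions under the Youden criterion (re-running the
six-criterion inner selection per elimination step would multiply the cost
for little benefit; the choice is configurable).

## Clinical validation

The production models (baseline, full proteomic, parsimonious) predict
status on the validation cohort, and baseline-MCI subjects are stratified
into predicted-normal vs predicted-abnormal. Kaplan-Meier curves with
log-transformed Greenwood 95% bands, the single-covariate Cox hazard ratio
(Breslow ties, Wald CI) and the log-rank test quantify the separation;
cross-cohort log-rank tests check that each predicted stratum's survival is
equivalent to the corresponding measured-CSF stratum on the training
cohort. PET concordance uses each subject's earliest PET record (ties at
the same month resolved PiB first), dichotomized at SUVR ≥ 1.5 (PiB) or
≥ 1.11 (AV45) — boundary values classified abnormal, a documented
convention — and reports the AUC of the model scores against PET status,
separately per cohort. Kaplan-Meier, Cox and log-rank computations are
delegated to the `survival` package behind this module's interface; the
test suite cross-checks them against hand-computed product-limit values and
a brute-force partial-likelihood maximizer.

## Determinism and numerical choices

Every random draw descends from one global seed through
`derive_seed(seed, stage, repetition, fold)` (a multiplicative hash mod the
largest prime below 2³¹), so adding a pipeline stage never perturbs earlier
stages' draws, and identical configurations reproduce results byte for
byte. Forests run single-threaded for reproducibility. Degenerate inputs
are handled explicitly: constant regression targets flag the fit (R²
undefined), single-class folds abort with the fold identity, all-identical
predicted levels return a flagged degenerate cutoff, a stratum without
events flags the Cox fit, and no events at all give a log-rank statistic of
0 with p = 1.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script exercise the pipeline at
reduced sizes chosen to keep a complete run on one CPU comfortable while
leaving every statistical property measurable: 200–500-tree forests,
cohorts of 350–566 subjects, a 2 × 5 outer loop with a 1 × 3 inner loop,
and panels of 30–150 analytes (the planted-feature recovery check keeps
the full ~150-analyte width). These sizes are stated here as package
choices; all defaults remain at the full study scale (2000 trees,
10 × 10 / 3 × 3).

## Known limitations

* The generator's analytes are independent Gaussians apart from the
  planted effects; real panels have correlated blocks and heavy tails, so
  passing recovery tests here does not guarantee recovery under collinear
  signal. (The imputation tests *do* use correlated blocks, which is the
  property imputation needs.)
* Diagnosis is independent of CSF status (see above).
* MCAR missingness only; exponential hazards only.
* The six cutoff criteria and the 4%-rule reading are stated assumptions
  where the original description is not fully specified; both are isolated
  behind configuration points.
* Binary-task fits are unweighted despite the ~2:1 abnormal prevalence;
  sensitivity/specificity trade-offs shift accordingly.
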