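---
title: "ProteoMACE: methods and design notes"
author: "ProteoMACE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProteoMACE: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoMACE)
```

# The problem

Chronic coronary syndrome (CCS) is the stable phase of coronary artery
disease, but "stable" is relative: a sizeable fraction of patients go on to
major adverse cardiovascular events (MACE — cardiovascular death,
non-fatal myocardial infarction, unstable angina, heart failure). A
plasma-proteomic case/control comparison of patients who later did or did
not experience a MACE is a natural discovery design for prognostic
biomarkers, and a prospective survival cohort with ELISA-measured candidate
levels is the natural validation design. ProteoMACE implements the full
analysis chain between a quantified protein abundance matrix and a
validated risk model, together with synthetic-cohort generators so every
stage can be exercised and tested without patient data.

# Stage 1: differential abundance

For each protein, the event / non-event fold change is the ratio of
linear-scale group means over the non-missing entries, and significance is
a two-sided Welch (unequal-variance) *t*-test. A protein is a DEP when

$$\mathrm{FC} > 1.2 \;\text{or}\; \mathrm{FC} < 0.8,
\qquad p < 0.05 .$$

Two scale choices deserve note. The *t*-test is run on log2 abundances by
default (`logTransformTest = TRUE`) while FC stays a ratio of linear-scale
means: relative MS quantification has multiplicative error, so the log2
scale is where a location test is well-behaved, while fold change is
conventionally reported on the linear scale. Missing values are handled by
complete-case analysis per protein per group — no imputation, because any
imputation model would add assumptions the data collection does not
support. A protein with fewer than two observations in a group (or zero
variance in both groups) is flagged *untestable* rather than raising an
error; untestable proteins are counted, reported, and never selected. No
multiplicity correction is applied to DEP selection itself — the criterion
is the joint FC + raw-*p* rule above — whereas enrichment *p*-values
(below) are corrected.

# Stage 2: enrichment

Each annotation term (from a user-supplied GMT file) is tested for
over/under-representation of the DEPs against all identified proteins with
a two-tailed Fisher exact test on the 2×2 table. The two-tailed rule is
the *minimum-likelihood* convention: the *p*-value is the sum of the
hypergeometric point probabilities of every table (with the observed
margins) no more likely than the observed one, with a relative tolerance
of 1e-7 absorbing floating-point ties — the same convention as
`stats::fisher.test`, against which the implementation is cross-checked.
Multiple testing is controlled by Benjamini–Hochberg, the dominant
convention for enrichment when a "corrected *p*" is wanted without a
specified method. Terms with no background members are dropped; term
member lists are intersected with the background before testing.

# Stage 3: incremental feature selection

Features (the DEPs) are ranked by a univariate two-group one-way ANOVA *F*
test on log2 abundance — for two groups this is exactly the squared
pooled-variance *t* statistic, which the tests assert numerically. The
ordering is ascending *p*, ties broken by descending *F*, then
lexicographic id, so it is total and reproducible.

Nested subsets along the ranking (top-1, top-2, … top-`kMax`, default 30)
are scored by the stratified 10-fold cross-validated Matthews correlation
coefficient of a soft-voting classifier, and the selected subset is the
smallest *k* attaining the curve maximum (the *first-maximum* rule).

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FN)(TN+FP)}}$$

with MCC defined as 0 when any denominator factor vanishes (the standard
continuity convention). MCC inside the IFS loop is computed from the
held-out probabilities **pooled across folds** and thresholded at 0.5: with
38 samples, per-fold confusion tables are tiny and a per-fold MCC average
would be dominated by degenerate folds.

The ensemble averages the predicted event probabilities of three base
learners with equal weights:

* ridge-penalized logistic regression (`glmnet`, `alpha = 0`,
  `lambda = 1/n`). A penalized linear learner is deliberate: with tens of
  features against ~34 training samples an unpenalized logistic fit
  separates perfectly and emits degenerate 0/1 probabilities;
* a radial-kernel SVM with Platt-calibrated probabilities
  (`e1071::svm(probability = TRUE)`);
* a random forest (500 trees).

Per-feature median imputation and standardization are fit on the training
folds only and applied to the held-out fold — the no-leakage property is
verified by a label-permutation test. Folds are stratified by class, and
all stochastic components (fold assignment, SVM calibration, forest) run
under seeds derived deterministically from one classifier seed (default
20150419), so identical inputs give identical curves. Cross-validated ROC
and AUC for the selected panel use the tie-corrected Mann–Whitney
construction on the same pooled held-out probabilities.

Equal voting weights are a documented choice (probability-weighted voting
without stated weights admits any convex combination; equal weights are the
neutral default). The probability threshold 0.5 for confusion counts is
likewise a convention; the ROC view is threshold-free.

# Stage 4: survival validation

Candidate biomarkers are validated in a prospective cohort by Cox
proportional-hazards regression (`survival::coxph`, Efron tie handling),
univariately and adjusted for the seven Framingham CHD covariates: age,
sex, total cholesterol, HDL-C, systolic blood pressure, current smoking,
diabetes. Hazard ratios carry Wald 95% CIs; the overall model *p* is the
score test, which for a single binary covariate is the log-rank test — the
pairing conventionally used when HRs are reported "with log-rank
*p*-values". Biomarkers enter the model in raw measurement units;
"per-*k*-units" reporting (e.g. per 10, per 100) is applied after the fit
as $\mathrm{HR}_k = e^{k\hat\beta}$ with CI $e^{k(\hat\beta \pm 1.96\,
\mathrm{se})}$, so $\mathrm{HR}_k = \mathrm{HR}_1^k$ exactly.

The baseline risk model is the Cox model **refit on the cohort** with the
seven Framingham covariates — not the published Framingham point score —
because a cohort-specific AUC implies cohort-specific coefficients. The
combined model adds the candidate biomarkers. Each model's risk score is
its centered linear predictor; the two scores are compared as ROC curves
for the binary event-by-end-of-follow-up outcome with DeLong's
structural-components *z*-test, which estimates
$\mathrm{var}(\widehat{AUC}_A - \widehat{AUC}_B)$ accounting for the
correlation induced by scoring the same subjects. Identical score vectors
return $z = 0$, $p = 1$ by convention. A time-dependent ROC (censoring
weights, Harrell's C) is out of scope and flagged as future work.

# The synthetic generators

The generators define the study conditions the test-suite runs under; they
are first-class, tested code.

**Discovery** (`simulateDiscovery`): per-protein baseline log2 means are
Gaussian (`baseLog2Mean = 20`, `baseLog2Sd = 1.5` across proteins);
within-group measurement noise is Gaussian on log2 with `noiseSd = 0.5`;
values are exponentiated to the linear scale, matching the multiplicative
error structure of MS relative quantification. Defaults mirror the
emulated design: 19 + 19 samples, 783 proteins, 57 planted differential
proteins with mean |log2 FC| 0.6 (≈ the 1.2/0.8 FC gate at 1.5×) and a
random sign per protein, 10% missingness completely at random (MCAR —
no mechanism being specified for the real data, intensity-dependent
missingness is a non-goal). `noiseSd = 0.5` gives single-protein effect
sizes (d ≈ 1.2 at the default planted effect) in the range typical of
plasma DIA panels. The log-normal form is itself an assumption — the
post-quantification distribution of real plasma abundances is not
specified by any upstream contract.

**Validation** (`simulateValidation`): covariates follow the reported
validation-cohort distributions (age ≈ N(81, 9.3) years truncated at 65,
total cholesterol ≈ N(4.0, 0.78) mmol/L, HDL-C ≈ N(1.37, 0.48), systolic
BP ≈ N(133, 17) mmHg, 12% smokers, 37% diabetes). Sex is mixed (70% male)
although the emulated study enrolled only men: a constant covariate would
make the seven-covariate baseline refit singular, so this deviation is
accepted and documented. Biomarker levels are Gaussian on an arbitrary
ELISA-like scale (EPCR 100 ± 25, CETP 1500 ± 400, CPB2 900 ± 250); true
effects are parameterized **per SD** (`logHrPerSd`), decoupling the
generator from measurement units, and converted to per-unit HRs after
fitting. Event times are exponential proportional hazards with linear
predictor $\sum\beta x$ (continuous covariates standardized by their
generating scale), administratively censored at 48 months; the baseline
rate is calibrated by bisection on $\log_{10}\lambda_0$ (200 iterations,
bracket $10^{-12}..10^4$) so the expected realized event fraction matches
the target (default 24.3%, the emulated rate). Censoring is
administrative-only; dropout is a non-goal.

What passing tests on these data do *not* show: robustness to batch
effects, intensity-dependent (MNAR) missingness, non-proportional hazards,
informative censoring, or correlated protein blocks — none of which the
generators emulate.

# Numerical choices and degenerate inputs

* Welch test: both groups constant → untestable, not an error; `t.test`'s
  "data essentially constant" condition is caught.
* MCC: 0 on a vanishing denominator factor.
* Fisher two-tail: relative tolerance 1e-7 on point-probability ties.
* Standardization: constant features get scale 1 and pass through as 0.
* `glmnet` needs ≥ 2 columns; single-feature fits are padded with a
  constant zero column whose ridge coefficient is exactly 0.
* Cox: aliased (singular) designs and constant covariates raise named
  errors; event times are floored at 1e-6 months against underflow.
* DeLong with zero variance: z = 0 when the AUC difference is also 0.
* All seeds are kept below 2^31; generators restore the caller's RNG
  state, so they are pure functions of their arguments.

# Problem sizes used by the test-suite

Simulation-based checks run at the smallest sizes where the property under
test is identifiable: Cox recovery and coverage at n = 5000; DeLong
calibration with 1000 replicates at n = 200; DEP power at 50 per group;
IFS recovery at 50 per group (at 19 + 19 the pooled-MCC curve cannot
resolve a third feature worth ~2 pooled errors, so the planted subset is
not identifiable at that size — a finding about the design, not the
implementation); the permutation-null check at the discovery size of
19 + 19.

# Known limitations

* Pooled 10-fold CV AUC at n = 38 has null dispersion ≈ 0.12, about 25%
  above the plain Mann–Whitney null (0.095), and a small pessimistic bias
  (null mean ≈ 0.48). This is a property of pooled CV prediction scoring
  at small n, not leakage; the permutation null is centered where it
  should be.
* CV AUC of the selected panel is optimistic because feature ranking and
  subset selection see all samples; nested CV would remove this and is
  deliberately not implemented.
* The final narrowing from the IFS-selected panel to a handful of
  clinically validated biomarkers is partly judgment-based in any real
  study; the package carries the algorithmic part and takes the final
  biomarker list as user input to the validation stage.
* Proportionality diagnostics, competing risks and time-dependent ROC are
  out of scope.
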