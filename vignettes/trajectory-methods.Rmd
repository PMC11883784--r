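---
title: "Modelling symptom trajectories by inflammation level: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling symptom trajectories by inflammation level: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`inflamtraj` implements a life-course trajectory analysis: multilevel
polynomial growth-curve models of repeated depressive-symptom scores
stratified by baseline IL-6 tertile, with delta-method contrasts of
predicted scores at an age grid, FDR adjustment, cross-cohort
standardisation, and a sensitivity battery. This vignette is the package's
account of the statistics: the model and its assumptions, the parameters
that matter, what the synthetic-cohort generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open.

## The model

Let $y_{ij}$ be the symptom score of person $i$ at assessment $j$, and
$c_{ij} = \mathrm{age}_{ij} - a_0$ the age centered at the cohort's
minimum assessment age $a_0$ (10 years for the youth profile, 39 for the
mid-life profile; centering at the minimum keeps the intercept
interpretable as the score at study entry and improves conditioning). The
model is the Gaussian linear mixed model

$$y_{ij} = \sum_{k=0}^{d}\beta_k c_{ij}^k
  + \sum_{g}\mathbb{1}[G_i = g]\Big(\gamma_{g0} + \sum_{k=1}^{d}\gamma_{gk} c_{ij}^k\Big)
  + x_i'\delta + \sum_{k=0}^{q} b_{ik} c_{ij}^k + e_{ij},$$

with fixed polynomial degree $d \in \{1,\dots,4\}$, tertile groups
$g \in \{\text{middle}, \text{top}\}$ against the bottom-tertile
reference, person-level random coefficients
$b_i \sim N(0, \mathbf{G})$ with *unstructured* $\mathbf{G}$ of dimension
$q + 1 \le d + 1$, and $e_{ij} \sim N(0, \sigma^2)$. Raw powers of
centered age are used — not orthogonal polynomials — so that reported
coefficients are in score units per centered-year$^k$, the convention in
which such analyses are reported.

Assumptions worth stating plainly:

* **Gaussian outcome.** The instruments are bounded sums of ordinal items
  (SMFQ 0–26, PHQ-2 0–6). The Gaussian model treats them as continuous;
  this is the field's standard practice and is what the package fits.
* **Missing at random.** The likelihood is computed over observed rows
  only (full-information maximum likelihood): a person's missing wave is
  ignorable provided missingness does not depend on the unobserved score
  at that wave given their observed trajectory. The generator can violate
  this on purpose (see below).
* **No group × covariate or age × covariate interactions.** A useful
  consequence is that group contrasts are invariant to the covariate
  profile at which predictions are made; the package tests this
  invariance to 1e-10.

Estimation is by maximum likelihood through `lme4::lmer`. ML rather than
REML is the default because the degree-selection ladder compares models
that differ in their fixed effects, for which REML likelihoods are not
comparable; REML is available by flag for final-model refits.

## Degree selection, convergence, and inference

`select_degree()` fits each candidate degree with the random structure
held constant, and reports log-likelihood, parameter count,
$\mathrm{BIC} = -2\ell + p\log n_{\mathrm{obs}}$, and likelihood-ratio
tests between consecutive candidates. The BIC sample size is the
observation count, the common mixed-model convention; since conventions
differ, the quantity is stored alongside its inputs so any alternative can
be recomputed. The chosen degree is the lowest BIC, ties resolved toward
the lower degree.

Two numerical choices matter here:

* **Internal age rescaling.** With centered ages up to 18 (youth) or 41
  (mid-life), $c^4$ spans five orders of magnitude and derivative checks
  become unreliable. The design is fitted on $c/s$ (with $s$ the maximum
  absolute centered age) and the estimates, their covariance and
  $\mathbf{G}$ are transformed back *exactly* — a linear
  reparameterisation, not an approximation — so reported coefficients are
  per raw centered-year$^k$.
* **Optimizer retry before structural fallback.** `lme4`'s gradient check
  raises "failed to converge" warnings at large $n$ that are often false
  alarms. `fit_growth_model()` first retries the same model with the
  `bobyqa` optimizer; only if no optimizer yields a clean fit does it
  reduce the random order $q \to q-1 \to \dots \to 0$, recording the
  fallback. Singular (boundary) $\mathbf{G}$ estimates are flagged, not
  errored, because $\hat{\mathbf{G}}$ on the boundary is a legitimate ML
  solution. Non-convergence at $q = 0$ is an error carrying the optimizer
  diagnostics.

Wald inference uses normal quantiles (1.96 for 95% intervals) rather than
a degrees-of-freedom correction: the intended use is cohort-scale $n$
where the difference is negligible.

## Predicted scores, contrasts, FDR

`predict_score()` evaluates $\hat y(g, a) = r'\hat\beta$ where $r$ is the
fixed-design row for group $g$ at age $a$ with covariates at a declared
profile (continuous covariates at 0 on their Z-scale, categorical at
reference). `contrast_scores()` compares two groups at one age via
$L = r_a - r_b$: the score is linear in $\beta$, so the delta method is
exact here, and the implementation asserts at run time that the contrast
equals the difference of the two predictions. Tests additionally require
agreement with a 2,000-draw parametric bootstrap
($\beta^* \sim N(\hat\beta, V)$) within 5% on the standard error.

FDR adjustment is Benjamini–Hochberg, applied *within one contrast pair
across the age grid*, so the family size equals the grid length (7 for
the youth grid 10, 13, 16, 19, 22, 25, 28; 5 for the mid-life grid 40–80
by decade). That matches the convention of counting one test per time
point per comparison. Pooling all pairs into one family is available by
flag but off by default, since the per-pair family is the declared one.

**Standardised differences.** To compare cohorts measured on different
instruments, differences are also reported on a Z-score scale. The exact
transformation used in the original analyses is described in material not
available here, so the package operationalises it as
*refit-on-standardised-outcome*: Z-score the score over all person-wave
observations, refit the identical model, recompute contrasts (`z_std`).
For a linear model this coincides, up to fitting tolerance, with dividing
raw differences by the outcome SD — a property the tests verify — and the
operation is isolated behind `standardize_contrasts()` so an alternative
definition can be swapped in.

## The synthetic-cohort generator

`simulate_cohort()` draws, in a fixed and documented order (covariates,
biomarkers, wave ages, random effects, residuals, missingness — so seeds
are stable across versions): baseline covariates; log-scale IL-6 and CRP
with configurable correlation; jittered, monotone wave ages truncated at
the centering age; random effects from $\mathbf{G}$; and latent scores
from the polynomial model. Two profile constructors encode the study
conditions:

* `alspac_truth()`: 11 waves at target ages 10–28 (jitter SD 0.3 y),
  SMFQ-like bounds 0–26, IL-6 log-normal on a pg/ml scale with meanlog
  −0.21 and sdlog 0.745 (chosen once so the tertile cutoffs fall near the
  published 0.588 and 1.12 pg/ml), CRP log-normal with ≈1–2% of values at
  or above the 10 mg/L exclusion threshold, reference trajectory at the
  published fully adjusted coefficients (intercept 1.1192, quadratic
  0.1355, quartic 0.0003; linear and cubic terms are below printed
  precision and set to 0), top-tertile × linear-age interaction 0.3581,
  random intercept + linear slope $\mathbf{G} = \mathrm{diag}(4, 0.02)$,
  $\sigma^2 = 9$.
* `ukb_truth()`: 8 waves at target ages 40–75 (jitter SD 2 y), PHQ-2-like
  bounds 0–6, IL-6 Gaussian on a log2-type normalised scale (mean 0, SD
  0.713, matching published cutoffs −0.31 and 0.30), quadratic reference
  trajectory (intercept 0.8401), tertile main effects 0.1417 (middle) and
  0.2041 (top) with quadratic-age interactions 0.0002/0.0003,
  $\sigma^2 = 2$, and $\mathbf{G} = \mathrm{diag}(0.8, 0.001)$ — the
  random-intercept SD of ≈0.9 PHQ-2 points is this package's one free
  calibration, chosen once as a realistic between-person spread for a 0–6
  screen.

Scores are *continuous latent values by default*; rounding/clipping to
integer instrument units is a flag. This separates estimator correctness
(exact recovery in the noiseless limit requires the continuous scale)
from instrument discreteness (realism runs). The generator accepts
$\sigma^2 = 0$ precisely so that the noiseless limit is testable.

Missingness mechanisms, all through a logistic link on wave-level
completion: `none`, `mcar` (base retention only), `mar_baseline`
(additive log-odds shift per IL-6 tertile — exposure-dependent attrition,
which FIML tolerates), and `mnar_score` (log-odds shift per latent-score
unit — the stress case). The tests demonstrate all three behaviours:
MCAR deletion leaves coefficients within combined sampling error;
`mnar_score` with high scorers dropping out biases the recovered
trajectory downward; `mar_baseline` produces a detectable negative
association between top tertile and completed-wave count.

**What passing tests do not show.** The generator draws covariates
independently of IL-6, uses a single biomarker law per cohort, has no
secular trends, no measurement error in IL-6, no item-level structure in
the instruments, and its missingness follows exactly one mechanism at a
time. Recovery on these cohorts demonstrates that the estimator and
contrast machinery are correct under the stated model; it says nothing
about confounding, assay differences, or mixed missingness mechanisms in
real cohorts.

## Preparation rules and degenerate inputs

Exclusions run in a fixed, logged order: CRP ≥ 10 mg/L (inclusive
boundary; missing CRP retained and flagged by default, droppable by
flag), then optional flag-based exclusions, then the ≥ *k* assessments
rule (default *k* = 1). Tertiles are computed *after* exclusions, on the
included sample, using type-7 empirical quantiles at 1/3 and 2/3 (the
quantile estimator is configurable since the convention is rarely
stated); ties at a cutoff deterministically go to the upper group
(boundaries half-open below). Covariate transforms add log-BMI and
Z-scale continuous covariates over included persons; zero-variance
columns are emitted as all-zero with a warning rather than NaN, and
non-positive BMI rows are flagged invalid and excluded from scaling.
Categorical covariates are dummy-coded against declared reference levels
(male; never-smoker; low SES) rather than alphabetical defaults, so the
fitted intercept refers to the conventional baseline person — with
alphabetical references the intercept silently absorbs covariate main
effects, which the recovery tests caught during development.

Sensitivity re-runs recompute tertiles on each retained subsample by
default (each run is then self-contained); freezing the main-run cutoffs
is available by flag, since it is genuinely unclear which convention a
given analysis used. The inverse normal transform uses average ranks for
ties and the Blom offset 3/8; its own three-point closed form
(−0.8694, 0, 0.8694) fixes the definition as the *unscaled* transform,
with Z-scaling applied afterwards by the continuous-exposure model.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to make the statistical
assertions sharp while keeping the suite fast: parameter recovery at the
full study scale (5,000 persons × 11 waves, quartic; 10,000 × 8,
quadratic); BIC selection consistency over 20 replicates of a 5,000 ×
6-wave quadratic truth against candidates 1–3; the false-positive check
over 20 planted-null end-to-end runs at n = 2,000; missingness behaviour
at n = 2,000 (MCAR/MNAR) and n = 20,000 (attrition regression); and the
FDR implementation against a brute-force step-up oracle on 1,000 random
p-vectors.

## Known limitations

Non-Gaussian outcomes (ordinal or count likelihoods), autocorrelated
residuals, Bayesian estimation, covariate imputation, and harmonisation
of real assay scales are out of scope. The bounded instruments are
modelled as Gaussian, so predicted scores near the floor can be biased in
cohorts whose scores pile up at 0 — visible in realism runs with rounding
and clipping enabled. Standardised differences depend on the
refit-on-standardised-outcome operationalisation described above.
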