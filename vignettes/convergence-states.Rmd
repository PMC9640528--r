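---
title: "Convergence states: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergence states: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

This package quantifies the *convergence* of multivoxel activation states:
the idea that trials conducive to successful encoding occupy a compact
region of neural state space, so that a trial's proximity to a prototypical
state — its **pattern typicality** — is a meaningful per-trial brain
measure. Each trial's activation pattern over the $V$ voxels of a region of
interest is a point in $\mathbb{R}^V$. Distances are **correlation
distance**, $d(x, y) = 1 - r_{xy}$ with $r$ the Pearson correlation:
invariant to each pattern's additive offset and positive scale, ranging
over $[0, 2]$.

The prototypical state is a **centroid** estimated with leave-one-run-out
cross-validation: for each scanner run $r$, a centroid is computed from the
trials of all other runs, and every trial of run $r$ is scored by its
correlation distance to that held-out-fold centroid
(`loro_typicality()`). No trial contributes to the centroid it is scored
against, which also insulates the score from within-run temporal
autocorrelation. Shorter distance = higher typicality = greater
convergence.

Two centroid estimators are provided (`compute_centroid()`):

* `kmeans_mean` (default) — the mean of row-standardized patterns. With a
  single cluster this is the closed-form $k{=}1$ k-means solution under
  correlation geometry, so the statistic is fully deterministic; no
  stochastic initialization exists to seed.
* `medoid` — the member pattern minimizing summed correlation distance to
  all patterns, the literal "point with the shortest distance to all other
  points".

The two estimators agree on compact clouds and diverge on pathological
geometries (two antipodal clusters: the mean collapses toward the
orthogonal complement while the medoid stays inside one cluster); the
regression tests pin down this divergence case. Rows are standardized
before averaging because k-means under correlation distance operates on
standardized vectors; the medoid needs no standardization beyond what the
distance already ignores.

Inference uses the **raw** distance; the within-subject z-scored variant
(`zscore_within_subject()`) is used for outlier flagging
(`flag_outliers()`, default threshold 3 within-subject SD — the threshold
is a configurable choice, as no canonical value exists) and for
visualization.

## Trial-level estimates

In BOLD mode, per-trial patterns come from a **least-squares-all** GLM
(`build_lsa_design()`, `fit_lsa()`): every (trial, interval) event is a
separate regressor — the question/anticipation epoch and the answer epoch
of each trial — convolved with a canonical double-gamma HRF (peak 6 s,
undershoot 16 s, ratio 1/6, no derivatives), plus nuisance columns and an
intercept. With the default study design (144 trials, 2 intervals) this is
288 task regressors per subject, fit per run with estimates concatenated
across runs. t-values use the voxel's pooled residual variance with
degrees of freedom computed from the matrix rank (not the column count),
and are mapped to z-values via the two-sided p (`t_to_z()`), evaluated in
log space so large |t| never overflows.

The **question-epoch** choice is genuinely open: the anticipatory analyses
target the interval between question onset and answer onset, so the
default regressor spans that whole epoch; `"stim"` (question presentation
only) and `"impulse"` are configurable alternatives. Nuisance regressors
are accepted as an arbitrary per-run matrix — motion and physiological
models are upstream concerns.

A numerical note: each regressor is evaluated as the difference of the
HRF's running integral at the event's two edges (trapezoid quadrature on a
50 ms grid), which is algebraically the boxcar convolution but costs
O(timepoints) per event. The synthetic BOLD generator uses the same
construction, so with zero noise the LSA fit returns planted amplitudes to
numerical precision — the basis of the GLM oracle tests.

## Linking models

* `fit_condition_effect()` — linear mixed model of a trial-level response
  on condition (reference level "low", so the coefficient is the
  high-minus-low shift), subject random intercepts, Satterthwaite degrees
  of freedom.
* `fit_memory_model()` — mixed-effects logistic regression of trial-level
  recall on all supplied brain measures jointly, subject random
  intercepts, Wald tests. Complete separation is detected and reported
  with the offending predictor named.
* Random slopes follow the selection policy: attempted for the focal
  predictor, retained when a likelihood-ratio test (`lrt_select()`)
  prefers them at p < 0.05.
* `mediate()` — product-of-coefficients decomposition of the modulator →
  memory path through typicality. The mediator model is linear, the
  outcome model logistic; `indirect = a b`, `total = direct + indirect`
  (an approximation on the log-odds scale, as usual for logistic
  outcomes), `prop_mediated = indirect / total`. Uncertainty comes from a
  nonparametric bootstrap that resamples **whole subjects** with
  replacement — the cluster carries the within-subject dependence, so the
  per-replicate refits are plain lm/glm — with percentile intervals,
  default 5000 replicates, fully seeded. This is a transparent, seedable
  stand-in for quasi-Bayesian mediation machinery; at the double null
  (both paths zero) any product-of-coefficients test is conservative, a
  known property verified (not hidden) by the calibration suite, which
  additionally checks that the test attains its nominal size on the null
  boundary where only the treatment → mediator path is zero.
* `subject_correlation()` — between-subject Pearson r with Fisher-z CI.

## The permutation-null map

`convergence_map()` correlates a per-trial series (hippocampal typicality)
with every voxel of a grid, controlling a covariate (the modulatory
univariate signal) by residualizing both sides. Each voxel's null is built
from permutations of the typicality series' **trial order within subject**
— the minimal exchangeable null for a trialwise correlation, breaking the
pairing while preserving both marginals — with the covariate
residualization re-applied inside every permutation so the null matches
the observed statistic. The null's 95th-percentile r is subtracted per
voxel, leaving positive values only where the observed correlation beats
its own null; a one-sample t across subjects with family-wise error
control (Bonferroni by default; a max-statistic sign-flip option) gives
the group map. Permutations are shared across voxels within a subject
(vectorized and variance-reducing); 500 permutations is the default.

## What the generator emulates

`cohort_spec()` defaults encode the study design: 23 subjects, 6 runs, 12
high- + 12 low-curiosity trials per run, 4 s questions, 9 s or 13 s
anticipation delays, 1 s answers, a 1–20 s uniform inter-trial interval
standing in for the active-baseline task, TR 2 s. Memory intercepts are
the logits of recall rates 0.63 (high) and 0.40 (low), so with zero slopes
the marginal rates match those values.

Hidden ground truth per trial: a standard-normal **latent modulator**
(VTA-like drive) and a **latent eccentricity**

$$ e = \max\!\big(0,\; b_0 + \beta_c\,[\text{cond}=\text{high}] +
\beta_m\, m + \varepsilon\big), $$

with defaults $b_0 = 0.5$, $\beta_c = -0.02$, $\beta_m = -0.05$,
$\varepsilon \sim N(0, 0.15^2)$. Patterns are planted **exactly at** their
eccentricity: each trial sits at correlation distance $e$ from the
subject's prototype, displaced along a trial-unique direction orthogonal
to the prototype, plus i.i.d. voxel noise (sd 0.02 against a unit-norm
signal). This makes distance-from-centroid an identifiable ground truth —
the measured distance is $e$ up to centroid estimation error. The
modulator ROI is generated differently: the modulator enters as a
spatially uniform amplitude on a centered prototype, so the ROI mean
observes the modulator plus only measurement noise (no subject-level
amplitude offset). Recall is Bernoulli with log-odds linear in condition
intercept, eccentricity (default −0.6 per distance unit) and modulator
(default +0.1).

Calibration of the open magnitudes was a one-time design decision: the
eccentricity noise (0.15) dominates the planted condition shift by an
order of magnitude, mirroring a study in which the condition effect on
distance is small (order 0.02) while the typicality–memory association is
clearly detectable; at 3,312 trials the planted memory slope then carries
|z| ≈ 2.3, comparable detectability to the reported effect. The base
distance 0.5 keeps the truncation at zero negligible.

What the generator does **not** emulate: spatial autocorrelation and
anatomical structure, physiological noise and scanner drift, action
contingency and catch trials, subject-level heterogeneity in the planted
slopes or in recall propensity (per-subject recall rates vary only
binomially around the condition intercepts, so group-level statistics on
the behavioural contrast run larger than in real cohorts), and any
temporal dynamics of the state within a trial. Passing
tests therefore certify the estimators and their calibration under the
assumed generative geometry — not robustness to realistic fMRI artifacts,
which are upstream preprocessing concerns.

## Pipeline and determinism

`run_pipeline()` executes simulate → (BOLD + trial GLM) → convergence →
univariate → models → (permutation map) and writes every table, a results
JSON and a manifest with MD5 checksums. Every stage derives its seed from
the top-level seed via a stable arithmetic hash of the stage name
(`child_seed()`), so adding a stage never perturbs another stage's random
stream, and identical configurations reproduce byte-identical outputs.

In synthetic BOLD mode the convergence stage consumes LSA **betas** by
default (`glm$value_type`): planted amplitudes are the estimand there, and
with zero BOLD noise the residual variance is zero so t/z are undefined;
z-valued maps are the natural choice for real data, where per-voxel noise
differs. The linking models in the recovery suite include condition as a
covariate, matching the generative model (condition shifts both the recall
intercept and the distance), which removes the omitted-variable bias a
brain-measures-only memory model would absorb.

## Problem sizes used by the validation suite

The test suite and acceptance checks choose sizes that keep the full run
in the tens of minutes on one CPU while preserving the regimes that
matter: oracle-equivalence checks run at up to 200 trials × 500 voxels
(100 random instances); GLM recovery at the full design (23 × 6 × 24
trials, 300 voxels, noiseless); parameter recovery on 50 cohorts at
default settings; type-I calibration on 200 null cohorts with reduced ROI
sizes (60 + 10 voxels — voxel count affects only measurement noise, not
test size); mediation bootstraps at 99–199 replicates inside those loops
(5000 remains the analysis default); the permutation map at 2,000 voxels
and 500 permutations.

## Known limitations

* The mediation decomposition on the log-odds scale is approximate for
  logistic outcomes; `prop_mediated` is reported with a stability warning
  whenever the total effect's CI covers zero.
* Wald tests for the mixed logistic model are asymptotic in the number of
  trials; with very few subjects and predictors dominated by
  between-subject variance they can run slightly liberal.
* The k-means-mean centroid assumes a unimodal state cloud; multi-cluster
  state discovery (k > 1) is out of scope, and the medoid option is the
  guard rail for grossly non-convex geometries.
* Bonferroni FWE is exact but conservative for smooth volumetric data;
  the max-statistic permutation option is the sharper alternative at desk
  scale. Random-field corrections are not implemented.
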