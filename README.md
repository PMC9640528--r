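# typicality

Convergence-state (pattern typicality) analysis for trial-level fMRI.

## The problem

When people anticipate information they are motivated to learn, encoding
tends to succeed — and one account of why is that anticipatory brain
states *converge*: trials that lead to successful memory occupy a compact
region of multivoxel state space. This package implements that analysis
for curiosity/anticipation designs: it quantifies, per trial, how close a
region's activation pattern is to a prototypical state, and links that
typicality to a modulatory univariate signal (midbrain VTA activation) and
to trial-level memory outcomes.

It is written for cognitive-neuroscience analysts who have preprocessed
BOLD runs, ROI masks and event tables (or who want a fully synthetic,
seeded test bed with planted effects — the default mode, no data
required).

## The statistic

A trial's pattern over the $V$ voxels of an ROI is a point in
$\mathbb{R}^V$. With correlation distance $d(x,y) = 1 - r_{xy}$, the
prototypical state is a centroid estimated by leave-one-run-out
cross-validation — for run $r$, the $k{=}1$ k-means centroid (mean of
row-standardized patterns; a medoid option exists) of all other runs'
trials — and the trial's **pattern typicality** is

$$ d_i \;=\; 1 - \mathrm{corr}\!\left(x_i,\; c_{-\,\mathrm{run}(i)}\right)
\in [0, 2], $$

shorter distance = higher typicality = greater convergence. Downstream:
linear mixed models for condition and modulator effects on $d$,
mixed-effects logistic regression of recall on $d$ (all ROIs jointly),
likelihood-ratio model comparison, subject-bootstrap mediation of the
modulator → memory path through $d$, and a voxelwise correlation map in
which each voxel's permutation-null 95th-percentile r is subtracted before
a group one-sample t with family-wise error control.

Trial-level patterns come either directly from the synthetic generator or
from a least-squares-all GLM (one regressor per trial and interval,
canonical double-gamma HRF, t→z conversion).

## Worked example

```r
library(typicality)

spec <- cohort_spec(seed = 1)      # 23 subjects, 6 runs, 24 trials/run
coh  <- simulate_cohort(spec)      # trial table + planted multivoxel patterns

typ <- compute_typicality(coh$patterns, coh$trials, rois = "HPC")
m   <- join_features(compute_roi_means(coh$patterns, coh$trials),
                     typ, coh$trials)

tidy(fit_condition_effect(m, "dist_HPC"))
#> # A tibble: 2 x 8
#>   term          estimate      se    df statistic  p_value conf_low conf_high
#>   <chr>            <dbl>   <dbl> <dbl>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 (Intercept)     0.529  0.00363 3310.    146.   0          0.522    0.536
#> 2 conditionhigh  -0.0193 0.00513 3310.     -3.76 0.000173  -0.0293  -0.00923
```

The `conditionhigh` row is the high-minus-low shift in correlation
distance: negative, so high-curiosity anticipation is closer to the
prototypical state (planted truth −0.02). Continuing:

```r
tidy(fit_lmm(m, "dist_HPC", "mean_VTA"))      # modulator -> typicality
tidy(fit_memory_model(m, c("dist_HPC", "mean_VTA")))  # typicality -> recall
mediate(m, "mean_VTA", "dist_HPC", n_boot = 5000, seed = 1)
autoplot(typ, coh$trials)                     # distances by condition
```

`run_pipeline(pipeline_config(seed = 1), "out/")` executes the whole
chain — simulate, (optional BOLD synthesis + trial GLM), convergence
scoring, univariate summaries, linking models, permutation map — writing
every table plus a results JSON and an MD5-checksummed manifest;
identical config + seed reproduce byte-identical outputs.

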