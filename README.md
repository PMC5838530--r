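# rtnf — real-time fMRI neurofeedback simulation and analysis

`rtnf` is an R toolkit for building and validating closed-loop real-time
fMRI neurofeedback pipelines of the kind used in proof-of-concept trials
with Huntington's disease gene carriers, where patients learn to upregulate
their supplementary motor area while watching a thermometer bar. It is aimed
at methods developers and analysts who need the full training computation
and its downstream statistics as tested, reusable code that runs end to end
on synthetic data with known ground truth.

## What it computes

**Feedback signal.** During each 30 s upregulation block the displayed bar
reflects the target-ROI percent signal change against a hemodynamically
weighted baseline from the preceding 30 s baseline block:

    PSC_t = 100 * (x_t - b) / b,     b = sum_i w_i * x_i

with weights `w` proportional to the double-gamma HRF sampled across the
baseline block (negative lobes floored, normalized to sum to 1); 16 s
response blocks between upregulation and baseline are never used. Only
increases are shown: bar height is `clip(PSC, 0, S)/S`, and the scale `S`
is *shaped* after every upregulation block to that block's maximum displayed
PSC (floored at a minimum), so reward difficulty tracks recent performance.

**ROI definition.** Localizer GLM (fist clenching vs rest), strict `t > 3`
thresholding within an anatomical mask, per-visit redraw, and group-level
inclusive-OR union masks; 6 mm sphere seeds for connectivity.

**Offline inference.** Motion scrubbing (spike regressors above 1 mm
scan-to-scan displacement, run exclusion above 2 mm), voxelwise block
contrasts, linear mixed-effects visit trends (random subject intercept,
REML, Satterthwaite tests via `lmerTest`), PPI connectivity terms
(centered product, no deconvolution), and voxelwise behaviour regression
with 26-connected cluster reporting.

**Clinical scores.** CAP = `100 * Age * (CAG - 30) / 627`, the
seven-measure direction-harmonized composite score standardized against
reference norms, quantitative-motor tapping measures, and (partial)
Spearman correlations.

**Synthetic data.** Cohorts with Table-1-like covariates (Gaussian-copula
caudate–CAP rank correlation), paced tap sequences, and 4-D BOLD runs with
planted upregulation amplitude that grows across visits, AR(1) noise,
drift, and plantable motion spikes — every run paired with its ground
truth.

## Worked example

Simulate a visit-2 training run (planted amplitude 0.8 % + 0.4 %/visit,
AR(1) noise), run the closed-loop engine, then estimate the offline
contrast:

```r
library(rtnf)

grid  <- acquisition_grid(c(12, 12, 8))
truth <- simulation_truth(central_roi(grid, c(2, 2, 1)),
                          base_amplitude = 0.8, learning_slope = 0.4,
                          ar_coefficient = 0.3, noise_sd = 1)
run <- simulate_run(truth, visit = 2, grid = grid, seed = 7)
fb  <- run_feedback(run, truth$roi_mask)
round(fb$blocks, 3)
#>   block scale_used max_psc baseline
#> 1     3      1.000   1.476  100.077
#> 2     6      1.476   1.133  100.628
#> 3     9      1.133   1.349  100.700
#> 4    12      1.349   1.180  100.842
#> 5    15      1.180   1.182  101.065
```

Each row is one upregulation block: the thermometer scale it was displayed
at, the maximum PSC the participant achieved (which becomes the next
block's scale — note block 2's scale is block 1's maximum), and the
HRF-weighted baseline it was measured against. The offline GLM recovers the
planted amplitude (visit 2 ⇒ 1.2 % true, estimated on the HRF-integral
regressor scale):

```r
bc <- block_contrast(run, truth$roi_mask,
                     nuisance = cbind(run$motion,
                                      spike_regressors(run$motion)$columns))
bc$roi
#> [1] 1.434
```

Clinical utilities work straight off the packaged 10-participant cohort
table:

```r
tab <- hd_cohort()
round(cap_score(tab$age[1], tab$cag[1]), 2)        # 109.73 -> prints as 110
round(spearman_rho(tab$caudate_pct_icv, tab$tms), 2)  # -0.77
```

A full synthetic study — cohort, per-visit localizers, feedback runs,
offline contrasts, trend/PPI/behaviour models, composite change — is one
call: `replay_study(study_config(seed = 1))`. A miniature on-disk dataset
(NIfTI + events/motion TSV + cohort CSV + truth JSON) comes from
`make_fixtures(dir)`, and `inst/cli/rtnf-cli.R` exposes `fixtures`,
`replay` and `feedback` subcommands for shell use.

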