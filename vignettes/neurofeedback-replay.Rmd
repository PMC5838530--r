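---
title: "Closed-loop neurofeedback training: models, engine and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop neurofeedback training: models, engine and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnf)
```

## The problem this package addresses

In real-time fMRI neurofeedback training, a participant lies in the scanner
and watches a thermometer bar whose height reflects the current activity of a
target brain region — here the (pre-)supplementary motor area of Huntington's
disease gene carriers, localized per visit with a fist-clenching task. The
participant's job is to drive the bar up using motor imagery; the computer's
job is to turn a noisy 4-D image stream into an honest, motivating bar height
in real time. `rtnf` implements that computation and the offline analyses
that establish whether training worked, and wraps both in a synthetic-data
generator with recorded ground truth so every stage can be validated without
any patient data.

## The feedback model

A neurofeedback run is a fixed block design: 6 baseline blocks (30 s), 6
response blocks (16 s), and 5 upregulation blocks (30 s), interleaved as
repeating baseline–response–upregulation triplets closed by a final
baseline–response pair (426 s at TR = 1 s). The response blocks give the
hemodynamic response time to return to baseline before the next upregulation
block; their samples are never used in any feedback computation.

During an upregulation block the displayed quantity is the percent signal
change (PSC) of the target-ROI mean signal $x_t$ against a baseline $b$
estimated from the *preceding* baseline block:

$$\mathrm{PSC}_t = 100 \cdot \frac{x_t - b}{b}, \qquad
  b = \sum_{i=1}^{30} w_i\, x_{t_i},$$

where the $t_i$ index the baseline-block volumes and the weights $w_i$ are
the hemodynamic response function (HRF) sampled at the time since block
onset, floored at zero and normalized to sum to one. The HRF is the standard
double-gamma form — a gamma density peaking near 5 s minus 1/6 of a gamma
density peaking near 15 s. Weighting the baseline this way emphasizes the
part of the baseline block where the previous block's response has washed
out and the control-condition response is fully developed, instead of
averaging the block uniformly.

Two details of the baseline weighting were genuinely open and are settable:

* whether the weights follow the HRF itself or the block-convolved response
  (`baseline_weights(method = "hrf")`, the default, vs `"convolved"`); and
* negative HRF lobes are floored at zero so the baseline stays a convex
  combination of observed samples — a weighted *average* — rather than an
  extrapolation.

### Shaping

The thermometer maximum (the "scale" $S$, in PSC %) adapts to performance:
after each upregulation block, $S \leftarrow \max(\text{max PSC of that
block}, \varepsilon)$. A weak block lowers the bar so small improvements
look large; a strong block demands a higher PSC for the same bar height.
Only increases are displayed: the bar height is
$\mathrm{clip}(\mathrm{PSC}, 0, S)/S$. Before any history exists the scale
is $S_0$ (default 1 % PSC), and $\varepsilon$ (default 0.1 %) keeps the
scale positive after an all-decrease block. Both are configuration values:
the protocol needs *some* first-block scale and an all-decrease block would
otherwise produce a nonpositive, undefined scale.

The bar updates on average every 1.5 s. With data arriving once per second,
this is realized as alternating 1 s / 2 s gaps — exactly 20 display samples
per 30 s block — and the shaping maximum is taken over the *displayed*
samples, since that is the quantity that shaped the participant's behaviour.
A PSC above the current scale saturates the bar mid-block.

```{r engine-demo}
run <- simulate_run(
  simulation_truth(central_roi(acquisition_grid(c(6, 6, 4)), c(1, 1, 1)),
                   base_amplitude = 1, learning_slope = 0,
                   ar_coefficient = 0, noise_sd = 0, drift_slope = 0),
  grid = acquisition_grid(c(6, 6, 4)), seed = 1)
fb <- run_feedback(run, run$truth$roi_mask)
fb$blocks
```

Even in this noise-free 1 %-amplitude run the recovered block maxima are not
exactly 1: the first upregulation block overshoots (the convolved response
transiently exceeds its plateau before the undershoot settles), and later
baselines are slightly inflated by the tail of the preceding upregulation
block, which the engine — like the original protocol — cannot avoid, because
the baseline block directly follows an upregulation block. The tests check
the engine against an independent convolution oracle that reproduces both
effects.

## ROI selection and offline inference

The target ROI is redrawn each visit by thresholding the localizer GLM
t-map at t > 3 (strictly: "greater than" excludes boundary voxels) within an
anatomical constraint. Analyses use the group mask — the inclusive-OR union
of all individual masks (`union_mask`, threshold 1) — so that visit-to-visit
changes in ROI size do not masquerade as activation changes. On synthetic
common-grid data the original normalize-and-smooth step before the union
reduces to the union itself; this is a simplification of the registration
chain, not of the union rule.

Offline, each run is fit with a voxelwise GLM (HRF-convolved task
regressors, intercept, linear drift, six motion parameters and one-hot spike
regressors for volumes whose scan-to-scan displacement exceeds 1 mm), and
the upregulation-versus-baseline contrast is averaged over the group mask.
The displacement metric is the maximum over the six realignment parameters
of the absolute frame difference, rotations converted to mm on a 50 mm head
radius — chosen for auditability; the original artifact-detection tool's
exact formula is not public, so the metric is documented rather than
asserted as identical. Runs with any displacement above 2 mm are excluded.

Learning is tested with a linear mixed model: ROI contrast on visit and run
(fixed), subject (random intercept), age and caudate volume (%ICV) as
confounds, REML estimation, Satterthwaite degrees of freedom for the Wald
test on the visit slope (`lmerTest`). A constant response degenerates the
variance decomposition and falls back to the fixed-effects fit. Connectivity
change uses psychophysiological interaction (PPI) terms: the seed series
mean-centered, the condition regressor HRF-convolved and centered, and their
elementwise product — no deconvolution, matching the stated construction of
the interaction as a product of the condition and time-series regressors.
Behavioural relevance is assessed by voxelwise regression of
activation-change maps on composite-score change (age and caudate %ICV as
confounds), thresholded at voxel p < .001 and reported as 26-connected
cluster sizes. Random-field family-wise correction is out of scope; an
optional max-cluster-size permutation null (`n_perm`) provides a
self-contained alternative.

## Clinical scores

The CAP disease-burden score is $100 \cdot \mathrm{Age} \cdot
(\mathrm{CAG} - 30)/627$, kept exact internally and rounded only for
display. Note the packaged cohort table's printed CAP values for
participants 3, 6, 8 and 9 do not reproduce from their integer ages —
consistent with fractional ages having been used for the printed table —
so exact-value tests pin only the participants that reproduce.

The composite score averages seven z-standardized measures — Stroop word
reading, SDMT, log annulus length of indirect circle tracing, negative
emotion recognition, and three speeded/paced tapping timing measures —
after harmonizing directions so larger is always better (the three timing
measures are negated; variability measures are log-transformed first).
Standardization uses reference norms from an independent sample;
`example_norms()` is a synthetic stand-in with that structure, since no such
reference table is distributable with this package. The mid-tap-interval
deviation measure is defined here as the offset of each inter-tap midpoint
from the nearest target-grid midpoint (grid anchored at the first onset);
the original operational definition is not public, so the formula is
isolated in `tapping_measures()` where an alternative can be swapped in.

## What the synthetic data emulate — and what they do not

`simulate_run` plants, on a flat 100-unit baseline (so PSC is directly
interpretable): a plateau-normalized HRF-convolved upregulation response of
amplitude $a_0 + g(v-1)$ PSC % at visit $v$; AR(1) noise (innovation SD
$\sigma$, coefficient $\varphi$); linear drift; and a motion table with
plantable step spikes. The learning rate $g$ is a free per-subject parameter
rather than a population model, because between-participant variability in
learning is real but its distribution is unknown. `simulate_cohort` draws
ages and CAG repeats uniformly, derives CAP, and induces the negative
caudate-CAP rank correlation through a Gaussian copula (the latent Pearson
correlation is $2\sin(\pi\rho_s/6)$ so the requested Spearman value is
matched); the seven measures are linear in caudate %ICV plus noise, with
signs chosen so healthier caudate means better performance.

Not emulated: anatomy and registration (all data share one grid),
susceptibility and slice-timing effects, physiological noise waveforms, and
any model of the participant's learning *process* (the amplitude schedule is
imposed, not emergent). Passing tests therefore certify the computational
chain — not that the method would behave identically on real scanner data
with registration error and structured physiological noise.

## Numerical and scale choices

* HRF support is sampled to 32 s at TR resolution; block designs are
  convolved discretely at TR = 1 s with no microtime upsampling, which is
  adequate for 16–30 s blocks.
* Baseline weights error out if all raw weights are zero; PSC errors on a
  nonpositive baseline; log transforms guard nonpositive inputs; Spearman
  utilities error on constant input rather than returning NA.
* Default simulation scale: grids of 24×24×16 (generator default) down to
  8×8×6 (study replay default), 5 participants × 3 visits × 3 runs per
  replay, chosen so a full replay runs in seconds on a laptop while leaving
  every statistical property intact; all sizes are configurable up to and
  beyond the original 64×64×60 acquisition.
* The study replay derives per-stage seeds from one global seed, so an
  entire replayed study is a pure function of its configuration.
* The replay's behaviour-regression stage needs at least 5 participants
  (intercept + composite + two confounds leave no residual degrees of
  freedom below that); smaller replays record the stage as skipped.

## Known limitations

The engine consumes already-reconstructed volumes; real-time motion
correction and incremental GLMs of the original acquisition software are out
of scope. Family-wise error control for cluster inference is not
implemented. The composite's reference norms and the exact Q-Motor
operational definitions are conventions documented above, not reproductions
of the originals.
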