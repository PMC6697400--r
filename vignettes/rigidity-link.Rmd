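---
title: "Linking perceptual stability to cognitive rigidity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking perceptual stability to cognitive rigidity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexlink)
```

## Scientific background

Two superficially unrelated laboratory behaviors are unusually stable
within a person. First, viewing an ambiguous structure-from-motion
stimulus produces spontaneous alternations between two percepts, and the
typical dwell time of a percept (seconds to tens of seconds) is an
individual trait. Second, when observers freely choose on every trial
which of two tasks to perform — here, find the designated shape or find
the brightest figure — they alternate spontaneously between tasks, and
the typical length of a run of task repetitions is again an individual
trait. Both can be read as expressions of a single disposition: how
strongly the current perceptual or cognitive state resists replacement.

This package implements the analysis chain for studies asking three
questions about that disposition in autism spectrum disorder (ASD):

1. Are percept durations and task repetition runs longer in ASD than in
   matched typically developed (TD) adults, and do the two indices
   correlate across individuals within the ASD group?
2. Is there a brain structural substrate — a region whose gray-matter
   volume (GMV) relates negatively to **both** indices?
3. Does that region's GMV statistically mediate the association between
   the two behavioral indices?

## Behavioral scoring

Percept timelines are streams of button events marking onsets of clear
(`up`/`down`) or mixed percepts. A clear percept lasts from its onset to
the next event; mixed intervals and the final (truncated) percept are
excluded. The subject-level index is the **median** duration within each
run averaged across runs — the median first, because percept durations
are strongly right-skewed.

Task-switching sessions are scored retrospectively: each trial presents
four figures of which exactly one is the designated shape (a circle) and
a distinct one is uniquely brightest, so the chosen figure reveals the
intended task (circle → shape task; brightest → brightness task; anything
else or a timeout → unclassifiable). Repetition run lengths come from
run-length encoding of the classified stream with unclassifiable trials
removed; the subject index is again the per-run median averaged across
runs. Yoked instructed sessions replay the classified spontaneous task
sequence as explicit cues, giving matched accuracy and switch-cost
measurements (spontaneous switch costs are near zero; instructed switch
costs are large — evidence that spontaneous "switches" are not reactive
reconfiguration).

```{r behavior-example}
tl <- data.frame(run_index = 1, onset_s = c(0, 4, 10, 11.5, 20),
                 label = c("up", "down", "mixed", "up", "down"))
percept_durations(tl)          # mixed interval and truncated tail excluded
```

## The momentum random walk

To ask whether spontaneous switching is *more regular than random*, task
choice is modeled as a bounded random walk on a path graph
`A – h1 – … – hk – B`: the walker never stays in place, keeps its
previous direction with probability `p_trans`, and reverses otherwise;
moves from an extreme are forced inward and reset the direction. The two
extremes are the two tasks, hidden states are uncommitted intermediate
states, and an extreme-to-extreme passage corresponds to a task run.
`p_trans = 0.5` is the most random walk; `p_trans → 1` gives a regular
sweep with passage time exactly `n_hidden + 1`.

Two independent routes to the same quantity keep this module honest:
`simulate_walk()` + `passage_durations()` measure passage durations by
simulation, while `expected_passage_time()` solves the linear system of
the direction-augmented chain (states = position × last direction)
exactly. At `(n_hidden = 1, p_trans = 0.5)` the expected passage takes
4.0 steps; at `(1, 0.9)` it takes `2/0.9` steps.

```{r walk-example}
expected_passage_time(walk_spec(1, 0.5))
mean(passage_durations(simulate_walk(walk_spec(1, 0.5, n_steps = 2e4))))
```

Observed run-length distributions are compared to simulated passage-time
distributions after dividing by their mean (shape, not scale, is
informative) on a fixed support of `[0, 5]` mean-units with 25 bins and
the tail folded into the last bin. The divergence is
`D(empirical || simulated)` with `epsilon = 1e-10` smoothing, in nats;
`randomness_grid()` maps it over `p_trans ∈ {0.5, …, 0.9}` ×
`n_hidden ∈ {1, …, 5}`. When the empirical distribution is generated by
a persistence-0.5 process (geometric run lengths), mean KL increases
monotonically with `p_trans` — more regular walks fit random behavior
progressively worse.

## Voxelwise morphometry

`voxelwise_regression()` fits, at every in-mask voxel, OLS of GMV on an
intercept, the behavioral index, and covariates (age and full-scale IQ in
the canonical analysis), entirely vectorized as one matrix product; it
reports the t and two-sided p of the behavioral coefficient.
Multiplicity is controlled by Benjamini–Hochberg FDR (`stats::p.adjust`)
over in-mask voxels at `q = 0.05`. The study's target is the
**conjunction of the two negative maps**: voxels where GMV decreases with
*both* longer percept durations and longer repetition runs. Clusters of
the conjunction are labeled by 26-connectivity breadth-first search with
peak |t| voxel coordinates (0-based indices and volume-centered mm).

## Mediation and the latent model

`mediate()` estimates the indirect effect `alpha * beta` (x → mediator →
y) with a percentile bootstrap over subjects; both regressions are refit
on every resample (closed-form, vectorized across resamples), and the
two-sided p is read off the bootstrap distribution, floored at
`1/n_boot`. `voxelwise_mediation()` repeats this at every voxel with one
shared set of resample indices. `fit_latent_model()` fits a one-factor
measurement model (factor variance fixed at 1) by quasi-Newton
maximization of the Wishart likelihood and reports AGFI, CFI, RMSEA, and
SRMR; with three indicators the model is just-identified (`df = 0`), so
fit is exact and RMSEA is defined as 0.

## The synthetic cohort generator

The generator exists to exercise and validate the pipeline, not to model
the brain. Its default parameters **are** the study design: 22 subjects
per group of high-functioning adults (IQ ≥ 85), matched on age and IQ,
five 90 s bistable-perception runs, five 180 s spontaneous task-switching
runs with yoked instructed sessions.

One latent rigidity trait `z` per subject (TD mean 0, ASD mean 1, SD 1)
drives everything:

* **Percept durations** are gamma distributed (shape 2.5) with scale
  `2.3 * exp(0.35 * u1)`, where `u1` is the subject's perceptual rigidity
  component; short mixed intervals occupy ~1.7 % of run time.
* **Task persistence** is `plogis(qlogis(0.75) + 0.35 * u2)` with `u2`
  the cognitive rigidity component; lapses (1 %) and timeouts (0.2 %)
  produce unclassifiable trials.
* `u1` and `u2` each load on `z` with loading
  `sqrt(trait_behavior_corr / behavior_attenuation)`; the attenuation
  factor (0.85, estimated once from the generating model at large n)
  compensates for finite-run measurement noise so the *realized*
  correlation between the two scored indices matches the target 0.45.
* **Volumes** are a 32³ grid (3 mm voxels) with an ellipsoidal in-brain
  mask, baseline GMV 0.5, and Gaussian-smoothed noise (FWHM 8 mm,
  pre-smoothing SD 0.12) emulating the spatial correlation of
  preprocessed maps. Inside a planted 18 mm-radius sphere, GMV is
  shifted by `-0.08` per SD of the subject's **structural rigidity
  substrate** — the mean of `u1` and `u2`, rescaled to unit within-group
  SD. The substrate tracks both behavioral components directly (not only
  their shared factor) because the modeled claim is that the region
  underlies both behaviors; this is what makes voxel–behavior
  correlations of the size reported in such studies (peak t ≈ 5 at
  n = 22) attainable, which a single-common-factor structure caps at
  `sqrt(0.45) ≈ 0.67`.
* **Clinical scores**: the ordinal restricted-repetitive-behavior (RRB)
  score {0, 1, 2} is a fixed-quantile discretization of `z` in the ASD
  group (probabilities 0.4/0.4/0.2, mean 0.8); social and communication
  scores are independent calibrated draws.

Everything is reproducible: a `cohort_spec` plus its seed determines the
cohort exactly.

### Emulation scope

The generator emulates the *statistical structure* of such a study — group
differences, behavior–behavior correlation, a negative GMV cluster, an
RRB gradient — not psychophysics or neuroanatomy. Percept timelines are
renewal processes without adaptation or serial correlation; task choice
is a two-state persistence process, so run lengths are geometric rather
than subtly over-regular; volumes have stationary noise and a single
spherical effect rather than cortical geometry. Analyses that depend
only on the statistical structure (everything in this package) transfer;
analyses of, e.g., duration autocorrelation would not.

## Numerical choices

* Voxelwise OLS uses one Cholesky-based solve shared across voxels;
  t maps match per-voxel `lm()` references to ~1e-10 relative error.
* The exact first-passage solver builds the full (position × direction)
  system and uses dense `solve()` — at most 14 states, so stability is
  not a concern.
* The bootstrap uses closed-form path estimates vectorized over
  resamples when there are no covariates (an index matrix and row-sums,
  no per-resample `lm`); degenerate resamples (constant x or mediator)
  are redrawn.
* KL smoothing adds `epsilon` to *both* distributions and renormalizes,
  keeping the divergence finite when simulated bins are empty, with bias
  bounded by the epsilon mass.
* The latent model optimizes log-loadings-free parameters with
  `optim(method = "BFGS")` on the ML fit function; residual variances
  are parameterized on the log scale to stay positive, and Heywood cases
  are bounded at 1e-6 and flagged.

## Limitations

* The planted-cluster design gives the pipeline realistic *power*, but
  effect sizes at n = 22 remain variable: individual seeds can produce a
  partial conjunction or a non-significant behavioral group test, just
  as individual studies do.
* The conjunction ROI is selected on the same data used for the ROI
  correlations and mediation that follow; as in the studies this
  pipeline emulates, those follow-up estimates are conditional on
  selection and should be read as descriptive, not as unbiased effect
  sizes.
* The mediation model is directional by assumption; with a shared latent
  cause the indirect effect quantifies association structure, not a
  verified causal path.

## Session information

```{r session}
sessionInfo()
```
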