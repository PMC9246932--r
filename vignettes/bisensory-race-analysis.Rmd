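---
title: "Modelling multisensory reaction times: race models, switch costs and channel dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multisensory reaction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multirace)
```

## The problem

In a speeded bisensory detection task, observers respond to randomly
interleaved auditory (A), visual (V) and audiovisual (AV) stimuli.
Responses to AV stimuli are usually faster than to either component alone
(the redundant signals effect). The central question this package
addresses is *how much* of that speed-up statistical facilitation alone
can explain, and what the residual tells us about multisensory
facilitation, competition between the senses, and the cost of switching
sensory modality from one trial to the next.

All analyses work on whole RT distributions rather than means. Each
condition's RTs are summarised as an empirical CDF evaluated at 20
linearly spaced latencies between shared 2.5th/97.5th percentile cutoffs
("vertical" quantisation). Working with cumulative probabilities rather
than interpolated latencies makes subjects with very different overall
speeds comparable and places no constraint on trial counts per condition.

## Race models, bounds, benefits

Writing `F_A(t)` and `F_V(t)` for the unisensory CDFs, Raab's independent
race model predicts the AV CDF by probability summation,

    F_race(t) = F_A(t) + F_V(t) - F_A(t) F_V(t),

under context invariance (each channel behaves as it does unisensorily)
and channel independence. Two reference bounds bracket the race
prediction: Grice's bound `max(F_A, F_V)` (perfect positive channel
coupling) and Miller's bound `min(F_A + F_V, 1)` (the independence term
dropped; its violation implies integration). The package always retains
the joint-probability term for prediction and exposes Miller's bound only
as a bound.

Because the allocation of processing resources depends partly on the
preceding trial, the default race prediction is *conditioned on preceding
modality*: the race model is computed separately within the three strata
defined by the previous trial's condition (A, V, AV) and the three CDFs
averaged with equal 1/3 weights — the printed form of the estimator, not a
trial-count-weighted average. Degenerate strata (fewer than `min_n = 5`
RTs) fall back to the unconditioned CDF for the affected term, with a
warning.

Three scalar statistics summarise each subject, all areas over the unit
quantile interval computed with the rectangle rule (the arithmetic mean of
the 20 per-quantile differences; the integrals are printed without a
quadrature convention, and on an equally spaced grid the mean rule is
exact for the step functions involved):

* predicted benefit — area between the race CDF and Grice's bound;
* empirical benefit — area between the AV CDF and Grice's bound;
* multisensory gain — area between the AV CDF and the race CDF, equal to
  the sum of its positive and negative parts and, algebraically, to
  empirical minus predicted benefit (asserted to 1e-12 in the tests).

Race-model violation is tested at every quantile with right-tailed
sign-flipping permutation tests on the per-subject difference functions,
family-wise corrected by the permutation distribution of the maximum
statistic.

## Competition (bias) models

To ask whether young observers process AV stimuli competitively rather
than facilitatively, two families of bias models predict the AV CDF from
conditioned unisensory CDFs `F_c(m, t)` (condition `c` preceded by
modality `m`):

* Model 1b — a fixed bias towards modality `b`:
  `F_1b = (1/3) [F_b(A,·) + F_b(V,·) + F_b(AV,·)]`;
* Model 2b — a bias towards the preceding modality, defaulting to `b`
  after an AV trial: `F_2b = (1/3) [F_A(A,·) + F_V(V,·) + F_b(AV,·)]`.

A mixture parameter `p` interpolates between facilitation and
competition: the mixture benefit is the area between
`(1-p) F_race + p F_bias` and Grice's bound, affine in `p` by
construction, evaluated on the grid p = 0, 0.25, ..., 1. Models are
compared within age groups (6-9, 10-12, 13-17, 18-40 years, inclusive
integer ages) by the Pearson correlation between mixture and empirical
benefits across subjects, with two-tailed permutation tests of the
pairing. The pure-bias (`p = 1`) correlations of Models 1A and 1V form
the sensory-dominance profile.

## Modality switch effects

Trials are classed by the preceding trial within the same block: repeats
(A→A, V→V, AV→AV), switches (V→A, A→V, and V/A→AV, with the two
multisensory directions also kept separate), while AV→A and AV→V are
neither. The switch effect is the area between the repeat and switch
CDFs (positive when switching slows responses). The separated A→AV and
V→AV effects can be normalised by the pooled V/A→AV effect; the
normalisation is computed at group level because individual pooled
effects can sit arbitrarily close to zero. A mean-RT variant
(`mean(switch) - mean(repeat)` in ms) supports comparisons with designs
using longer inter-stimulus intervals via an optional restriction on the
preceding ISI. Finally, the full race analysis can be run separately
within switch and repeat partitions; within a partition the
preceding-modality strata are necessarily incomplete, so the race model
falls back to the unconditioned form (flagged per subject).

## Channel dependency: the context-variant race model

The LATER framework treats the reciprocal of RT — a processing rate, here
`1000/RT` in 1/s — as normally distributed. Unisensory channels are fit
by maximum likelihood (sample mean and ML standard deviation of the
rates). The context-variant race model then predicts the AV RT as
`1000 / max(X_A, X_V)` with `(X_A, X_V)` bivariate normal: channel SDs
inflated multiplicatively by `(1 + eta)` and correlated at `rho`. `eta`
captures the extra variability of empirical AV responses (e.g. pooling of
neuronal noise); `rho` the trial-to-trial coupling between channels,
typically negative in adults.

`(rho, eta)` are estimated by maximising the likelihood of the observed
AV RTs with the channel parameters fixed at their unisensory fits. The
density of the max of two correlated normals has the closed form

    f_max(z) = f_A(z) Phi[(z_V - rho z_A)/sqrt(1-rho^2)]
             + f_V(z) Phi[(z_A - rho z_V)/sqrt(1-rho^2)]

(standardised scores `z_A`, `z_V`), which the optimiser uses directly on
the rate scale (the RT-to-rate Jacobian is parameter-free). The
published expression for this density is typographically corrupted in
print, so the implementation is validated against a million-draw
Monte-Carlo oracle (agreement within 0.005 everywhere, asserted in the
tests). The predicted AV *CDF* needs the bivariate normal rectangle
probability, computed by a one-dimensional Gauss-Legendre reduction
(96 nodes; no external dependency). The search is bounded
(`rho` in [-0.95, 0.95], `eta` in [0, 2]) L-BFGS-B from 5 fixed starts,
so fits are deterministic. The multiplicative `sigma' = sigma (1 + eta)`
parameterisation is one defensible reading of "inflated variability"; it
is isolated in a single function so alternatives are swappable.

## Inference layer

* Permutation tests (default 10,000 permutations, add-one p estimator):
  sign-flipping for one-sample/paired, label permutation for two-sample;
  multivariate corrections by max-statistic (FWER) or Benjamini-Hochberg
  (the FDR procedure is not further specified in the source analyses, so
  BH at q = 0.05 is used).
* BCa bootstrap confidence intervals (bias correction from the bootstrap
  distribution, acceleration from the jackknife); reduces to the
  percentile interval when both are zero.
* Hedge's g with the exact small-sample correction factor and BCa CIs.
* JZS Bayes factors (BF01) for t statistics with a Cauchy(0, 1) prior on
  the standardised effect, by numerical integration; regression terms use
  the same construction with the residual degrees of freedom.
* Rank-based inverse normal (rankit) transform with mid-ranks for ties.
* Age-binned similarity matrices (pairwise RMSE, and Pearson correlation
  after a *pooled* RIN transform of all difference-function values) with
  the per-row extremal trace used to diagnose developmental lags. The
  source description of the binning is internally inconsistent (10 bins
  vs 6-21 years by 2.5); the default here is edges 6 to 21 by 2.5 (6
  bins), with `bin_edges` exposed.
* Deterministic participant matching: exact on sex, nearest neighbour on
  standardised (age, PIQ), without replacement, ties broken by lower
  subject id.
* Moving-window group comparisons (default 7-year window, 1-year step)
  with within-window re-matching, BCa CIs, permutation tests
  FDR-corrected across windows, and per-window BF01.
* A mixed-effects model of single-trial RTs: fixed effects contrast-coded
  group, continuous age, condition (AV reference); random by-subject
  intercepts and condition slopes, ISI intercepts, and preceding-modality
  intercepts with condition slopes; maximum likelihood via lme4, p-values
  by Satterthwaite approximation (lmerTest). ISI is a continuous variable
  and cannot index a grouping factor directly, so it is discretised into
  deciles for the random factor (quartiles give materially identical
  fixed effects).
* Mediation (age → switch effect → gain, all z-scored): three
  regressions give the total effect `c`, path `a`, and paths `b`/`c'`;
  the indirect effect `a*b` satisfies `a*b + c' = c` exactly, and its SE
  and p come from a BCa-adjusted bootstrap over subjects. Significant
  `a*b` with significant `c'` is classified as partial mediation.

## The synthetic cohort generator

Every analysis above is exercised end to end on synthetic cohorts, so the
generator is first-class, tested code. It emulates the design and the
statistical structure the analyses assume: three equiprobable conditions
in completely randomised order; ISIs uniform on 1000-3000 ms; 8 blocks of
100 trials by default (the source design reports blocks of ~100 and 6-10
blocks per participant); LATER-style channels whose rates increase with
age; a within-trial channel correlation and multisensory noise inflation;
per-channel switch costs on the rate scale (a channel is penalised when
the preceding trial did not contain its modality — so a unisensory switch
penalises the responding channel, while an AV trial is penalised only on
its "switched" channel, which is what makes switch costs inflate
multisensory gain); optional competition modes in which the AV response
is triggered by a biased channel; misses as absent RTs; and false alarms
as a per-subject count consumed only by accuracy scoring (FA timestamps
never enter RT analyses).

Default parameter choices (all configurable) and their rationale:

* rate means 1.95 (A) and 1.80 (V) 1/s at age 6, +0.045/yr — median RTs
  of roughly 510-530 ms in young children falling towards ~290 ms in
  adults, matching typical detection-task magnitudes;
* rate SD 0.55 1/s; between-subject jitter SD 0.22 on means, 0.08 on SDs;
* a dedicated sensory-dominance jitter (SD 0.25 1/s, added to the A and
  subtracted from the V rate mean per subject): individual differences in
  which modality dominates are a documented feature of this population
  and are what makes the fixed-bias and preceding-modality-bias models
  empirically distinguishable — without it, Models 1b and 2b differ only
  through a single stratum and model recovery is not identifiable;
* channel correlation 0.15 at age 6 falling by 0.012/yr; noise inflation
  0.05 rising by 0.004/yr — the directions the fitted parameters take in
  the empirical cohort;
* switch cost 0.18 1/s (~25-35 ms on unisensory means), optionally
  decaying exponentially with the preceding ISI;
* group effects: ASD rate decrement 0.12 1/s and a +0.25 shift in channel
  correlation below age 18 (deficits that resolve by adulthood); an
  optional developmental age-lag re-parameterises ASD subjects as younger;
* miss rate 5%, FA rate 3%, ages uniform over 6-40, PIQ ~ N(107, 13)
  truncated at 80 so that default cohorts pass the exclusion screen.

Negative rates are removed by rejection sampling on the triggering rate
(negligible mass under the default regime, so the reciprocal stays
defined without distorting the distributions).

What the generator does *not* emulate: the empirical shape of the
deposited data's RT distributions beyond reciprocal-normality, fatigue
and attentional drift within a session, higher-order (n-2, n-3) sequence
effects, age-dependent miss/FA rates, and any neural observable. Passing
tests therefore demonstrate that the estimators recover the structure
they assume, under that structure — not that real data satisfy the
assumptions.

## Numerical conventions and degenerate inputs

* Ties at an evaluation time count as `<= t`, fixing reproducibility.
* Percentile cutoffs use linear interpolation between order statistics
  (R's type 7); RTs exactly at a cutoff are retained.
* Cleaning is a pure flagging pass — rows are never dropped, a validity
  flag and reason column are recomputed from the raw columns — so
  cleaning is exactly idempotent and leaves an audit trail.
* The pooled CDF limits are the extreme per-condition trim cutoffs, so
  they bound the retained data exactly.
* The per-condition percentile trim leaves a small *positive* offset
  (~+0.01 at the defaults) in the null expectation of the gain statistic,
  because trimmed CDFs reach 0 and 1 at their own cutoffs inside the
  pooled limits. This is a property of the trimming procedure itself;
  absolute gains should be read with that in mind, and the generator-level
  null check in the test suite is computed on untrimmed samples.
* Preceding-modality context resets at block boundaries, and trials whose
  predecessor drew no response are excluded from conditioned strata (the
  preceding modality is only defined by an attended, answered trial).
* Permutation p-values use the add-one estimator and can never be zero.
* Constant bootstrap distributions yield zero-width CIs; statistics
  undefined on a resample are redrawn (bounded retries).

## Problem sizes

The test suite and the acceptance script run, by choice, at these scales:
million-draw Monte-Carlo oracles for the race and max-rate CDFs; LATER
recovery at n = 5000; (rho, eta) recovery over 100 replicates of 400 AV
trials; model-selection recovery over 100 cohorts of 40 subjects per
generating mode (five modes); FWER audits over 500 null cohorts of 20
subjects x 20 quantiles; BCa coverage over 1000 replicate datasets; and
cohort-level pattern recovery on cohorts of 90-100 subjects per group.
The bundled analysis scripts use a demonstration cohort of 30 subjects
per group.

## Known limitations

* The conditioned race model and the bias models share strata; with very
  short sessions the AV-preceded strata get thin and fall back to
  unconditioned CDFs, which blunts the distinction between model
  families.
* `eta` and `rho` trade off against each other at small AV counts; the
  reported median absolute errors (about 0.05 and 0.03 at 400 trials) are
  what the fixed-start bounded search achieves under the generator's own
  assumptions.
* The mean-rule AUC differs from trapezoidal quadrature by up to 1/40 of
  the range on 20 points; all statistics use the same rule, so
  comparisons are internally consistent.
* Bias-model evaluation uses correlation across subjects, which is
  invariant to a model's overall offset; a model can fit levels badly and
  still correlate well.
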