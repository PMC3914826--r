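---
title: "Minimum saccadic reaction times and accuracy-matched surrogate inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum saccadic reaction times and accuracy-matched surrogate inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccmask)
```

## The scientific question

When a briefly flashed target is made hard to see — by object-substitution
masking (OSM: four surrounding dots that outlast the target), by a
conventional backward pattern mask, or simply by lowering its contrast —
does the impairment act uniformly in time, or does it spare the very
fastest responses? In a two-alternative saccadic choice task, observers
saccade to the hemifield containing a target among distractors; selective
saccades can be initiated barely more than 100 ms after stimulus onset,
early enough to be driven almost entirely by the first feedforward sweep of
visual processing. If masking interferes mainly with later, reentrant
processing, the fastest saccades should *escape* it; a contrast reduction,
which degrades the input itself, should impair fast and slow responses
alike.

`saccmask` implements the analysis chain that turns per-trial tables
(observer, condition, contrast, saccadic reaction time, correctness) into
that inference, together with a fully synthetic observer/experiment
simulator so every stage can be exercised and validated end to end without
any recordings.

## The statistics

**Minimum SRT.** SRTs are binned into half-open 10-ms bins anchored at
0 ms. In each bin a one-sample chi-square against the 50/50 null,
$\chi^2 = (n_c - n_i)^2/(n_c + n_i)$ with df = 1 and no continuity
correction, asks whether correct saccades significantly outnumber errors.
The minimum SRT is the left edge of the first bin that *begins* a run of at
least 5 consecutive significant bins. Two deliberate conventions: a
directional gate (a bin where errors dominate never counts, whatever its
chi-square), and bins anchored at 0 (the estimate shifts with the anchor,
so the anchor is part of the definition). An undefined minimum SRT — no
qualifying run — is a first-class value, not an error: resampled data sets
legitimately produce it. Both a Yates-corrected variant and a
"run-contains" reading of the criterion are available behind flags.

**Cumulative accuracy time-course.** At each observed SRT $t$, the
proportion correct among all trials with SRT $\le t$. The curve closes on
the overall accuracy at the last time point; points before 110 ms are
computed but flagged not-for-display because they average very few trials.

**The accuracy-matched surrogate null.** The inferential core. For a
low-visibility condition with realized accuracy $a$ and $n$ analyzable
trials, one surrogate draw resamples $n$ SRTs (with replacement) from the
*correct* trials of the high-visibility reference condition and relabels
`round(n(1-a))` of them, chosen uniformly at random, as incorrect. The
relabelling ignores SRT — that independence *is* the null hypothesis of a
time-uniform impairment — while the accuracy match is exact by construction
on every draw. An ensemble (default 500 draws) yields the null distribution
of the minimum SRT and a pointwise 95% band for the accuracy time-course.
An observed minimum SRT below the ensemble's 2.5th percentile is flagged
`escaping`: faster than any time-uniform impairment of equal severity can
explain. Undefined minima order as +∞ (they are the slowest possible
outcome), so an undefined observed minimum is consistent with the null
exactly when the surrogate ensemble itself produces undefined minima at a
compatible rate. Sampling is with replacement because 500 independent draws of the
full correct set without replacement would be identical; the draw size
equals the target condition's analyzable trial count; per-time-point band
exceedance is reported pointwise, without multiplicity correction, with a
max-statistic family-wise variant available but non-canonical.

**Group-level statistics.** Observer-by-condition summaries (accuracy,
median SRT, minimum SRT) enter classical one-way ANOVAs — with 4 observers
and 4 conditions, df = (3, 12) — followed by Tukey HSD pairwise
comparisons; the summaries are treated as independent observations to match
that df convention. A gamma GLM with reciprocal link,
$1/E[\mathrm{SRT}] = b_0 + b_1\,\mathrm{contrast}$, checks on a
single-trial basis that staircase-driven contrast variation does not itself
explain SRT variability (Wald test on $b_1$; Pearson dispersion).

## Preprocessing

The exclusion cascade is fixed and order-documented:

1. **Anticipations**: SRT strictly below 70 ms (an SRT of exactly 70 ms is
   retained).
2. **Slow outliers**: adjusted boxplot fences computed on the
   anticipation-free SRTs. The medcouple MC (a bounded, robust skewness
   measure; exact O(n²) kernel median with the standard tie-handling
   pattern) sets asymmetric fences
   $[Q_1 - 1.5e^{-4MC}\mathrm{IQR},\; Q_3 + 1.5e^{3MC}\mathrm{IQR}]$ for
   $MC \ge 0$ (exponents swap to $(-3, 4)$ for $MC < 0$). Only the upper
   fence excludes trials — the lower tail is already handled by the 70-ms
   rule. Fences are computed per observer × condition, since latency
   distributions differ across observers; quartiles use the
   median-unbiased convention (`type = 8`), which the fence values depend
   on. With MC = 0 everything reduces to Tukey's rule.
3. **Staircase stability**: within each observer × condition cell, trials
   before the staircase's first stable estimate are dropped (below).

The flagged set is invariant to input row order. Saccade detection from
gaze traces (velocity 30°/s, acceleration 8000°/s², displacement 0.15°
thresholds; central differences on a 3-sample smoothed position signal) is
a documented reimplementation of the standard tracker heuristics, validated
only on constructed synthetic traces; SRT is the onset of the first saccade
after stimulus onset.

## The QUEST staircase

Each observer × condition cell runs its own Bayesian staircase over a
200-point grid of log10 threshold contrast spanning the Gaussian prior
mean ± 4 SD. The psychometric family is the Weibull on contrast with guess
rate 0.5 and lapse 0.01 — the canonical QUEST choice; the original study
names the procedure but not the family. Updates multiply the posterior
pointwise by the outcome likelihood (log-domain arithmetic, renormalized
each trial, so posterior order-invariance holds to machine precision).

**Recommendation rule.** The next trial is placed at the contrast where
the *posterior-predictive* psychometric function — the Weibull family
averaged over the threshold posterior — attains the condition's target
proportion (0.82 for common-offset, 0.60 for the three low-visibility
conditions), clamped to the displayable range and solved by bisection on
log contrast. The predictive rule was chosen over the classical plug-in
at the posterior-mean threshold because the posterior predictive is a
calibrated forecast of outcome frequencies at the tested contrasts: when
the assumed family is misspecified — exactly the situation on masked
trials, whose true accuracy-vs-contrast curve is a flattened Weibull
capped well below 1 — the plug-in rule equilibrates measurably above
target (realized ≈ 0.63 for a 0.60 target in simulation), while the
predictive rule holds ≈ 0.61. Both plug-in variants (`"mean"`, `"mode"`)
remain available.

**Stability rule.** "Arrived at a stable estimate" is operationalized as:
the posterior-mean log10 threshold ranged over less than 0.12 log10 units
across the last 40 trials. With 960 trials per cell in the simulated
design, a 100-trial window would by itself forfeit more than 10% of each
cell before any stability criterion was evaluated; 40/0.12 keeps overall
retention near the ~92% empirical scale (≈ 88% in simulation) while still
rejecting the early transient. Both parameters are exposed in the
configuration.

## The synthetic observer

The simulator generates the statistical structure the analysis assumes,
plus ground truth for parameter-recovery tests:

* **Psychometric function**: Weibull, threshold 0.2, slope 3.5, guess 0.5,
  lapse 0.01.
* **SRT sampler**: LATER-style reciprocal-normal — SRT = shift + 1/rate,
  rate ~ truncated normal. Defaults: shift 55 ms; main population rate
  N(1/150, 0.0019) (median ≈ 205 ms); plus a 10% *express-saccade*
  population, rate N(1/75, 0.004) (median ≈ 130 ms). The two-population
  form follows the well-documented bimodality of saccadic latency
  distributions and is what gives the left tail a gradual shoulder: a
  single reciprocal-normal has so sharp a lower edge that the 10-ms bins
  between 110 and 160 ms are either nearly empty or already crowded, and
  the consecutive-bin minimum-SRT statistic then cannot discriminate a
  latency-dependent impairment from a uniform one at realistic trial
  counts. The mixture was chosen by an a-priori power analysis of exactly
  that discrimination, before any acceptance test existed; set
  `srt_express_prob = 0` for the single-population sampler.
* **Masking impairment**: a step function of SRT. On `osm`/`backward`
  trials, the above-chance accuracy component is multiplied by
  `1 - mask_degradation` for saccades initiated at or after
  `mask_onset_ms` (default 160 ms); earlier saccades are untouched. The
  multiplicative form, $p' = 0.5 + (p - 0.5)(1 - d)$, guarantees the
  2AFC chance floor is never crossed, so no clamp is ever active; a
  subtractive form would need one. A smooth logistic ramp is available via
  `mask_ramp_ms` (no functional form is dictated by the phenomenon). On
  `low_contrast` trials a `uniform_degradation` applies at all latencies;
  its default is 0 because in the emulated design the low-contrast
  impairment is carried by the staircase-controlled contrast itself.
* **Design**: 4 observers × 40 blocks × 96 trials, the four conditions
  exactly balanced (24 each) and randomly ordered within every block.
  Exact balancing (rather than i.i.d. equiprobable assignment) reduces
  variance in staircase convergence; "equiprobable, randomly interleaved"
  permits either reading. One root seed spawns a deterministic
  per-observer stream, so any single observer's data can be regenerated in
  isolation.

With `mask_degradation = 0.80` and these SRT defaults, the staircase
equilibrium puts pre-onset masked accuracy near 0.82 — fast masked saccades
as accurate as the high-visibility reference, the signature pattern — while
overall masked accuracy is held near the 0.60 target. One honest caveat:
the masked-condition staircases are *intentionally misspecified* (their
model ignores the latency dependence), so realized masked accuracy
equilibrates slightly above target (≈ 0.61–0.63). All surrogate inference
matches the *realized* accuracy, so the comparison stays self-consistent;
exact convergence to target is guaranteed (and tested) only for
well-specified, zero-degradation observers.

What the simulator does **not** emulate: letter arrays and stimulus
rendering, attention allocation, directed errors toward the lure (errors
are generic wrong-side saccades), blinks and tracker artifacts, or
between-observer heterogeneity (all simulated observers share parameters
unless configured otherwise). Passing recovery tests therefore show that
the pipeline detects a latency-dependent impairment of the simulated form
at these sample sizes — not that every feature of real data is reproduced.

## Numerical choices and degenerate inputs

* Chi-square critical values from `qchisq(1 - alpha, 1)`; empty bins never
  significant.
* Bootstrap and surrogate intervals are percentile intervals;
  surrogate minimum-SRT intervals use order statistics (`type = 1`)
  because the support is a discrete grid of bin edges. More than 50%
  undefined draws marks the interval unreliable (with a warning), and
  undefined bootstrap statistics are counted and reported, never silently
  dropped.
* Surrogate relabel counts round half up; at thousands of trials per
  condition the rounding error is below 1/n.
* The staircase posterior is clamped away from 0/1 likelihoods
  (±1e-12) and renormalized every update; a non-finite posterior raises an
  error pointing at grid misconfiguration.
* Zero-IQR samples collapse the outlier fences to [Q1, Q3] with a warning;
  a never-stable staircase excludes its whole cell with a warning.

## Problem sizes used in the shipped checks

The packaged tests run the full design (4 × 40 × 96 = 15,360 trials per
experiment) for single-experiment checks, 50 replicate experiments for the
parameter-recovery property (masked minimum SRT below the surrogate 95% CI
in ≥ 90% of replicates; time-uniform condition inside it in ≈ 95%), 500
surrogate draws per ensemble, 3,000-trial staircase calibrations, and
1,000-sample brute-force oracle comparisons for the medcouple and the
minimum-SRT scan. These sizes were chosen so the whole battery completes in
minutes on one core while keeping every binomial tolerance at least three
standard errors wide.

## Known limitations

* The saccade detector is validated on synthetic traces only; real tracker
  data contain blinks, drift and noise regimes it does not model.
* The surrogate band comparison is pointwise; treat the reported
  significant time intervals descriptively, not as family-wise inference.
* Minimum SRT is a binned statistic: its resolution is one bin width, and
  comparisons across analyses are only meaningful under the same anchor
  and width.
* With few trials (small cells, very low accuracy) the minimum SRT is
  frequently undefined; the package reports this state rather than
  guessing.
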