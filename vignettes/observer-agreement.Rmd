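---
title: "Observer variability in leaf counting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer variability in leaf counting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Leaf count is a standard longitudinal phenotype for *Arabidopsis* rosettes:
genotypes that emit leaves at different rates separate cleanly when counts
are followed over a few weeks.  Counts, however, come from humans looking at
top-view images, and humans disagree — mostly about small, newly emerged
leaves.  `leafagree` provides the statistical machinery to quantify that
disagreement, to ask whether it endangers downstream genotype-by-time
inference, and to study how much annotation effort (including crowd-sourced
annotation) such a study actually needs.  Because the package is built
around a synthetic cohort-and-observer simulator, every analysis can be
exercised end to end with known ground truth.

## The synthetic cohort

The reference design images 2 cultivars × 5 replicate plants at 13
occasions spaced 48 h apart — 130 images per resolution variant.  Plant
*p* of cultivar *c* has latent count

$$ n_p(t) = n_0 + \max(0,\; r_c + u_p)\,t, \qquad u_p \sim N(0,\sigma_u^2), $$

with time $t$ in days.  The observed true count is the latent value rounded
half-up and forced non-decreasing by a running maximum (a no-op while the
slope is non-negative; kept for safety in the degenerate cases).  Leaf
emergence times are the crossing times of successive integers,
$t_j = (j - 0.5 - n_0)/(r_c + u_p)$ clamped at 0, so the number of leaves
emerged by an occasion always equals the true count at that occasion.  Leaf
*age* (time since emergence) drives the observer error model below.

Defaults: $n_0 = 2$, $r_{\text{wild type}} = 0.50$ and
$r_{\text{mutant}} = 0.35$ leaves/day, $\sigma_u = 0.05$ leaves/day, and a
"young leaf" age threshold of 2 days.  The rate gap gives end-of-study
counts near 14 vs 10 over a 24-day window — two clearly diverging growth
curves with an interaction effect of a similar character to what slow- and
normal-growing cultivars show in practice.  No published values exist for
the initial count or absolute ranges; these are package choices, made once.
Half-up rounding (`floor(x + 0.5)`) is used instead of R's round-half-even
so trajectories are platform-stable.

The two resolution variants (nominal 300 and 470 px) and the optional
geometrically transformed image copies (datasets C and D mirroring
originals A and B) are metadata: a rotated image shows the same plant, so
transformed copies share their original's ground truth.

## The observer model

An observer detects each true leaf independently.  A leaf younger than the
age threshold is missed with probability `p_miss_young[resolution]`; older
leaves with probability `p_miss_old`; with probability `p_spurious` one
extra count is added.  Default profiles encode the qualitative structure
that distinguishes annotator experience:

| profile | p_miss_young (high res) | p_miss_young (low res) | p_miss_old |
|---|---|---|---|
| experienced (ExP) | 0.10 | 0.30 | 0.01 |
| non-experienced (NExP) | 0.35 | 0.35 | 0.02 |
| citizen | 0.35 | 0.35 | 0.04 |

Experienced observers are resolution-sensitive (they can see emerging
leaves, but only when resolution permits); non-experienced observers miss
young leaves regardless of resolution; citizen volunteers additionally miss
the occasional mature leaf, giving a net undercounting tendency.  All
defaults are miss-only (`p_spurious = 0`), so a simulated count never
exceeds the truth — the property behind the maximum-consensus results
below.

Counting *without* the dot-annotation tool ("spreadsheet" mode) adds a
discretised zero-mean normal perturbation (SD 0.8 counts by default,
clipped at zero).  This captures the error from restarting a manual count
midway without modelling the cognitive process.  Tool-mode annotations can
carry per-leaf timestamps, generated as cumulative exponential gaps with a
mean of 1.1 s per leaf; `timing_summary()` excludes per-plant durations
above 200 s (an annotator who paused) and reports the exclusion count.

The citizen simulator gives every image 3–8 annotations from distinct
users, drawn from a pool whose activity weights follow a Zipf law
(`weight ∝ rank^-skew`) so a few prolific users dominate, as crowd
platforms show.  Each user's confidence answer ("did you annotate all
leaves": yes = 3, not sure = 2, missed leaves = 1) is drawn conditionally
on how many leaves that user actually missed on that image
(0 / 1 / ≥2 missed → (0.80, 0.15, 0.05) / (0.50, 0.30, 0.20) /
(0.20, 0.40, 0.40) over confidences 3/2/1).  This single mechanism produces
the negative association between count spread and mean confidence that the
confidence-spread analysis then measures; pool size and per-user error
rates have no published values and are free simulator parameters.

## Agreement metrics

For a reference observer $X_R$ paired with another source $X_o$ over a
common image set, with $d = X_R - X_o$:

* **DiC**: mean and SD of $d$.  Positive DiC means the other source
  undercounts relative to the reference.
* **|DiC|**: mean and SD of $|d|$.
* **MSE**: $\overline{d^2}$; identically equal to
  $\overline{d}^2 + \mathrm{Var}_{\text{pop}}(d)$, an identity the test
  suite asserts to $10^{-10}$.
* **$R^2$**: the squared Pearson correlation.  This satisfies "variance in
  $X_R$ predictable from $X_o$" while staying symmetric, which matters
  because the package compares in both directions; a regression $R^2$ would
  not be.  Zero variance in either vector flags $R^2$ as undefined rather
  than erroring.
* **Krippendorff's alpha** on a ratio scale: $1 - D_o/D_e$ from the
  coincidence matrix over pairable values, with difference function
  $\delta^2(c,k) = ((c-k)/(c+k))^2$ and $\delta^2(0,0) = 0$ by continuity
  (two observers who both report zero leaves agree perfectly).  No
  installed R package provides this variant, so it is implemented here and
  verified against an independent brute-force pair-enumeration oracle.

Reported SDs use the sample ($n-1$) denominator; the MSE identity uses the
population form internally, as it must.

The Bland–Altman representation is adapted for discrete counts: pairs map
to (mean, difference) coordinates, and coincident pairs merge into cells
with a multiplicity — on integer data a conventional scatter hides most of
the mass.  Means are kept at half-integer resolution so merging is exact,
with no floating-point tolerance.  Bias and the 1.96·SD limits of agreement
live in the `ba_grid` object; plotting is a thin optional layer, so tests
never inspect pixels.  The x-axis is the pair mean, the standard
Bland–Altman choice.

## Longitudinal inference

The phenotyping question is whether cultivars differ in their count
*trend*.  `fit_interaction_anova()` fits

$$ \text{count} \sim \text{time} \times \text{cultivar} + (1 + \text{time} \mid \text{plant}) $$

by REML with time as a continuous predictor (13 occasions as a categorical
factor would squander degrees of freedom) and reports Type III F tests with
Satterthwaite denominator degrees of freedom via `lmerTest`.  The
time-by-cultivar interaction is the term of interest; its coefficient
estimates the cultivar difference in emergence rate, and the package also
returns its Satterthwaite 95% interval.

The random-effect structure deserves a note.  The cohort generator varies
plants through their *slopes* ($u_p$ perturbs the emergence rate), so a
random-intercept-only model is misspecified for its own data: its residuals
hide within-plant correlation that grows with time, the interaction
standard error is badly underestimated, and in simulation the nominal-5%
test rejects a true null about 59% of the time.  With the correlated
intercept-plus-slope structure the empirical size is ≈ 0.052 (1000 null
cohorts) and the interaction interval covers the true rate difference in
≈ 94% of cohorts.  The package therefore defaults to the richer structure —
the plant is still the random-effect grouping unit — and degrades
gracefully: when all random-effect variances are estimated at (effectively)
zero the fit falls back to a random intercept and finally to the OLS
ANCOVA, whose F statistics the mixed model reproduces to $10^{-14}$ in that
limit.  "Effectively zero" means a relative covariance parameter below
$10^{-3}$ (random-effect SD under 0.1% of the residual SD): the optimizer
stalls around $10^{-3}$–$10^{-4}$ on exactly degenerate data, so a stricter
cut fails to detect true degeneracy.

Consensus counts enter the model unrounded, consistent with averaging
across observers before modelling.

## The subsampling study

To ask how much annotation effort the inference actually needs, a
Monte-Carlo study draws, per trial, a binary sampling matrix with exactly
`K` ones per plant-time row (columns = observers, chosen uniformly without
replacement, rows independent), averages the selected observers' counts
into a consensus, fits the interaction ANOVA, and records the interaction
p-value.  Across 500 trials the p-value distribution is summarised by
minimum, maximum, mean, sample SD and *raw* kurtosis $m_4/m_2^2$ (the
non-excess convention, reference value 3 for a normal; the distributions
here are strongly leptokurtic, so the convention matters when reading the
numbers).  A master seed spawns per-trial sub-seeds through a counter-based
scheme, so any individual trial can be reproduced for debugging.  Trials
whose model fails are excluded and counted, never silently redrawn.

Pools can be restricted to experienced or non-experienced observers via
`observer_pool()`, mirroring the three natural pool conditions.  Note that
trials within one study share the same simulated cohort: the p-value spread
reflects observer-sampling noise only.  Statements about test calibration
(size, coverage) therefore come from re-simulating whole cohorts, not from
subsampling trials.

## Citizen consensus

`consensus_counts()` aggregates each image's citizen counts by mean,
maximum or a seeded uniformly-random single pick.  Under the default
miss-only citizen model the mean is biased low (every annotator can only
miss), while the maximum — the union of what anyone saw, in count terms —
is nearly unbiased; in simulation the absolute bias of the maximum is an
order of magnitude below that of the average.  This is the regime where
annotators err by omission; with spurious counts enabled the maximum would
accumulate false positives instead, which is why both rules are exposed.

`confidence_spread()` relates each image's count SD to its mean confidence
as a normalised 2-D histogram, with exact-zero SD kept as its own "none"
category, and reports the mass in the low-spread/high-confidence quadrant.
The quadrant boundaries (SD < 1.0 count, mean confidence > 2.0) split the
axes at their natural midpoints and are configurable; the quadrant fraction
is computed from the raw per-image values, not from the binned histogram,
so it does not depend on the bin edges.

## What the simulator does and does not show

The generator reproduces the *structure* of a real annotation study — a
genotype-dependent emergence process, age- and resolution-dependent misses,
experience classes, skewed crowd activity, confidence tied to actual
misses — with parameters chosen once for realism.  It does not model
occlusion geometry, dot-placement accuracy, fatigue drift within a session,
inter-leaf appearance variation, or annotator learning.  Passing tests
therefore demonstrate that the statistical machinery behaves correctly and
that the study design carries the claimed properties under plausible error
rates; they do not certify any particular human error rate, which only real
annotations can.

## Numerical and testing choices

Monte-Carlo problem sizes in the shipped tests and acceptance script: 1000
null cohorts for empirical size, 200 cohorts for coverage and for the
consensus-bias comparison, 500 subsampling trials at the reference design
(130 rows × 9 observers), 500 random matrices for the alpha oracle check,
1000 random vectors for the MSE identity.  These sizes give binomial
standard errors well inside the asserted bands while keeping a full run in
minutes.  All randomness flows from explicit seeds; seeded functions
restore the caller's RNG state (`withr::with_seed`), and sub-seeds are
derived with a small multiplicative scheme kept below $2^{31}$.

Known limitations: the interaction coefficient is only reported for
two-cultivar designs (with more cultivars the interaction is a multi-df
term and the single-difference summary is undefined); alpha confidence
intervals (e.g. by bootstrap) are not provided; no ordinal-scale alpha,
weighted kappa or ICC variants; the Bland–Altman grid carries no
repeated-measures correction to its limits of agreement.
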