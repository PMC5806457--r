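# leafagree

Humans are still the reference instrument for counting leaves in top-view
images of *Arabidopsis* rosettes — and humans disagree, mostly about small,
newly emerged leaves.  `leafagree` is an R package for quantifying that
disagreement and for asking the question that actually matters for a
phenotyping study: does observer variability endanger the downstream
genotype-by-time inference, and how much annotation effort (expert,
non-expert, or crowd-sourced) does the inference need?

It is aimed at phenotyping groups designing annotation campaigns, and at
anyone working with inter-rater count data.

## What it computes

For a reference observer `X_R` paired with any other count source `X_o`
(another observer, a consensus of citizens, an algorithm's predictions),
with `d = X_R − X_o`:

- **DiC** `(mean(d), sd(d))` and **|DiC|** `(mean|d|, sd|d|)`;
- **MSE** `mean(d²)`;
- **R²**, the squared Pearson correlation;
- **Krippendorff's alpha** on a ratio scale, `1 − D_o/D_e` with difference
  function `δ²(c,k) = ((c−k)/(c+k))²` over the coincidence matrix;
- a **Bland–Altman grid** for discrete counts (coincident points merged
  into multiplicity-weighted cells) with bias and `±1.96·sd` limits of
  agreement, plus the difference histogram;
- a **mixed-effect repeated-measures ANOVA** of `count ~ time × cultivar`
  with a per-plant random intercept and time slope (Satterthwaite F tests);
  the time-by-cultivar interaction tests whether longitudinal trends
  differ between genotypes;
- a **Monte-Carlo observer-subsampling study**: per trial, a random binary
  sampling matrix assigns exactly `K` observers to every plant-time
  observation, their counts are averaged, and the interaction p-value is
  recorded; the p-value distribution over 500 trials is summarised by
  min/max/mean/sd/kurtosis (raw, non-excess);
- **citizen-consensus aggregation** (average, maximum, single random
  annotation) and the relation between per-image count spread and
  self-reported confidence (yes = 3 / not sure = 2 / missed leaves = 1).

Everything runs against a synthetic cohort-and-observer simulator with
known ground truth: a two-cultivar design (5 replicates × 13 occasions at
48 h = 130 images), plant counts growing as `n0 + max(0, rate + u_p)·t`
with per-plant rate deviations, and observers who miss young leaves with
resolution- and experience-dependent probabilities.  See the methods
vignette (`vignettes/observer-agreement.Rmd`) for the models, defaults and
their rationale.

## Worked example

```r
library(leafagree)

design <- build_design()                      # 2 cultivars x 5 plants x 13 occasions
truth  <- simulate_growth(design, growth_params(), seed = 42)

ref   <- simulate_observer_counts(truth, design,
                                  default_observer_profile("ExP", "exp_01"),  seed = 101)
other <- simulate_observer_counts(truth, design,
                                  default_observer_profile("NExP", "nexp_01"), seed = 106)

paired <- pair_counts(ref, other)
agreement_report(paired)
#> # A tibble: 1 × 7
#>   dic_mean dic_sd adic_mean adic_sd   mse    r2 alpha
#>      <dbl>  <dbl>     <dbl>   <dbl> <dbl> <dbl> <dbl>
#> 1   0.0462  0.879     0.585   0.656 0.769 0.945 0.721

within_one_fraction(paired)
#> [1] 0.9230769

ba_grid(paired)
#> <ba_grid> 130 pairs in 49 cells; bias 0.046, LoA [-1.677, 1.769]
```

The experienced and non-experienced observers agree closely on average
(DiC 0.05 ± 0.88 leaves; 92% of images within one leaf) but the
chance-adjusted alpha (0.72) reveals the young-leaf misses that raw
correlation (R² 0.95) glosses over.

```r
tab <- build_count_table(ref, design, "single")
res <- fit_interaction_anova(tab)
as.data.frame(res)
#>                 term      sum_sq df_num    df_den    f_value      p_value interaction
#> 1          time_days 191.7875686      1  8.043731 455.797987 2.273177e-08       FALSE
#> 2           cultivar   0.6875208      1 10.244677   1.633946 2.293588e-01       FALSE
#> 3 time_days:cultivar   7.7450899      1  8.043731  18.406805 2.617031e-03        TRUE
attr(res, "interaction")$estimate
#> [1] 0.1846154
```

Even through one noisy observer, the cultivars' growth trends separate
clearly (interaction p = 0.0026); the interaction coefficient (0.18
leaves/day) estimates this cohort's realized wild-type-minus-mutant
emergence-rate difference (generator value 0.15, plus the luck of the
plant draw).

```r
citizens <- simulate_citizen_study(truth, design, seed = 7)
confidence_spread(citizens)
#> <confidence_spread> 130 images (0 excluded); 82% in the low-spread/high-confidence
#> quadrant (sd < 1, confidence > 2)
```

Citizens agree with each other and say so: most images sit in the
low-spread / high-confidence quadrant, and their mean consensus
undercounts truth by 0.62 leaves (miss-only annotators), a bias the
maximum-consensus rule nearly eliminates.

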