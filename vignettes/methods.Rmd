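---
title: "Hypomanic personality and sleep: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypomanic personality and sleep: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpsleep)
```

## The scientific question

Sleep disturbance is a hallmark of bipolar disorder and persists between
episodes. One way to ask whether disturbed sleep *precedes* the disorder is
to study healthy people who vary on a dimensional vulnerability trait —
hypomanic personality, measured by a 44-item true/false questionnaire — and
test whether higher trait scores go with worse and, especially, more
*variable* sleep. `hpsleep` implements that analysis end to end: scoring and
factor analysis of the questionnaire, per-subject actigraphy summaries,
covariate-adjusted rank correlations over a fixed 21-variable sleep panel,
a permutation-based quantile–quantile (QQ) envelope that aggregates the
evidence across the whole grid of tests, decile extreme-group contrasts,
and cross-validated incremental prediction. Because the motivating cohort
data are not publicly deposited, the package ships a synthetic cohort
generator whose defaults encode the study conditions; every analysis stage
is exercised, and tested, against cohorts it generates.

## The synthetic cohort model

`cohort_config()` fixes the generating model:

* **Subjects.** Ages uniform on 60–82 years, sex Bernoulli with
  `p_female = 0.48`, and three latent personality factors — *hypomanic
  core*, *social vitality*, *ordinariness* — drawn from a trivariate normal
  with correlations (core, vitality) = 0.40, (core, ordinariness) = −0.30,
  (vitality, ordinariness) = −0.10. A standardized socioeconomic index
  loads 0.45 on vitality, so that vitality is the facet most explained by
  social position. By default 1766 subjects carry questionnaire + PSQI
  data and a random 771 of them also have actigraphy, mirroring the
  subsample sizes the analysis is meant for.
* **Items.** Each of 44 items is assigned to one factor with loading
  `a` in [0, 1) and threshold `tau`; the response latent is
  `y* = a F + sqrt(1 - a^2) e`, endorsed when `y* > tau`. Because `y*` is
  standard normal, the implied tetrachoric correlation between items is
  exactly `a_i a_j corr(F_i, F_j)` — a closed form that serves as the
  oracle for the whole factor-analysis stack. Ordinariness items are
  reverse-keyed relative to the hypomanic pole.
* **Nights.** Each actigraphy subject contributes 5–7 nights with
  probabilities (0.02, 0.06, 0.92), i.e. a mean of 6.9 nights. Per
  subject, the person-level mean of each sleep parameter is linear — and
  the log of the person-level night-to-night SD log-linear — in the three
  factors, centred age, and sex. Nightly draws are onset-time normal,
  duration normal, latency lognormal, awakenings (NWAK) Poisson, and WASO
  gamma, giving right-skewed non-negative marginals like real actigraphy.
  Implausible draws are rejected and *resampled* (never clipped, to avoid
  point masses at the bounds; at most 100 attempts, then an error):
  duration in (120, 720) min, latency < 300 min, WASO < 400 min,
  NWAK < 30, onset between 20:00 and 05:00, and — jointly — final
  awakening before the next noon, since a later offset would wrap the
  stored clock time past the linearization reference.
* **PSQI.** Item-level self-reports (reported latency, duration, bed and
  get-up times, ordinal quality/disturbance/medication/sleepiness items)
  are generated from latent components that are linear in the factors,
  age, and sex, with unit-normal residuals and fixed ordinal thresholds.
* **Seeding.** One global seed expands into per-stage child seeds through
  the fixed affine map in `child_seed()` (`subjects`, `items`, `nights`,
  `psqi`, …), so each stage is independently reproducible and identical
  configurations give byte-identical CSV output.

The latent factor truth is written to a separate `truth.csv` that no
analysis stage reads; it exists solely for recovery tests.

### Effect-size calibration

Cross-domain coefficients are the generator's most consequential knobs.
They were set once, by large-sample Monte Carlo (cohorts of 150,000–250,000
subjects), so that the *population* covariate-adjusted Spearman
correlations between the latent factors and the panel variables fall in the
0.05–0.16 band typical of this literature, with one anchored condition: the
(core, ISD WASO | age, sex) partial Spearman equals 0.12. That anchor is
what the effect-recovery tests re-estimate on replicate cohorts. Signs
follow the substantive pattern: higher core means shorter, more fragmented,
and more variable sleep and worse perceived sleep; ordinariness the
opposite; vitality shares the objective impairment of core but reports
*better* subjective sleep.

### What the generator does not emulate

No raw accelerometer signal (nights are generated at the parameter level),
no clinical exclusion cascade (cohorts are post-exclusion by construction),
no missing-at-random item nonresponse, no weekday/weekend or seasonal
structure, and no heavy-tailed subject outliers beyond what the lognormal /
gamma marginals produce. Passing tests therefore demonstrate that the
*pipeline* is correct and calibrated under a realistic generating model,
not that the substantive findings replicate in any real cohort.

## Actigraphy summaries

`summarize_sleep()` reduces night records to the 14-variable panel: the
mean and the intraindividual standard deviation (ISD, the `n - 1` sample
SD across a subject's nights) of onset latency, onset time, offset time,
duration, NWAK, WASO, and efficiency. Choices worth knowing:

* Clock times are linearized as minutes elapsed since **noon**, so evening
  onsets and morning offsets each live on one continuous axis and the
  midnight wrap is harmless. This is a linear, not circular, treatment; it
  is the documented limitation for free-running rhythms whose onsets
  straddle noon.
* Efficiency is duration / (latency + duration + WASO), computed **per
  night** and then averaged — symmetric with how its ISD is defined.
* Subjects with fewer than `min_nights = 5` nights are dropped (and
  counted in the log), not imputed.

## Questionnaire scoring and factor analysis

Sum-scores are keyed by a frozen `ScoringKey` (direction relative to the
hypomanic pole, subscale assignment); the PSQI's seven 0–3 components and
0–21 total are computed from cut-points shipped as an editable YAML table
(`psqi_scoring.yaml`), because published scoring dialects differ and the
pipeline must be testable against any of them.

The subscales themselves come from factor analysis of the tetrachoric
correlation matrix:

1. **Tetrachorics** are maximum-likelihood estimates under the latent
   bivariate-normal model, with thresholds fixed at the marginal
   inverse-normal estimates. With margins matched, the ML condition
   reduces to solving `Phi2(h, k, rho) = p11`, which the package solves by
   vectorized bisection over a Gauss–Legendre evaluation of the bivariate
   normal CDF — fast enough to estimate all 946 item pairs, and all the
   parallel-analysis replicates, in seconds. Tables with a single empty
   cell get a +0.5 continuity correction (flagged); perfectly concordant
   tables are capped at ±(1 − 1e−6).
2. **Smoothing.** Pairwise tetrachoric matrices need not be positive
   semi-definite; eigenvalues below 1e−6 are clipped and the matrix is
   rescaled to unit diagonal (`smooth_to_psd()`), a no-op for PSD input.
3. **Retention** uses Horn's parallel analysis (`retain_k()`, 100
   simulations, 95th percentile, seeded). For dichotomous input the null
   eigenvalues are computed from random *binary* data with the observed
   item marginals, correlated with the same tetrachoric estimator. A
   Pearson-on-normal-data null would understate the sampling dispersion of
   tetrachoric estimates and inflate the retained dimensionality; the
   binary null keeps estimator and null matched. For continuous input the
   classical normal-data null is used.
4. **Extraction** is iterated principal-axis factoring started from
   squared multiple correlations (tolerance 1e−6 on the communalities,
   1000-iteration cap with an informative non-convergence error; Heywood
   communalities are clipped to 1 and flagged).
5. **Rotation** is promax (varimax then a power-4 oblique target), chosen
   over oblimin because the two-stage algorithm is deterministic and easy
   to test; factor correlations are reported. Column signs are fixed so
   each factor's largest-magnitude loading is positive, and columns are
   ordered by sum of squared loadings.
6. **Scores** are Thurstone regression scores
   (`Z R^{-1} (pattern %*% phi)`), standardized, with factors labeled by
   configured marker-item lists — labels are interpretation, not
   algorithm, so they are configuration.

## Association analysis

The core statistic is the partial Spearman correlation, constructed as
rank → residualize → Pearson: `x`, `y`, and the covariates (age, sex) are
average-rank transformed; ranked `x` and `y` are residualized on the
ranked covariates by least squares; the correlation of residuals is
tested with `t = rho sqrt((n - 2 - k)/(1 - rho^2))` on `n − 2 − k` degrees
of freedom. `correlate_grid()` applies it over the full 4 × 21 grid
(84 tests) with per-pair complete cases, so actigraphy and PSQI
subsamples of different sizes coexist. Multiple-test correction defaults
to Benjamini–Hochberg applied jointly across all 84 tests (one family);
Holm and Bonferroni are switchable. Dependent-correlation contrasts use
Steiger's Z. Extreme groups take the bottom/top deciles by the
nearest-rank rule with boundary ties included (so group sizes are
unequal in general) and are compared by tie-corrected Kruskal–Wallis
tests.

## The permutation QQ envelope

To aggregate evidence across the 84 dependent tests, the package builds a
permutation null that keeps each domain's internal correlation structure
and destroys only the cross-domain links: subject rows of the **sleep
block** are shuffled as whole rows while the personality block and the
covariates stay fixed. Shuffling the sleep side (rather than personality)
keeps the personality–covariate alignment intact, so the covariate
adjustment remains meaningful under the null; the shuffled sleep block is
consequently also de-associated from the covariates — one of two equally
defensible readings of the procedure, fixed and documented here. Complete-
case masks are frozen before permuting (columns sharing a missingness
pattern are shuffled together), so every test keeps a constant n across
replicates.

Each replicate's 84 p values are sorted in **descending** order; across
replicates the rank-wise mean forms the expected line and the 5th/95th
percentiles (linear-interpolation rule) the envelope. Observed p values
are sorted the same way and flagged where they leave the envelope;
excess signal shows up as the observed curve dropping below the 5th
percentile at the smallest-p ranks. The analytic Beta order-statistic
envelope is used only as a test oracle — the method itself is
deliberately permutation-based. The default is 10,000 replicates (an
envelope stable to ~0.01); production analyses can raise
`n_replicates` arbitrarily.

## Incremental prediction

`cv_predict_scores()` contrasts, on identical seeded ten-fold splits,
out-of-sample R² of covariates-only vs covariates + the 21 sleep
variables, per personality score, with OLS as the (configurable) learner.
Predictors are standardized on each training fold only; R² is pooled over
all held-out predictions (`1 − SSE/SST` about the full-sample mean),
which is stabler than averaging per-fold R² with small folds. The sleep
panel contains an exact accounting identity — offset = onset + duration +
WASO, blurred only by storage rounding — so near-dependent columns are
treated as rank-deficient (pivoted QR, relative tolerance 1e−2) and
dropped with a log entry rather than left to blow up the fit.

## Numerical and scale choices

* All tables are RFC-4180 CSV, '.' decimals, empty string for missing,
  clock times as HH:MM; every writer's output is readable by its reader.
* The test suite runs the study-scale checks at deliberately chosen sizes:
  factor retention on 25 cohorts of n = 2861; null calibration on 200
  zero-effect cohorts of n = 771 (envelope coverage on 40 of them at 1500
  replicates); effect recovery on 100 cohorts of n = 5000 against a
  250,000-subject reference; order-statistic calibration at 10,000
  permutation replicates.
* The 5th–95th envelope of an R-replicate permutation set covers a fresh
  null curve with probability 0.90 minus a term of order 1/R, so coverage
  assertions are one-sided significance checks against 0.90 rather than
  sharp thresholds.

## Known limitations

Linear (not circular) clock statistics; a single scoring key frozen by
configuration rather than estimated item polarity; OLS-only prediction
(no regularization — by design, the contrast is the object of interest);
no missing-data machinery beyond complete-case exclusion, matching the
analysis it implements; and the generator caveats listed above.
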