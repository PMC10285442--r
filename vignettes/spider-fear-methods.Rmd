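---
title: "Measuring spider fear in a simulated cohort: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spider fear in a simulated cohort: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clinicians and researchers measure fear of spiders with instruments that tap
different processes: self-report questionnaires (SPQ for spider fear, SNAQ for
snake fear, DS-R for disgust propensity), a behavioral approach test (BAT)
toward a live tarantula, subjective 1–7 fear ratings of pictures, and — at the
expensive end — fMRI brain activation during picture viewing. A useful
single-number summary of the neurophysiological response is the **Spider Fear
Index (SFI)**: the average first-level *spider > beetle* t-statistic inside a
data-driven region of interest (ROI), where the ROI comes from an independent
scanning session so that selection and measurement noise do not mix.

`spiderfear` implements that whole measurement chain on *synthetic* data. No
subject-level data from the motivating study are deposited, so the package's
job is not to reproduce empirical coefficients but to (a) implement every
closed-form scoring and design rule exactly, and (b) verify, on a generative
model with known ground truth, that the pipeline recovers what was planted:
group separation, the responsive region, and the ordering of individual
activation levels.

# The generative model

## Latent traits

Each subject carries three standardized latent traits: spider fear, snake
fear, and disgust propensity. Spider fear has a group-dependent mean
(default 2.5 for phobics, 0 for controls, within-group SD 0.5); snake fear
and disgust are constructed as
$s = \rho\, f + \sqrt{1-\rho^2}\,\varepsilon$ with default correlations
$\rho_s = 0.3$ and $\rho_d = 0.4$, reflecting the mild coupling between
spider fear, snake fear and disgust reported in the questionnaire
literature. The snake trait is capped (default 2.0) to emulate the
screening rule that excluded snake-fearful respondents (SNAQ > 17).

The trait separation and the item parameters below were calibrated once,
against the published group summaries (mean SPQ about 21.7 in phobics versus
1.6 in controls, mean BAT 4.6 versus 6.8, controls answering no to every
interview question), and then frozen. They are deliberately *not* arguments
of the test suite.

## Observed measures

* **Binary questionnaires (SPQ 31 items, SNAQ 30 items).** A two-parameter
  logistic item-response model: the probability of a fearful-direction
  answer to item $i$ is $\mathrm{logit}^{-1}(a(f - d_i))$ with a common
  discrimination $a$ and evenly spaced difficulties $d_i$ (SPQ: $a = 2.2$,
  $d_i \in [0.5, 3.2]$; SNAQ: $a = 1.5$, $d_i \in [1.2, 4.0]$, driven by the
  snake trait). Nine items per scale are reverse-keyed: the generator flips
  the stored response, the scorer flips it back (response XOR reversed).
  This is the simplest model producing realistic total-score distributions;
  the identity of the reversed items is unpublished, so the default key
  reverses items 1–9 and is a configurable input.
* **DS-R.** 25 ordinal 0–4 elicitor items from a rounded, clipped linear
  model on the disgust trait (loading 0.8, residual SD 0.8); items 1, 6, 10
  are generated reversed and scored as $4 - x$; catch items 12 and 16
  receive the keyed attention value. The factor assignment of elicitors to
  the core / animal-reminder / contamination subscales is unpublished; the
  default key uses a documented block assignment (12/8/5 items) and is
  likewise configurable.
* **BAT.** A latent avoidance value $f + \varepsilon$ (noise SD 0.8) is
  compared against seven decreasing step thresholds
  (5.5, 5.0, 4.5, 3.0, 2.4, 2.0, 1.0); the score is the number of thresholds
  above the avoidance value, which automatically yields a completed-step
  prefix and the characteristic bimodal phobic split between "uncover and
  look" (4) and "touch" (6–7). A score of 0 (refusing every step) is
  permitted even though the published scale starts at 1, because the refusal
  case is otherwise undefined.
* **Interview.** Six independent yes/no answers with probability
  $\mathrm{logit}^{-1}(9(f - 1.4))$; the classification rule is at least
  5 of 6. The link is steep so that controls essentially always answer no
  to everything and phobics nearly always clear the threshold. Because the
  generator defines groups by the latent trait while the rule operates on
  answers, rare boundary subjects can disagree — a property real interview
  data share.
* **Ratings.** Rating of picture $j$ in category $c$ is
  $\mathrm{round}(\mathrm{clip}(\mu_c + w_c f + w'_c s + \varepsilon,\, 1, 7))$
  over 40 unique pictures in each of six categories (tarantula,
  daddy-long-legs, beetle, leaves, snake, lizard). Spider categories load on
  the spider trait (1.7 and 1.0), snake and lizard on the snake trait (1.2
  and 0.6), beetles and leaves on neither; residual SD 1.

Only women were studied in the motivating work, so the generator emulates a
female cohort with uniform ages in 18–66 and no sex structure.

## Block design and BOLD signal

Each subject is scanned in two sessions of four conditions ("spider":
tarantula, daddy-long-legs, beetle, leaves; "fear": tarantula, beetle,
snake, lizard). Blocks hold 10 pictures of 1.5 s each, matching the TR of
1.5 s; eight blocks per condition fill 8 minutes and 320 volumes.

Block order is pseudorandom but carryover-balanced. A linear sequence of 32
blocks has 31 adjacent pairs, which no assignment can divide equally among
the 12 ordered condition pairs (or 16 including repeats); exact balance is
therefore defined *circularly*, counting the wrap-around transition and
same-condition transitions. Under that definition a balanced sequence exists
exactly when the number of blocks per condition is a multiple of four, and
is constructed as a seeded Eulerian circuit on the complete directed graph
with self-loops. Other block counts fall back to a seeded shuffle (or error,
if strict balance is requested).

The BOLD signal at voxel $v$ is
$y_v(t) = \sum_c \beta_{v,c} X_c(t) + \epsilon_v(t)$, where $X_c$ is the
condition boxcar convolved with a canonical double-gamma HRF (response peak
parameter 6, undershoot 16, ratio 1/6, sampled at the TR, unit peak height)
and $\epsilon_v$ is stationary AR(1) Gaussian noise (marginal SD 1,
lag-1 coefficient 0.3 — the analysis software the field uses assumes an
AR model of this kind). Outside the ground-truth region every condition
evokes a common visual response (0.5 % signal change); inside the region
(default: the central $3^3$ cube of a $12^3$ grid of 3 mm voxels) the
tarantula condition gains a baseline bump (+0.2) plus
`activation_gain` × spider trait (default 0.5 per trait unit). The bump
means controls also activate weakly, so the control-group SFI is small but
positive, as in a real visual-fear paradigm.

A 12³ grid is deliberately far below a whole-brain acquisition; it keeps a
61-subject, two-session experiment at roughly ten seconds of computation
while preserving every statistical property the analyses rely on
(multiple-testing burden, spatial ground truth, AR noise).

## What the generator does *not* emulate

Scanner preprocessing (bias-field correction, realignment, slice timing,
spatial normalization), motion and physiological artifacts, spatially
correlated noise, and nonlinear hemodynamics are all absent. Passing tests
therefore show that the *statistical pipeline* is correct and calibrated,
not that it is robust to real acquisition artifacts. Spatial smoothing is
implemented (`smooth_volumes`, separable Gaussian, mirrored boundaries) with
8 mm FWHM as the documented reference width, but the pipeline default is
*no* smoothing: on a small grid with a compact planted region, smoothing
mostly blurs the ground truth that the recovery tests compare against, and
in a real analysis smoothing belongs to the preprocessing chain this package
does not model.

# The analysis chain

## First level and group level

Per voxel, ordinary least squares against the HRF-convolved design
(condition regressors, intercept, linear drift):
$\hat\beta = (X'X)^{-1}X'y$, $t = c'\hat\beta / \sqrt{\hat\sigma^2
c'(X'X)^{-1}c}$ for the contrast $c$ = tarantula − beetle. No pre-whitening
is applied at the first level, so subject-level t-values are mildly
miscalibrated under AR(1) noise (a documented limitation shared by the
simplest standard analyses). The group analysis is a voxelwise one-sample
t-test; by default it tests the subject-level *contrast estimates* (not
their t-values), because subject estimates are unbiased regardless of
within-subject autocorrelation, which keeps the group test exactly
calibrated — this is also why the null family-wise error simulation comes
out at its nominal level despite the unwhitened first level. A t-averaging
group variant is available behind a flag.

Zero-variance voxels produce sentinel (infinite) t-values and are excluded
from ROI candidacy rather than silently mapped to zero.

## ROI and SFI

The ROI is the set of voxels surviving one-sided FWE control at
$\alpha = 0.05$ in the *fear*-session group map, computed from the phobic
group only (the flag `roi_group = "all"` pools everyone). Bonferroni is the
default correction because it is exactly reproducible; a sign-flipping
max-t permutation threshold is provided as the closer analogue of the FWE
machinery in standard fMRI software. The SFI is then the plain mean of the
subject's *spider*-session first-level t-values inside that mask — the
subject-level quantity averaged is the t-statistic by definition, with a
contrast-estimate variant behind a flag for sensitivity analysis. An empty
mask raises an error: the index is undefined without a region, and
silently returning zero would fabricate a measurement.

Because the mask comes from one session and the index from the other, the
SFI of a subject with no true spider response is centred at zero; this
independence is verified by simulation in the test suite. Note that the
numerical scale of the SFI depends on the noise model and session length,
so its simulated range is not comparable to values computed from real
scanner data.

One phobic subject is excluded by `run_study()` before analysis
(`exclude_phobic = 1`), emulating the data-quality exclusion that reduced
the motivating study's sample to 29 + 32 = 61; the exclusion hook takes any
set of subject ids.

## Redundancy analysis

The fear ratings (one column per picture, 240 columns; a 6-column
category-mean variant exists for speed) are the response matrix $Y$;
group, SFI, SPQ, SNAQ, DS-R, BAT and age are the explanatory matrix $X$.
$Y$ is column-centred, regressed on centred $X$, and the fitted values are
decomposed by SVD; eigenvalues are $d_k^2/(n-1)$ and the proportion
explained is the fitted-to-total sum-of-squares ratio. With seven
explanatory variables the model yields seven constrained axes. Scores are
reported in the two conventional triplot scalings.

Term significance uses sequential ("Type I") permutation tests: term $k$'s
pseudo-F is the variance it adds per degree of freedom over the full-model
residual variance, and its null distribution comes from permuting the
residuals of the model with the preceding terms
($Y^* = \hat Y_{k-1} + P\,(Y - \hat Y_{k-1})$). Free row permutation is
available as an option. P-values are $(1 + \#\{F^* \ge F\})/(1 + B)$, so
the attainable minimum is $1/(1+B)$; the motivating analysis used
$B = 2000$, and the package default is 1999. A computational note: all
trace statistics are invariant to replacing $Y$ by its left singular
factor $UD$, which caps the per-permutation cost at $n$ columns regardless
of how many pictures are rated.

## Model reduction, discrimination, correlation

* `lm_aic_select()` reduces the linear model SFI ~ BAT + SPQ + SNAQ + DS-R
  + six fear scores + group + age by backward elimination under
  $AIC = n\log(RSS/n) + 2k$ (exhaustive search optional up to 12
  candidates). The RSS is floored at $10^{-12}$ of the total sum of squares
  so that exact fits are compared by parameter count rather than by
  $\log 0$.
* `lda_classify()` is a two-group linear discriminant with pooled
  within-group covariance and proportional priors, reporting the
  resubstitution confusion matrix (the apparent classification the
  motivating analysis tabulated) with leave-one-out CV as an option, and
  ranking variables by their one-way ANOVA F — the ordering a stepwise
  discriminant analysis reports. A ridge fallback
  ($S + 10^{-6}\bar{s}\,I$) handles singular pooled covariance with a
  warning.
* `spearman_cor()` ranks with average ranks and returns the Pearson
  correlation of ranks; p-values are exact by full enumeration for
  $n \le 8$ (40320 permutations, vectorised — full enumeration beyond 8 is
  disproportionate) and otherwise use the t approximation
  $t = r_s\sqrt{(n-2)/(1-r_s^2)}$.

# Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds; identical seeds give
  bitwise-identical cohorts, series, and permutation p-values. Per-subject
  noise seeds are small offsets of the base seed.
* Rank decisions use SVD/QR tolerances of order machine epsilon times the
  leading singular value; a rank-deficient explanatory matrix in RDA drops
  the redundant directions with a warning, while a rank-deficient GLM
  design is an error.
* Degenerate inputs fail loudly: zero-length blocks, all-zero contrasts,
  empty ROIs, constant vectors in rank correlation, non-prefix BAT
  patterns, out-of-range item responses.
* Smoothing uses mirrored (edge-duplicating) boundaries, which preserve
  constants and total mass exactly; this is asserted to $10^{-9}$ in tests.

# Problem sizes used by the test suite

The suite regenerates every fixture in code. The heavier checks use: the
full default cohort (61 analysed subjects, $12^3$ grid, two sessions) for
SFI parameter recovery; 200 replicates of an 8-subject null group for the
family-wise error calibration (the null distribution of the FWE procedure
does not depend on group size, so a small group is a pure speed choice);
and 500 simulated datasets with 199 permutations each for the level of the
sequential test, where the discrete permutation p rejects at rate
$9/200 = 0.045$ at nominal 0.05. Both calibration checks assert the
observed count inside a 99.9 % binomial band around the procedure's exact
level.

# Known limitations

* Item-level questionnaire structure is a convenience model; only total
  score distributions were calibrated. Reversed-item identities and DS-R
  subscale assignments are stand-in defaults, clearly exposed as
  configuration.
* The first level is unwhitened OLS; subject t-values inherit AR(1)
  miscalibration. Group inference and the SFI ordering are unaffected (the
  group test consumes unbiased estimates), but absolute subject-level
  t-magnitudes should not be interpreted.
* Resubstitution classification is optimistic by construction; it is
  reported because the reference analysis reported it, and the CV option
  exists for honest error rates.
* The between-group correlations among SFI, SPQ and BAT partly reflect the
  two-group design; the generator's `trait_means` can be set equal (with a
  continuous trait spread) to study within-group structure, but no
  published value constrains that regime.
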