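---
title: "Methods: fractal brain dynamics, behavioral PLS, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal brain dynamics, behavioral PLS, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hurstpls)
```

This vignette is the package's own account of its models, the tunable
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the methods literature leaves
them open. Every empirical claim here is one the test suite or the
acceptance script computes; nothing is asserted from outside the package.

## 1. Hurst estimation by detrended fluctuation analysis

A parcel time series x(t) is mean-centered and integrated into a profile
X(t). For a window size n with N = floor(T/n) windows, the first n·N frames
are partitioned into contiguous windows, a polynomial trend (order 1 by
default) is removed within each, and the root-mean-square residual F(n) is
recorded. For a self-affine signal F(n) ~ n^H, so H is estimated as the OLS
slope of log F(n) on log n. The R² of that regression is returned with
every fit: it is a mono-fractality diagnostic, not a filter — the package
reports it and leaves rejection thresholds to the analyst, because no
principled universal cutoff exists.

**Window scheme.** Window sizes are constrained to a frequency band: a
window of n frames at repetition time `tr` probes fluctuations near
1/(n·tr) Hz. The defaults `f_low = 0.01`, `f_high = 0.1` Hz exclude scanner
drift and high-frequency physiological confounds; with `tr = 0.8` s and
T = 362 frames this yields windows of 13 to 90 frames (the 90 comes from
requiring at least `min_windows_per_scale = 4` windows per scale; the band
alone would allow up to 125). Window *counts* N are sampled approximately
uniformly over the admissible integer range — all of them when there are at
most `max_n_scales = 30`, else that many evenly spaced values — and
duplicate window sizes keep the larger N. Note that because n = floor(T/N),
not every integer window size is attainable: at T = 362 the largest
sub-0.01-Hz window is 120 frames (floor(362/3)), not the band cap of 125.

**Numerical choices.** Natural logarithms in the slope regression (the
slope is base-invariant); non-overlapping forward windows only, with an
optional `reverse_pass` flag that averages a second pass over the reversed
profile (off by default); remainder frames beyond n·N are dropped per
scale. Constant series are an error; a series that DFA cannot sensibly
describe (e.g. a pure ramp) returns its slope *with* its R² rather than
failing silently — the estimate is visibly outside (0, 1) and the
diagnostic is attached.

**Block-level estimation.** `block_hurst()` fits each task block
separately, capping the largest window at floor(block_length / 4) while
keeping the band's smallest window, then averages H across same-condition
blocks. With the full-run band the smallest admissible window is 13 frames,
so a typical 40-frame block admits no scales at all; block-level analyses
therefore use a widened high-frequency bound (`f_high = 0.3` Hz, smallest
window 5 frames) — this is a package design choice, made because short
blocks physically cannot contain sub-0.1-Hz cycles, and it is the pipeline
default for block stages only.

## 2. Fractional Gaussian noise and the calibration anchors

`simulate_fgn()` synthesizes exact fGn by circulant embedding
(Davies–Harte): the autocovariance
γ(k) = ½(|k+1|^{2H} − 2|k|^{2H} + |k−1|^{2H}) is embedded in a circulant
matrix whose eigenvalues come from one FFT; a second FFT of
suitably scaled complex Gaussians yields a series with exactly this
covariance. If the embedding ever failed to be nonnegative definite the
generator falls back to spectral synthesis with a warning; for fGn with
H ∈ (0, 1) this does not occur in practice. H = 0.5 reduces to i.i.d.
Gaussian noise. `simulate_colored_noise()` synthesizes 1/f^β noise with
deterministic spectral amplitudes and uniform random phases.

Two calibration anchors tie the estimator to known ground truth and are
recomputed from scratch by `scripts/acceptance.R`: white noise (mean DFA
estimate ≈ 0.5 at T = 362 under the frequency-constrained scheme) and pink
noise (β = 1, mean estimate ≈ 1 at T = 4096 with log-spaced windows
16–512, consistent with H = (β + 1)/2). A periodogram-slope estimator
(H = (1 − slope)/2) serves as an independent oracle in the tests — it is
deliberately never a user-facing estimation path.

One testing subtlety: the fGn autocovariance invariant is checked with the
known-zero-mean estimator. The usual demeaned estimator is biased downward
by var(sample mean) ≈ n^{2H−2}, which at H = 0.9 and n = 512 is ~0.29 and
would fail any generator, including a perfect one.

## 3. Behavioral PLS

With X the subjects × parcels H matrix and Y the subjects × outcomes
matrix, both column-centered, the cross-block covariance X′Y is decomposed
as USV′. Columns are centered but **not** variance-scaled by default: the
decomposition is of the covariance, and a `scale_columns` flag provides the
correlation-PLS variant for users who want design loadings on the
correlation scale. The covariance explained by LV i is s²ᵢ/Σs²ⱼ. Signs are
fixed by flipping each LV so its largest-magnitude design loading is
positive.

**Weighted analysis.** With sampling weights w the weighted mean, variance
and covariance (population-style, Σw normalization) replace their
unweighted counterparts everywhere, so constant weights reproduce the
unweighted path exactly and duplicating a subject while halving its weight
changes nothing (both are tested identities). In the weighted permutation
test the weights travel with the permuted brain rows and multiply the
X-side deviations, while the denominator uses the (permutation-invariant)
total weight; the printed form of this estimator admits a reading with a
second weight on the outcome-side deviation, which double-counts weights
and breaks the equal-weights reduction, so the single-weight reading is
used.

**Inference.** LV p-values are rank-matched: the observed s_i is compared
with rank-i permuted singular values, p = (1 + #{s_perm ≥ s_obs})/(B + 1),
with rows of X permuted against a fixed Y. Bootstrap ratios are the
original loading divided by the standard deviation of its bootstrap
distribution, after matching each resample's LVs to the original by
maximal |dot product| of brain loadings with sign alignment (no Procrustes
rotation — with ≤ a handful of LVs greedy matching is stable and
reproducible). Under a null loading the BR is approximately standard
normal, so |BR| > 3 corresponds to p < 0.001; the tests verify both the
normality of null-parcel BRs and the type-I calibration of the permutation
p (≈ 0.05 at α = 0.05 across replicate null datasets).

## 4. Pattern scores and stable regions

The stable-region mask keeps parcels with |BR| > 3, carrying the loading
sign. A subject's pattern score is the Pearson correlation (Spearman
available) across parcels between their H map and the LV's brain loadings;
being a correlation it is invariant to affine rescaling of the subject's
map, which is what lets a model fit in one cohort score another (the tests
exercise this transfer with a second simulated cohort sharing the anatomy
but not the subjects). `mean_stable_h` averages H over all stable parcels
regardless of sign — in the planted world, as in the motivating analyses,
only negative-loading parcels are stable.

## 5. Spatial surrogates and spin tests

Correlations between brain maps inflate badly under naive permutation
because maps are spatially autocorrelated. The package's null generator
matches the empirical variogram (half the mean squared value difference
between parcel pairs, binned by centroid distance up to the median pairwise
distance — longer bins are sparse and unstable): each surrogate permutes
the source map, smooths it with k-nearest-neighbour exponential kernels
across a ten-value bandwidth grid (k from 3 to n_parcels/4), picks the
bandwidth and nonnegative affine combination
√a·smoothed + √b·noise whose variogram best fits the source's, and finally
rank-remaps to the source value distribution, so every surrogate holds
exactly the source's value multiset (rank statistics of the source are
exactly preserved). The spin p-value compares |r_observed| with the
surrogate correlations, two-sided by default, floored at
1/(n_surrogates + 1). Tests verify: variogram match > 0.9 for smooth maps
at realistic parcel counts, type-I ≈ 0.05 on independent equally smooth
maps where naive permutation over-rejects, and bit-identical surrogates
given (map, geometry, n, seed). Benjamini–Hochberg correction is routed
through `stats::p.adjust` behind `bh_adjust()`, with the hand-computed
step-up rule as the test oracle. True spherical-rotation nulls on cortical
meshes are out of scope — there is no surface geometry here.

## 6. Axes, sweeps, and block contrasts

`term_axis()` correlates every term map with the reference pattern,
assesses each against one shared surrogate ensemble of the reference map
(the ensemble is built once; terms are the family BH corrects across, at
α = 0.01), and splits survivors by sign. `combine_term_maps()` takes the
elementwise maximum z across a term set. `roi_sweep()` thresholds the
combined maps across a z grid (default 0.5–4 in steps of 0.05, finer than
any cutpoint one would report), computes each subject's mean-H difference
between the positive and negative ROI, and correlates it with scores —
Spearman by default, with subject-permutation p-values (1,000 by default)
rather than analytic ones, and explicit `empty`/`degenerate` flags instead
of silent zero-size means. `block_contrast_analysis()` applies the same
sweep logic to 2-back minus 0-back block-level H, correlating with d′,
accuracy and pattern scores, with subject-bootstrap standard deviations.
d′ is implemented verbatim as −2·erfc⁻¹(2·hit) + 2·erfc⁻¹(2·fa) — √2 times
the conventional z-difference — with a `conventional` flag; rates at 0 or 1
are clamped to 1/(2n) when the trial count is known (half-count
correction), else to a documented ε = 0.01.

## 7. Weights, Fisher intervals, cross-validation

`weight_model()` wraps an externally fitted linear predictor of inclusion
(the regularized fitter that produces it is deliberately pluggable and out
of scope); probabilities are logistic transforms and weights their
inverses. `assemble_weights()` multiplies streams elementwise with
provenance labels. `fisher_ci()` uses the tanh form
tanh(Z_r ∓ Φ⁻¹(1−α/2)·√(1/(n−3))), algebraically identical to the
exponential form, with the grouping read so that the interval is the
standard Fisher interval; coverage is verified by simulation.
`stratified_folds()` quantile-bins continuous covariates (4 bins — the
binning is a package choice), crosses them with categorical ones, and deals
subjects round-robin within strata with a running offset so fold sizes
balance globally. `crossval_pls()` refits per fold, correlates fold
loadings with the full-data pattern against its spin null, and computes
out-of-sample brain scores with training-fold centering only (no leakage).

A caution the tests make explicit: after shuffling outcome rows, fold
loadings do **not** drop all the way to spin-null behaviour. Any outcome
direction projected through X′ partially recovers the brain block's
dominant variance direction — which in a planted (or real) cohort is the
pattern itself — so the negative control is judged by its collapse relative
to the intact analysis (correlations fall from ≈ 1 to ≲ 0.5 and spin
p-values rise by an order of magnitude), not by an absolute p threshold.
This is a property of PLS cross-validation controls generally, not of this
implementation.

## 8. The synthetic cohort: what is planted, and what a green test means

`simulate_cohort()` draws, per configuration and seed, deterministically:

* **Latent severity** L_i ~ N(0, 1). Factor scores are
  loading·L_i + noise with design loadings (0.8, 0.1, 0.1, 0.55) over
  (general, externalizing, internalizing, ADHD) and noise SD 0.6, implying
  latent-factor correlations of 0.8 and 0.68 on the planted factors.
* **Baseline H** per parcel: 0.72 ± 0.06 across parcels (drawn with SD
  0.08, clamped to (0.5, 0.85)). The clamp keeps baseline + effect + noise
  inside the hard [0.05, 0.95] H bounds; letting the baseline approach
  0.95 clips several percent of cells and measurably attenuates planted
  pattern recovery, which is why the default sits lower than a 0.75 ± 0.08
  prior would put it.
* **Severity-to-H pattern**: true H is
  clamp(baseline_j − 0.08·loading_j·L_i + N(0, 0.05)), with loading_j =
  0.4 + 0.6·f_j, f a smooth (40 mm exponential-covariance) field scaled to
  [0, 1]. The pattern is deliberately brain-wide: a severity effect
  concentrated only on the task-relevant parcels would force the
  between-network H difference to *fall* with severity, contradicting the
  engagement mechanism below; distributing it lets both mechanisms coexist
  with the signs the analyses expect.
* **Cognitive set and suppression**: the top 30% of f defines the
  "cognitive" parcels. During 2-back blocks their H is further reduced by
  0.12·ability_i, with ability = −0.6·L + √(1−0.36)·noise. Able subjects
  suppress H under load; since ability is negatively coupled to severity,
  high-severity subjects fail to suppress — which is what makes the
  full-run cognitive-minus-other H difference and the 2-vs-0-back contrast
  rise with pattern scores while the contrast falls with d′.
* **Time series**: exact fGn per subject × parcel at the cell's true H;
  block-modulated parcels are built by concatenating condition-specific fGn
  segments per the block design (four 0-back and four 2-back blocks of 40
  frames with fixation lead/gaps in 362 frames), so block-level truth is
  well defined. Behavior: hit = logistic(1.4 + 0.8·ability),
  fa = logistic(−1.4 − 0.8·ability) (≈ 0.80/0.20 at mean ability, keeping
  d′ finite and monotone); 2-back accuracy and an out-of-scanner score are
  additional monotone functions of ability with noise.
* **Sampling structure**: five strata cut on a demographic proxy mildly
  correlated with severity, inclusion probabilities evenly spaced on
  [0.2, 1], weights their inverses; ~10% of subjects share a family id; an
  8-scale syndrome-like outcome set provides the alternate-outcome
  sensitivity run.
* **Geometry**: centroids uniform in a 140 × 170 × 120 mm box — brain-scale
  distances without anatomical files. Term maps are Gaussian random fields
  with exponential spatial covariance, z-scored, optionally mixing in
  ± the target pattern with a stated weight.

What the generator does **not** emulate: hemodynamics and task-evoked mean
signal (no HRF convolution), motion and physiological artifacts, voxel
space and parcellation (everything is parcel-level), multiple scanner
sites, non-Gaussian heavy-tailed behavior distributions, and any
multifractality — the series are exactly mono-fractal within condition. A
green recovery test therefore establishes that the estimators and inference
machinery do what they claim on data satisfying their assumptions; it does
not validate those assumptions against real BOLD data, and effect sizes in
the planted world are chosen for desk-scale statistical detectability, not
to mimic the published effect magnitudes (which depend on restricted-access
cohorts three orders of magnitude larger).

## 9. Known limitations

* DFA assumes a single scaling regime; the package reports R² but offers no
  multifractal spectrum estimation.
* The surrogate generator matches variograms approximately through a fixed
  kernel family; it is a fully specified, testable stand-in for
  variogram-matching null generators, not a reimplementation of any
  particular one, and it operates on parcel centroids, not cortical
  surfaces.
* The weighted-PLS permutation scheme follows one literal reading of its
  printed estimator (see §3); the alternative reading is not provided.
* Whether the original analyses z-scored columns before the decomposition
  is not knowable from the description; both paths exist here
  (`scale_columns`), with covariance-PLS the documented default.
* Fold-wise PLS controls retain dominant-direction leakage (§7); spin
  benchmarks for fold stability should always be read alongside the
  planted/intact comparison.

```{r example, eval = FALSE}
# End-to-end run at desk scale (about a minute):
res <- run_pipeline(cohort_config(n_subjects = 60, n_parcels = 24,
                                  seed = 101),
                    n_perm = 300, n_boot = 300, n_terms = 30,
                    k_folds = 5, seed = 2)
res
glance(res$model)
autoplot(res$model)
```
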