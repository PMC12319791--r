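---
title: "From dynamic emotion ratings to regional brain responses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dynamic emotion ratings to regional brain responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

emokinetics implements an analysis chain for naturalistic movie-viewing
fMRI in which observers continuously rate both the emotions they *perceive*
in the characters and the emotions they *feel* themselves, and the
resulting dynamic emotion models are related to region-of-interest (ROI)
BOLD time series. This vignette explains each stage's model, the
parameters that matter, and the design decisions taken where the
procedure left genuine freedom. A bundled synthetic-data generator with
known ground truth makes every stage testable end to end; its assumptions
— and therefore what a passing test does and does not establish about
real data — are described at the end.

## 1. From segment ratings to design matrices

Raters score each emotion's intensity (0 = not at all to 4 = extremely
much) over short 3–10 s segments while viewing movie clips. Within a clip
the continuous trace is reconstructed by linear interpolation through the
successive segment end-points, anchored at zero at the clip's first
moment; traces are never interpolated across clip boundaries, and after
the last end-point the trace is held constant. Time is discretized at the
scanner's TR (2.4 s) with sample *i* covering `[i·TR, (i+1)·TR)` and its
nominal time at the left edge — one convention had to be fixed; the left
edge keeps a clip's first sample exactly zero whenever clip onsets align
with the grid.

The neural regressor for an emotion is the rater-mean trace convolved
with a hemodynamic response function (HRF). Because the ratings evolve
slowly and their sampling is coarse, the HRF is a *single* gamma density
without the post-stimulus undershoot of canonical double-gamma models.
The gamma's shape (6) and scale (1 s) give a peak at 5 s — a standard
peak latency — and are exposed as parameters of `hrf_kernel()` because
the procedure fixes only the functional form, not the constants. The
kernel is normalized to unit sum so that convolution preserves the rating
scale's DC level and fitted weights stay interpretable in rating units.
Averaging raters before convolution versus after is immaterial (the
operations commute); the package averages first and keeps per-rater
series only for the reliability stage.

## 2. Rating reliability screening

Not every candidate emotion is reliably evoked by movies. Three
per-emotion, per-task measures are computed for each run and averaged
across runs with equal weights:

* `pct_raters` — fraction of raters giving any non-zero rating;
* `pct_timepoints` — fraction of TR samples with a non-zero rating from
  at least one rater;
* `mean_isc` — mean Pearson correlation of the TR-gridded
  (pre-convolution) rating series over all rater pairs.

The combined statistic is the geometric mean of the three run-averaged
components. All components are kept on `[0, 1]`-comparable scales
(fractions; the correlation clamped at zero before the product), because
a geometric mean of mixed-scale quantities is scale-dependent — the
procedure's description leaves this normalization open, so it is fixed
here and should be kept in mind when comparing absolute values. A
non-positive component yields a combined value of exactly 0; ISC pairs
with a constant series are dropped, and an emotion with no defined pair
scores 0. Each emotion's selection value is the larger of its two tasks'
combined values, so an emotion consistently rated in at least one task
survives.

The chance level is estimated by permutation: in each iteration the
values of each component are shuffled between emotions — independently
for each component, run and task — and the whole reliability computation
(across-run mean, geometric mean) is repeated. The threshold is the 95th
percentile (linear interpolation between order statistics, fixed
package-wide) of the pooled null values across iterations, emotions and
tasks. Shuffling *before* the across-run average matters: run-level
shuffling lets the null concentrate around chance-level component
combinations, whereas permuting the already run-averaged component
vectors merely reshuffles the observed products, producing a null whose
upper tail coincides with the observed distribution's own upper tail and
a screen with essentially no sensitivity. For single-run panels with few
emotions, `reliability_threshold(method = "exhaustive")` enumerates all
permutation triples exactly.

The temporal similarity of felt and perceived ratings of the same
emotion (`felt_perceived_similarity()`) is the Pearson correlation of
the two rater-mean series concatenated across runs, reported with its
square as shared variance.

## 3. Conditioning the ROI time series

Each participant's ROI series is conditioned in a fixed order: percent
signal change (`100·(y − mean)/mean` per ROI), nuisance regression, then
bandpass filtering.

The nuisance design contains the white-matter and CSF signals, the six
motion parameters, their squares (second-order effects), a linear trend
and an intercept; residuals are computed by QR projection and rank
deficiency is reported with the offending columns.

The bandpass matches the frequency content of slowly evolving emotion
episodes (20–100 s): passband 0.005–0.05 Hz (periods 200 down to 20 s).
The filter is an equiripple linear-phase FIR designed by the
Parks–McClellan (Remez exchange) algorithm with at most 1 dB passband
ripple and at least 40 dB attenuation in the upper stopband, which
begins at 0.0613 Hz. On the DC side, a bandpass whose passband sits this
close to 0 Hz cannot reach 40 dB at any reasonable order at a 2.4 s
sampling interval; the design therefore requires only ≥ 20 dB rejection
at 0 Hz (the lower transition runs from 0.001 to 0.005 Hz). The order is
increased in steps of 10 until the measured magnitude response on a
4096-point grid satisfies all three bounds; with the default bounds this
terminates at order 80 with 40.4 dB stopband attenuation and 0.95 dB
ripple. Application is zero-phase (two passes of the centered symmetric
convolution, equivalent to forward–backward filtering), so regressors
and BOLD stay temporally aligned; bounds are always quoted for the
single-pass response, and samples within half a kernel length of the
edges are flagged.

Two conditioning subtleties surfaced during development and are worth
stating plainly:

* **Matched design filtering.** The encoding fit is only consistent if
  the design matrix passes through the same filter as the BOLD
  (`filter_designs()`, on by default in the pipeline): clip-scale rating
  energy below the 0.005 Hz edge survives in an unfiltered design but
  not in the filtered BOLD, and the mismatch biases the weights
  substantially (measured ground-truth recovery r 0.49 unmatched versus
  0.97 matched at SNR 5).
* **Single-emotion mapping uses unfiltered regressors.** A narrowband
  series chance-correlates with its own circular shifts at |r| up to
  ~0.6, so shifting a *filtered* regressor does not produce a null
  surrogate; the mapping stage therefore correlates conditioned BOLD
  against the raw convolved model series.

## 4. Cross-validated encoding and decoding

All fits are ordinary least squares after removing the means of signals
and models (`fit_linear_map()`, minimum-norm on rank deficiency). Two
generalization schemes are used, mirroring the study layout of five runs
and fifty participants:

* **Between runs** (`between_run_cv()`): for each of the
  `choose(5, 3) = 10` train/test partitions, the full design of reliable
  emotions (one task) is fitted to the across-participant mean of the
  standardized training-run series; the predicted test-run series is
  scored against every individual participant's series (Pearson r per
  participant and ROI), and scores are averaged over partitions.
  Decoding reverses the roles: mean ROI activity predicts each emotion's
  rating series, scored per emotion on the held-out runs, with a null
  distribution from refitting after shuffling the training emotion
  labels within each split (per iteration, the maximum score over
  emotions is recorded; the default threshold is the 95th percentile of
  these maxima).
* **Within runs / across participants** (`within_run_cv()`): 10-fold
  cross-validation over participants (training sets of 45 with the study
  sizes), each fold crossed with every run partition. Uneven folds
  differ by at most one, assigned by seeded shuffle.

"Standardized" activity is implemented as demeaning within run combined
with **one pooled per-ROI scale per participant computed from the
training runs of the current split**. This choice is load-bearing twice
over. A per-run scale makes the training runs' targets mutually
inconsistent — the same weights cannot reproduce two differently scaled
copies of the same ROI — and demonstrably breaks the noiseless limit (in
which test correlations must be exactly 1 and recovery exact). A scale
pooled over *all* runs leaks test-run amplitudes into the training fit.
Training-run pooling is the unique option that is both self-consistent
and leakage-free.

The felt-versus-perceived contrast (`contrast_tasks()`) is a paired
t-test per ROI on participant-level fits, with family-wise error
controlled by the maximum statistic over ROIs under per-participant
random swapping of the felt/perceived order (equivalently sign-flipping
each difference); the threshold is the 95th percentile of the maxima. A
caution established on pure-noise simulations: fits *averaged over all
run partitions* carry a small positive cross-participant dependence,
because each run serves as test set in one partition and training set in
others, so one participant's test noise enters every other participant's
score through the shared group fit of another partition. On null data
this inflates the paired t (family-wise error 17/100 at nominal 5 with
eight participants); single-partition fits are calibrated (2/100). With
realistic between-participant variance the term is negligible, but
exactness of the sign-flip test is only guaranteed for fits from a
single partition.

`beta_recovery()` compares estimated with generative weights after
inverting the known standardization scale; at SNR 5 and the study's
temporal layout the recovery correlation is ≈ 0.97.

## 5. Single-emotion mapping with circular-shift nulls

For each ROI, emotion, run — and the average across runs — a one-sample
t-test across participants asks whether the correlation between the
single emotion regressor and the ROI series is consistently non-zero.
t-tests run on Fisher-z-transformed correlations (variance
stabilization; a raw-r mode exists). The null respects the regressors'
autocorrelation: each emotion receives `n_shift` surrogates made by
circular rotation by at least `min_shift = 20` samples forward or
backward (draws uniform on `[min_shift, n − min_shift]`), which
preserves the value multiset and the circular autocorrelation exactly.
Each permutation iteration pairs a random emotion-label permutation with
one random surrogate per emotion, recomputes every t, and saves the
maximum absolute value over the whole map; the two-tailed threshold is
the 97.5th percentile of these per-iteration maxima. Pooling per-emotion
maxima instead is measurably anti-conservative (12–14/100 family-wise
false positives versus 7/100 at nominal 5), because per-emotion max
distributions are heterogeneous.

A structural limitation, established analytically and by simulation:
when a cell's across-participant variance is dominated by amplitude
variation of the stimulus-locked component itself, a circular shift
scales the null correlation's mean and its across-participant sd by the
same chance-alignment factor, so the strongest cell's null t reproduces
its observed t and the family threshold tracks the maximum observed
statistic. Consequently the mapping has excellent specificity (zero
false positives in the planted-effect simulations; the planted emotion
always produces the top-ranked cell) but detects only cells close to the
map's maximum. In real data, where idiosyncratic in-band activity
dominates each participant's series, the regime is more favorable; on
strongly stimulus-locked synthetic data the conservatism is inherent.

`activation_extent()` summarizes a signed significance mask as counts
per emotion and signed fractions per macroanatomical region.

## 6. Cross-run similarity and clustering

The spatial pattern a condition evokes is compared *only across
disjoint run sets* (the training and test sets of each partition):
within-run pattern correlations are circular, being driven directly by
the rating correlations. For each partition, condition patterns —
participant- and run-averaged Fisher-z correlation maps — from the
training set are correlated across ROIs with patterns from the test set;
the matrices are averaged over the 10 partitions and symmetrized as
`(M + t(M))/2`, keeping the asymmetric original. The diagonal is each
condition's between-run reliability and is deliberately not forced to 1.
A generalized two-sided Dice index of thresholded signed maps
(`generalized_dice()`) provides a complementary overlap measure.

Correlation-map patterns have a known limitation: each map mixes the
condition's own pattern with every correlated regressor's pattern, plus
a positive floor from shared occupancy structure. On synthetic data with
planted pattern blocks this caps partition recovery whenever two blocks'
regressors happen to correlate. `cross_run_beta_similarity()` therefore
offers patterns built from the *jointly fitted* full-model weights,
which attribute shared variance instead of bleeding it; with those, the
planted partition (k = 2–4 blocks, within-block pattern correlation
0.8) is recovered with adjusted Rand index 1.0 in every tested seed at
SNR 5.

Clustering is the same code path for the rating-space matrix (temporal
correlations of the model time series across runs and tasks) and the
neural matrix: distances `d = 1 − s` (the simplest monotone map),
average-linkage (UPGMA) agglomeration via `stats::hclust`, leaves
ordered to maximize the summed similarity of adjacent leaves by dynamic
programming over the tree (ties broken lexicographically), and a cut at
70% of the maximum linkage height. Merges at or above the cutoff are
excluded (strict inequality, so a cut fraction of 1 does not join the
top merges); conditions left alone are labeled 0, unclustered. Felt and
perceived conditions enter one joint clustering with the task encoded in
the condition label.

## 7. The synthetic-data generator

`simulation_spec()` defaults mirror the study layout: 16 raters, 63
emotions (46 generated as reliable), 2 tasks, 5 runs of 575 TRs at
TR 2.4 s with 7–8 clips per run and 4 fixation TRs at each end, 50
participants, 273 ROIs. Where the study fixes no value, the defaults are
chosen once as plausible for this kind of data and documented here:

* `occurrence_rate = 0.3` — a reliable emotion occurs in about a third
  of clips, as an *episode* of 20–100 s (matching the stated range of
  emotion event lengths), not as whole-clip occupancy; episodes are
  piecewise-linear walks over 3–10 s segments, clipped to the 0–4 scale.
* `rater_agreement = 0.7` — each rater's trace mixes the shared latent
  episode with an idiosyncratic episode (own occurrence draw and own
  timing) at this weight, so agreement 1 gives identical raters and
  agreement 0 fully independent ones. Unreliable emotions are rated
  sparsely by 2–4 random raters with fully idiosyncratic profiles.
* `task_coupling = 0.8` — felt and perceived latent profiles of the same
  emotion share episode timing and are mixed in intensity.
* BOLD forward model: `y = baseline + X·beta_p + AR(1) noise + linear
  drift + scaled motion confounds`, with participant weights
  `beta_p = beta·(1 + gain_p) + tau·G_p` (`gain` sd 0.2; `tau` is
  `participant_beta_sd = 0.5` times the RMS of the non-zero group
  weights). The additive deviations are what keep across-participant
  consistency below 1 even without noise; they scale with the group
  weights, so a null (all-zero beta) dataset is pure noise and the
  lag-1 autocorrelation of its series equals `ar_coefficient` (0.4).
* Motion confounds are stationary slow AR(1) drifts plus scan-to-scan
  jitter. A random-walk motion model was rejected: random walks
  spuriously regress against any slow signal, and nuisance regression
  then removes most of the in-band stimulus-locked variance.
* `snr = 1` by default (`sd(group signal)/sd(noise)` per ROI); recovery
  and clustering guarantees are stated at SNR 5.

What the generator does *not* emulate: voxel-level structure,
hemodynamic nonlinearity and HRF variability, physiological
(cardiac/respiratory) noise, spatially correlated noise between ROIs,
rater-specific segmentation grids, and the dominance of idiosyncratic
ongoing activity that makes real across-participant consistency low.
Passing tests therefore establish the *procedures*' correctness and
calibration under a known forward model, not effect sizes or detection
rates to be expected on real recordings.

## 8. Problem sizes and numerical conventions

The test suite and the reference computations run at reduced sizes
chosen to keep the full suite in the tens of minutes on one CPU: ground
truth recovery uses 20 participants and 60 ROIs at the full temporal
layout (5 × 575 TRs, 63 emotions); cluster recovery uses 12 conditions,
100 ROIs, 12 participants; the type-I simulations use 100 pure-noise
replicates with 200 permutations each at small spatial sizes. Percentile
estimation everywhere is linear interpolation between order statistics
(R's type 7), documented and fixed so permutation thresholds are
reproducible. All stochastic stages draw from seed-derived private RNG
streams, so identical configurations produce identical outputs without
disturbing the caller's RNG state. Degenerate cells (constant series)
yield NA correlations that are excluded and flagged, or 0 where a
conservative value is required (decoding scores, Fisher-z inputs).
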