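---
title: "circuitscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circuitscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitscope)
```

circuitscope re-implements, as tested and reusable R functions, the
quantitative procedures used to study how the neuronal circular RNA Cdr1as
buffers miR-7 activity in cortical neurons: smFISH colocalization and
density quantification, presynaptic glutamate-release trace analysis,
multi-electrode-array (MEA) network metrics, miRNA target expression
statistics, and two-step random-forest gene-regulatory-network inference.
Every stage has a matched synthetic-data generator with recorded ground
truth, so the whole pipeline can be exercised and scored without any
external data. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic benchmarks do and do not
demonstrate.

## smFISH colocalization

**Spot-to-structure distances.** The protein channel is binarized with
Otsu's threshold (256-level histogram over the full image range; pixels
strictly above the threshold form the mask) and turned into a Euclidean
distance map: each pixel holds the distance in px to the nearest structure
pixel, exactly 0 on the structure. RNA spots are detected upstream with
subpixel precision, so the distance at a spot is read off by bilinear
interpolation of the 1, 2 or 4 surrounding pixel-center values. The
coordinate convention is 0-based pixel centers at integer coordinates,
origin at the top-left; valid spot coordinates span `[0, width - 1]`.
Distances convert to microns via the pixel size, default 0.215 um/px
(100 px = 21.5 um at the imaging scale used for these preparations); the
value is overridable everywhere it enters.

**RNA-RNA colocalization.** Two spot fields are compared by mutual nearest
neighbors (MNN): pairs `(i, j)` where each is the other's nearest neighbor,
distance ties broken toward the lowest spot id (the choice is arbitrary and
only matters on exactly tied distances). The observed statistic is the
fraction of MNN pairs at or below a distance threshold, with the median MNN
distance reported alongside; the null is built by re-placing the second
species uniformly at random within a region mask `n_random` times (default
1000, minimum 100), and the p-value is `(1 + #(null >= obs)) / (1 + n_random)`,
which is valid (never anti-conservative) for any number of
randomizations. The underlying "probability of random association" method
is published only in outline; the fraction-below-threshold statistic and
the uniform re-placement null are this package's documented concretization.
Cumulative MNN-distance curves for the test and null are returned for
plotting.

**Densities.** Spot counts per (cell, compartment) are normalized by area
(`spots / (area_px2 * pixel_size^2)`) or, when a length column is supplied,
per micron of neurite. Both modes exist because compartment quantification
is reported per area for somas but per length for neurites in this
literature; the function does not guess which is intended.

## Glutamate-release traces

Traces are presynaptic fluorescence time series from a glutamate sensor,
imaged continuously at 20 Hz; the evoked protocol is 20 field stimuli at
0.5 Hz. Active synapses are found as local maxima of the temporal first
derivative of the stack (3-frame moving average plus 1 px Gaussian spatial
smoothing, both configurable; thresholded at median + 5 MAD), each expanded
to a disc ROI of radius 4 px (49 pixels; 700 nm at this magnification), and
traces are ROI means per frame.

**Event detection.** The baseline is a running median with a 2 s window;
the noise SD is 1.4826 x MAD of the residual, floored at a scaled machine
epsilon so constant traces cannot divide by zero. Events are strict local
peaks of the residual exceeding `k_sigma` (default 7) times the noise SD,
with a one-frame refractory period; the refractory rule and the peak
definition are implementation choices, as the source procedure specifies
only the 7-sigma amplitude rule. At 7 sigma the Gaussian exceedance
probability is ~1e-12 per frame, so pure-noise traces should yield
essentially no events; the test suite asserts < 1 false positive per 1e4
frames.

**Release statistics.** Spontaneous frequency is the event count divided by
the acquisition duration (default 300 s). Evoked probability counts the
stimuli followed by at least one event exactly one frame after the stimulus
frame (50 ms at 20 Hz; the window width is configurable for sensitivity
analysis) divided by the number of stimuli, so it is always a multiple of
`1/n_stimuli`. Spontaneous contamination of evoked windows is not
subtracted — with the default rates it contributes ~0.0015 to the
probability, an order of magnitude below the sampling error at the tested
scales. Distributions are summarized by a Gaussian KDE with Scott's
bandwidth (Silverman optional); zero-fluorescence synapses are expected to
be removed upstream.

**Secretion assay.** The luminescence standard curve (calibration points
spanning 100 uM down to 1.28e-3 uM) is fitted by ordinary least squares and
inverted for interpolation; values outside the calibrated range warn. A
log-log option exists because the calibration spans five decades, where a
linear fit is dominated by the top points.

## MEA network metrics

Spikes are detected on voltage traces (12.5 kHz) as crossings of six times
the robust noise SD (1.4826 x MAD around the median — "estimated noise" is
otherwise unspecified) with a 1 ms refractory period. Electrodes below
5 spikes/min over the 600 s analysis window are dropped; the boundary is
inclusive. Single-electrode bursts use the fixed-ISI method: maximal runs
with inter-spike intervals at most 100 ms and at least 5 spikes (common
defaults for this hardware's analysis suite, which does not publish its
algorithm); burst duration is last minus first spike.

**Network bursts** pool all well spikes into 20 ms bins; a network burst is
a maximal run of occupied bins of at least `min_bins` (default 2) in which
at least 25% of the electrodes fire. The participation and run-length
minima are this package's choices; only the 20 ms bin is given by the
source procedure.

**Asynchrony** is the area under the well-wide pooled inter-electrode
cross-correlogram. The correlogram is built from the signed time difference
between each spike and the *nearest* spike of the other electrode in each
ordered pair, pooled well-wide at 20 ms resolution over +/-1 s lags, and
normalized so the zero-lag bin equals 1 (peak-bin fallback when the
zero-lag bin is empty, e.g. for trains offset by exactly one bin). The
nearest-spike formulation is deliberate: it makes the printed limit exact —
identical trains put every difference at lag zero, so the area is exactly
0 ("perfect synchrony") — whereas an all-pairs correlogram of Poisson
trains at 1 Hz would scatter adjacent-spike mass across nonzero lags and
could never reach 0. The metric increases monotonically with independent
per-electrode time jitter (property-tested via Spearman correlation over a
jitter grid).

**Oscillation** is the mean, across network bursts, of the coefficient of
variation of the pooled inter-spike intervals inside each burst window.
The SD convention is the population SD (divide by n), which matters for
small bursts and is therefore stated: ISIs {1, 1, 3, 3} give CoV 0.5.
Constant ISIs give 0; exponential ISIs give 1 (the implementation follows
the SD/mean formula as printed and encodes no further interpretation).
**Burst peak** aligns network bursts at onset, averages the pooled per-bin
counts (zero-padded to the longest burst) and divides the peak by the bin
width. Pre/post-treatment deltas subtract per-well metrics; genotype
comparisons are a thin utility over one-way ANOVA with Bonferroni-corrected
pairwise t tests.

## Expression statistics

Housekeeping normalization scales every sample by (grand geometric mean of
the housekeeping counts) / (sample geometric mean), with Actb, Tubb5 and
Vinculin as the default panel. The geometric mean is the convention of
count-based expression panels and makes the operation idempotent; a sample
globally scaled by c gets a factor 1/c relative to the others, restoring
all column ratios. Log2 fold changes use a pseudocount (default 1) on both
group means. The comparative ddCT method is implemented exactly:
`RQ = 2^-(dCT - mean(dCT_control))`.

Target lists are intersected across two prediction databases after
case-folding and stripping version suffixes; only genes present in both are
kept. The target CDF-shift test compares the log2 fold changes of predicted
targets against genes lacking predicted sites with a two-sided Mann-Whitney
U test (exact for small tie-free groups, normal approximation with tie
correction otherwise), returning both empirical CDF supports for the
cumulative plots. The background defaults to all non-target genes, with a
`de_only` flag restricting it to significant genes, because the two
published descriptions of the comparison differ on this point. DE filtering
applies strict inequalities — adjusted p below 0.05 and |log2FC| above
0.5 — matching the stated thresholds; a gene sitting exactly on either
boundary is excluded.

`simple_de_test` is deliberately a plain per-gene linear model (via limma)
on log2 normalized counts with an optional batch covariate and BH
adjustment. It exists so the downstream stages are self-contained on count
matrices; it is not a negative-binomial DE engine and makes no dispersion
shrinkage claims.

## Two-step random-forest network inference

Step 1 regresses each phenotype-related gene on a candidate regulator pool
with a random forest and keeps the top 10 predictors per response;
candidates appearing in the top-10 lists of at least two phenotype genes
become intermediate regulators. Step 2 repeats the procedure with the
intermediates as responses and the miR-7 target list as candidates (the
orientation is an interpretation of "connected to"; the reverse regression
is available via `direction`). Every retained response is validated by
leave-one-sample-out cross-validation: RMSE over folds, and the cosine
similarity between the vectors of (prediction - training-fold mean) and
(truth - training-fold mean) — "difference relative to the training
examples" is read as difference from the training-fold response mean, one
scalar per fold.

Forest settings: 1000 trees, `mtry = p/3` (the classical regression-forest
default; the sqrt(p) default of some implementations ranks essentially by
marginal correlation at small sample sizes), and out-of-bag *permutation*
importance. Permutation importance was chosen over impurity importance
after the impurity variant was observed to promote the same
high-sample-variance decoy genes across unrelated responses — a known bias
that directly corrupts the top-k overlap rule. Ranking ties are broken
alphabetically; every forest is deterministic given the stage seed, and
stage seeds fan out deterministically from a single pipeline seed.

## Synthetic data: what it emulates and what it does not

The generators define the benchmark conditions used throughout the tests:

- **Spot fields**: exactly `round(n * f)` spots on uniformly sampled
  structure pixels plus Gaussian subpixel jitter, remainder uniform over
  the frame; dual fields plant a fraction of B spots on A positions. No
  optics: no PSF, no detection noise, no segmentation errors — passing
  tests show the geometry and statistics are right, not that spot
  detection on real images would be.
- **Release traces**: Gaussian baseline noise plus events with an
  instantaneous rise (in units of the noise SD) and exponential decay,
  default time constant 2 frames (100 ms at 20 Hz, the qualitative decay
  scale of the glutamate sensor); evoked events occur with probability
  `evoked_p` exactly one frame after each stimulus, spontaneous events are
  Poisson. No bleaching, drift, or motion. Benchmarks use 500 synapses,
  300 s, `evoked_p = 0.4`, `spont_rate = 0.05 Hz`, amplitude 10 sigma —
  a high-SNR regime in which detection is essentially lossless, so the
  recovery test scores the estimators, not the detector.
- **Spike trains**: homogeneous Poisson background; `identical` copies one
  train to every electrode (the perfect-synchrony limit); planted
  single-electrode bursts are evenly spaced so inter-burst gaps dwarf the
  burst-detection ISI threshold and recovery can be exact; network bursts
  add per-electrode Gaussian onset jitter. Within-burst spike statistics
  of real cultures are not modeled.
- **Count matrices**: negative-binomial counts around lognormal baseline
  means, a planted log2 fold change on a designated target set in the
  overexpression condition, and per-(gene, batch) multiplicative effects.
  Real library-size variation and count outliers are not modeled, which is
  why the internal DE stage is a linear model rather than an NB engine.
- **Regulatory expression**: root-tier targets i.i.d. standard normal,
  children as weighted sums of parents plus Gaussian noise, decoys
  independent. The planted network uses orthogonal intermediate and
  phenotype pairs: each driving node keeps out-degree 2 (so the top-10 +
  overlap rule can in principle recover it) while the response tiers stay
  mutually uncorrelated, which keeps spurious overlap keeps near the
  chance level. Benchmarks use 8 + 8 + 600-gene tiers, 1000 decoys, 40
  samples, noise SD 0.1 (about 5% of the response SD).

## Numerical choices and degenerate inputs

- Otsu's threshold requires two distinct intensity values; constant images
  error. The Euclidean distance transform is exact (verified against an
  all-pairs oracle to < 1e-9 px on hundreds of random masks).
- Bilinear interpolation never leaves the [min, max] envelope of the four
  surrounding pixels; spots outside the map error with their spot id.
- The event detector floors the noise SD at a scaled machine epsilon;
  traces with NAs error rather than guess.
- The randomization p-value includes the +1 correction, so it can never be
  0 and is exact under the null up to discreteness of the fraction
  statistic.
- The asynchrony correlogram falls back to peak-bin normalization when the
  zero-lag bin is empty, and reports missing when no pair has any
  coincidence within the lag window.
- Burst IBI with fewer than two bursts is reported missing, not zero.
- LOSO cosine is reported missing when either difference vector is
  identically zero.

## Benchmark scales and known limitations

Test and benchmark sizes were chosen so the full suite exercises every
stage at statistically meaningful scale on a single CPU: 1000-replicate
calibration loops for the colocalization and Mann-Whitney tests (observed
type-I rates sit at the nominal 0.05), 500-synapse release recovery,
200-mask distance-transform oracles, and a 1600-gene network benchmark.

Two limitations are worth stating plainly. First, random-forest regression
is piecewise-constant: even on noiseless linear responses at 40 samples,
leave-one-sample-out RMSE is ~0.3-0.5 of the response SD (and the
difference-vector cosine correspondingly ~0.85-0.9), an interpolation bias
that no tree count removes; LOSO scores should be read as relative rankings
between models, not as absolute error floors. Second, the top-10 +
overlap-2 network rule at 40 samples is intrinsically noisy: with ~32
planted edges, a single chance overlap keep moves precision by ~6% and a
single dropped degree-2 node moves recall by ~19%, so recovered networks at
this scale should be treated as hypothesis sets, which is also how the
original analysis treated them (validating proposed connections against
external interaction databases).
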