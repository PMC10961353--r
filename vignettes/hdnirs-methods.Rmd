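---
title: "hdnirs: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hdnirs: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hdnirs` implements an analysis pipeline for high-density continuous-wave
fNIRS recordings of a short (2-s) left/right hand motor-imagery task:
montage geometry, a synthetic cohort generator, causal preprocessing,
signal-quality scoring with poor-quality (PQ) session partitioning,
block-average hemodynamic response estimation, a subject-independent
spatio-temporally regularized decoder with five reference decoders, and a
demographic factor-analysis battery. This vignette explains the models, the
tunable parameters, and the design decisions that were genuinely open.

# Montage geometry

The montage is a flat head-surface approximation (mm; x left to right,
y posterior to anterior). Twelve rigid tiles — six per hemisphere in a
2 x 3 grid — each hold 3 dual-wavelength sources (735/850 nm) and 4
detectors, giving 36 sources, 48 detectors, 1728 source-detector pairs and
3456 wavelength-resolved channels. Exact tile coordinates are not a claim
of fidelity to any vendor layout; they are a parameterized configuration
(`defaultGeometryConfig()`) whose default pitches (column 14 mm, row 40 mm,
hemisphere offset 33 mm) were chosen once so that the *tile-averaged*
channel census matches the emulated headset: 44 tile-pair channels of
15-60 mm center-to-center length (22 per hemisphere) and 36 dual-wavelength
tile pairs in the 25-45 mm band, with all cross-hemisphere tile pairs
longer than 60 mm. The motor region of interest (ROI) on each hemisphere is
centered on the two innermost posterior tiles; channels are ROI-labeled
when their midpoint lies within `roiRadius` (default 25 mm) of an ROI
center. The channel depth proxy is length/4, the convention used when
weight maps are plotted at depth.

`reducedMontage()` is the desk-scale variant used by the simulation
studies: one enlarged tile per hemisphere over the motor ROIs with optode
offsets scaled 3x, so source-detector separations span the cortically
sensitive 16-40 mm range (96 wavelength-resolved channels, 48 pairs at or
under 50 mm). Full-montage (3456-channel) simulation is supported by the
generator but the packaged studies run at this reduced dimensionality;
problem sizes used by the tests are 8-tile montages for block averaging and
quality partitioning (768 and 384 channels) and the reduced montage for
decoding.

# Task schedule

A session is a 2-min baseline followed by 4 blocks of 30 trials separated
by 30-s breaks. Each 17-s trial is 5 s rest, 2 s imagined tapping (the
marker is placed at tapping onset), 8 s rest and 2 s feedback. Session 1
splits each block into two sub-blocks of 13 imagined trials followed by 2
executed ("overt") trials, so it has 104 covert + 16 overt trials; sessions
2-3 have 120 covert trials. Left/right labels are balanced within every
block (covert and overt subsets separately) and pseudo-randomized by seed.
Sample indexing is 0-based with half-open time windows [t0, t1) throughout.

# Synthetic data generator

The generator is a two-compartment forward model, not a photon-transport
simulation. Its purpose is to give every pipeline stage a testable input
with the statistical structure the analysis assumes.

**Hemodynamics.** The planted response kernel is a double-gamma HRF
(positive-lobe peak 7 s, undershoot ratio 1/6) convolved with the 2-s task
boxcar and peak-normalized; the resulting HbO response peaks 8.0 s after
tapping onset (stored as `response_peak_s`). An optional initial dip
(default 12% of peak, 2.5 s) subtracts an early negative HbO lobe. Left-hand
trials drive the right motor patch at `amp_hbo` (default 0.35 uM) and the
left patch at `ipsi_ratio` = 0.4; HbR is `hbr_ratio` = -0.3 times the HbO
response with a 1-s washout lag and no dip. The lag matters: if HbR were an
exactly proportional copy of HbO, the two chromophore features would be
perfectly collinear carriers of one latent signal, a degenerate corner no
real dataset occupies. The default amplitude was fixed once so that
subject-independent decoding on a mild-hair cohort is modestly above chance,
which is the regime the method targets; it was not matched to any reported
accuracy. Cortical patches are spatial Gaussians (scale 20 mm) at the ROI
centers; a shared superficial compartment (default 0.3 uM) carries systemic
physiology into short channels via the depth weights
`superficialWeight(L) = exp(-L/30)` and
`corticalWeight(L) = L^2/(L^2+25^2) * exp(-(max(L-50,0)/8)^2)` — smooth
functions of channel length standing in for photon-path partial volumes.

**Noise.** Per-channel OD random-walk drift, montage-wide cardiac
(~1.2 Hz, jittered), respiration (~0.25 Hz) and Mayer (~0.1 Hz)
oscillations with per-channel gains, white OD noise, and montage-correlated
motion spikes and baseline shifts. Intensity is
`I0 * 10^(-L/15mm) * c_src * c_det * exp(-OD)` plus a 100-count dark floor
and additive detector noise (sd 50 counts). The light-level-independent
detector noise is what makes long and weakly coupled channels
noise-dominated, reproducing the characteristic coefficient-of-variation
falloff with channel length (sigmoid midpoint between 25 and 60 mm for
well-coupled sessions).

**Coupling and hair.** Per-optode coupling is log-normal with location
decreasing in the subject's hair-severity index (weighted mean of hair
length, darkness rank and density ordinals). Subjects at severity >= 0.65
receive a hard coupling ceiling of 0.015 — the PQ profile, in which
essentially no light couples through the hair and every channel beyond
25 mm exceeds 15% CoV. Subject factors are drawn once per subject and held
fixed across sessions (alertness varies per session).

**What the generator does not emulate.** Anatomy and photon transport;
trial-to-trial response variability beyond additive noise; non-stationary
coupling (cap shifts within a session); task-correlated systemic responses;
and the richer chromophore dynamics of real hemodynamics. Consequently,
passing tests demonstrate that the pipeline recovers the structures the
generator plants, not that real-data effect sizes would be reproduced.

# Causal preprocessing

All decoding-path transforms are strictly causal (output at t depends only
on samples <= t), verified by truncation tests.

* **Optical density.** `OD = -log(I/ref)` with the reference either the
  whole-session mean, the first-60-s mean, or a causal running EMA (forget
  0.01). Intensities are clamped at `1e-9 *` the channel median before the
  log; non-positive channels raise an error.
* **MACD bandpass.** Signal minus its slow EMA (forget 0.01), then a causal
  2-s rectangular moving average (zero-padded start); effective group delay
  about 1 s. Its impulse and frequency responses are pinned against
  analytic oracles.
* **Butterworth filtering.** Bandpasses are realized as a high-pass
  (order 2) plus low-pass (order 4) cascade because a single IIR bandpass
  spanning 0.02-2 Hz at 10 Hz sampling is numerically marginal; offline
  stages use zero-phase (forward-backward) filtering, the causal flag a
  single pass.
* **TDDR.** The published robust motion-correction algorithm: split at
  0.5 Hz, iteratively reweight the low-frequency derivatives with Tukey's
  biweight (c = 4.685, sigma = 1.4826 x MAD), integrate, re-add the
  residual. Two honest properties of the algorithm worth knowing: on
  *noise-free* data the robust sigma is set by the response itself, so the
  response is rejected as an outlier (recovery tests therefore run at a low
  but nonzero physiological noise floor); and its shrinkage is
  wavelength-specific, so after MBLL inversion a few percent of chromophore
  cross-talk is unavoidable.
* **GVTD rejection.** `g(t) = sqrt(mean_c diff(x_c)^2)`; the per-epoch
  statistic is the maximum of g within the epoch (sensitive to transient
  motion; the choice is configurable), thresholded at the session mean + 3
  SD of all epoch statistics before any rejection. Note that with fewer
  than ~11 epochs a single outlier cannot exceed a 3-SD threshold by
  construction of the z-score bound.
* **MBLL.** Per-pair 2 x 2 inversion of the pinned extinction matrix
  (`inst/extdata/extinction.yaml`, versioned so results are
  bit-reproducible), path length = channel length x DPF 6, concentrations
  in uM.
* **Recursive ZCA.** Running mean/covariance updated once per 5-s block
  with an exponentially weighted scheme (half-life 60 s — slow relative to
  trials, fast relative to cap drift); each block is transformed by the
  symmetric inverse square root of the *previous* estimate, with diagonal
  shrinkage `1e-6 * tr(Sigma)/C` so the shrinkage constant is unit-free.
  The first block passes unchanged; state is per session. The published
  description of the recursion's forgetting scheme is not printed in full
  anywhere, so this scheme is a documented stand-in with the stated
  block-update and shrinkage behavior.
* **Tile averaging.** All channels joining the same (source tile, detector
  tile, wavelength) triple are averaged; the virtual channel's length is
  the tile center-to-center distance. Averaging operates on whatever signal
  the session holds (raw intensity in the packaged chains).

# Quality scoring and session partitioning

Per-channel metrics on the task segments (baseline and breaks discarded
with a 1-s guard band): CoV (sample SD, ddof = 1), a robust SNR
`10 log10(median / MAD_raw)` (zero-MAD channels capped at 60 dB and
flagged), and a stimulus-dependent SNR comparing 0.01-0.1 Hz bandpassed,
baseline-subtracted task-window power against unfiltered task-window power
(mean-square powers, averaged over trials). As defined, that ratio is
bounded near 0 dB from above; its value is in *ranking* channels, which is
what the tests assert.

The ROI quality score is `sum(w_c q(cv_c)) / sum(w_c)` with Gaussian
weights (scale 25 mm) of midpoint distance to the nearest motor-ROI center
and `q(v) = exp(-v/0.1)`. The exact weighting of the original score is not
published, so the numeric threshold 0.02 from the original dataset is not
transferable; auto-partitioning instead re-derives the threshold per cohort
as the lowest upper bound of the lowest-quality cluster (largest gap among
sorted scores below the median). Sessions above the threshold are "minimum
viable quality" (MVQ), the rest PQ.

# Block averaging and group statistics

The offline neural-response chain: tile averaging, 15-60 mm tile pairs, OD
against the whole-session mean, zero-phase 0.02-2 Hz bandpass, TDDR, GVTD
(3 SD, statistics over all covert trials of the session), MBLL, epochs
[-5, 17) s with [-2, 0) s baseline subtraction, and per-condition means of
retained covert trials. Group statistics are two-sided one-sample t-tests
per timepoint across sessions, Benjamini-Hochberg corrected along the time
axis per channel/chromophore/condition; zero-variance nonzero-mean
timepoints are flagged degenerate and treated significant. Latency
recovery is assessed by the center of mass of the waveform above 80% of its
peak, pooling both contralateral conditions — the sample argmax of the
flat-topped response jitters by about +/-1 s at a 19-trial desk scale while
the pooled center of mass is stable to a few tenths of a second.

# The subject-independent decoder

Features: channels of length <= 50 mm; log-OD against the causal running
EMA baseline; recursive ZCA; MBLL; epochs [0, 8.5] s; polyphase resampling
to 5 Hz. The 10-Hz epoch keeps the onset sample and both endpoints (86
samples), and the pinned length convention at 5 Hz is
`floor(8.5*5)+1 = 43` columns. For integer decimation the polyphase
resampler is algebraically a causal FIR anti-alias filter plus a stride, so
it is applied as one precomputed matrix per epoch length
(`decimationMatrix()`, verified exactly against the reference resampler).
Rows are stacked channel-major, HbO block then HbR block; vec(W) is the
column-major vectorization of the [rows x time] weight matrix, and the
Tikhonov operators are built to match. Features are robustly z-scored
(per-feature median/MAD) with statistics fit on training trials only —
the scaler is an explicit input, so fitting on test data is impossible by
construction; zero-MAD features get unit scale and a flag.

The model minimizes, over weights W and unpenalized bias b,

    (1/N) sum_i log(1 + exp(-y_i (<W, X_i>_F + b)))
      + alpha ||W||_*  + beta ||Gs W||_F^2  + gamma ||W Dt'||_F^2

with labels left/right mapped to -1/+1 (the degenerate 0/1 coding sometimes
printed for this loss is treated as a typo). `Gs` has one row per pair of
same-chromophore feature rows within anisotropic distance
`sqrt(d_lateral^2 + (1.5 d_depth)^2) <= 15 mm`, Gaussian-weighted at scale
r/2 (the cited construction's exact weight profile is unpublished; this is
a documented stand-in honoring the radius and anisotropy); `Dt` is the
first-order temporal difference. The solver is a monotone FISTA: gradient
steps on the smooth part (logistic loss plus both quadratics), singular-
value soft-thresholding for the trace norm, backtracking line search
(robust to the operator spectra, no Lipschitz tuning), momentum restart on
rejected steps, and termination when the relative objective change stays
below 1e-6 (default cap 200 iterations). The objective trace is
non-increasing; on small instances the final objective matches an
independent quasi-Newton minimizer of the same objective (smoothed nuclear
norm) within 1e-4 relative.

Evaluation is leave-one-subject-out: all sessions of the test subject are
excluded from training; an optional nested grid over (alpha, beta) — the
published range is alpha 0.025-0.075 and beta 50-75 with gamma = 5; the
grid density is configurable since only the endpoints are printed — is
resolved by an inner leave-one-subject-out loop on each training set.
Every fold's fit inputs are fingerprinted and `checkNoLeakage()` audits
test/train disjointness, subject exclusion and scaler provenance.

**Known limitation (documented red check).** The planted HbR features
carry opposite-signed class information, but MBLL inversion of independent
per-wavelength noise makes the HbO/HbR estimates strongly anti-correlated
(rho ~ -0.75), and the *optimal* regularized decoder under this noise
regime is then the suppressor configuration: same-signed HbO/HbR weights.
The qualitative observation of opposite chromophore polarity at weight
hotspots (and the related short-vs-long channel polarity reversal) evidently
requires a real-data SNR structure the generator does not reproduce, and
the corresponding acceptance check is intentionally left failing rather
than adjusted.

# Reference decoders

Five literature-derived presets (`referenceVariants()`), all causal up to
the feature stage and sharing the MACD bandpass and the handcrafted windows
2-4 s (initial dip), 4.25-6.25 s (first tap) and 6.5-7.5 s (second tap):
`cui` (tile-averaged 25-45 mm, mutual-information top-80, linear C-SVM
with a nested logarithmic grid over C in 2^-5..2^15), `shin` (unaveraged
10-20 and 25-35 mm bands, CoV >= 0.40 rejection on 0.5-Hz-lowpassed
intensity, shrinkage LDA), `schudlo` (tile-averaged 25-35 mm, CoV
rejection, SFS to 4 features with deterministic lowest-index tie-breaks,
plain LDA), `trambaiolli` (tile-averaged 25-34 mm, a single 4.5-8.5 s
both-taps average plus the 2-4 s dip feature, F-score selection with a
nested feature count in 2..100, shrinkage LDA, subject-independent) and
`shin_zca` (the shin chain pooled across sessions with recursive ZCA,
subject-independent). Subject-specific presets are scored by 4-fold
blockwise within-session cross-validation (folds are task blocks);
subject-independent ones by LOSO. The mutual-information estimator is a
seed-free 8-quantile-bin histogram; the shrinkage LDA uses the analytic
Ledoit-Wolf intensity toward a scaled identity (implemented in-package, as
no installed package provides it). Every stage with fit semantics — CoV
rejection, selection, classification, scaling — is fit inside training
folds only.

# Factor analysis

Binary factors (sex; hair length binarized none/short vs medium/long) use
Wilcoxon rank-sum tests (exact when both groups are <= 20 without ties,
normal approximation otherwise); ordinal/continuous factors use Pearson,
Spearman and Kendall correlations (Kendall's p is the reported raw p) with
a Theil-Sen slope for plotting; the battery is Benjamini-Hochberg
corrected. Hair-color and ethnicity ordinals are ranked by lightness and by
cohort-mean hair occlusion respectively. ANOVAs code sex/ethnicity/age as
unordered categories (age in four bins: <30, 30-40, 40-50, >50); variance
explained is SS_factor/SS_total, and within one sequential multi-factor
table the factor and residual shares sum to 100%. The ceiling analysis
keeps the top 20% performers per alertness bin and reports Kendall's tau
and a Theil-Sen trend on that subset.

One subtlety in validating the battery: the planted dependence is defined
on the *coupling* scale while the battery measures the *quality* scale,
and the quality score is a saturating monotone transform of coupling. The
acceptance check therefore expresses the planted construction on the
quality scale as the isotonic image of the planted per-session mean
coupling before comparing variance-explained values.

# Reproducibility and problem sizes

All randomness flows through per-subject/per-session substreams derived
from one master seed (order-sensitive string hashing, so no two streams
collide). The packaged studies are sized for interactive use: the
chance-floor study is five cohorts of 12 subjects x 1 session on the
reduced montage (about half a minute per cohort); the planted-effect study
is 20 subjects; the quality study is 61 sessions (32/15/14 across three
sessions) on a 4-tile montage. These sizes are the package's own
desk-scale choices and are stated here so results can be reproduced
exactly.
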