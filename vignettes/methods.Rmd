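---
title: "Simulating and analysing resting-state EEG correlates of visual-exploration phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing resting-state EEG correlates of visual-exploration phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`eegtraits` links spontaneous EEG oscillatory features — relative band
power, the individual alpha frequency (IAF), and long-range temporal
correlations (LRTCs) of the alpha amplitude envelope — to a
visual-exploration phenotype: "static" viewers (long fixations, positive
PC1 scores above 1) versus "dynamic" viewers (short fixations, PC1 below
−1). This vignette is the package's own account of the models and the
choices behind them.

## The synthetic cohort: what it emulates and what it does not

No raw data accompany the study the pipeline targets, so the package
generates a phenotyped cohort with full ground truth. The generator is a
*stand-in model*: the source study states no generative model for either
the EEG or the gaze series, so every construction below is a design
choice, built to carry the statistical structure the analysis estimates,
and labelled as such.

### Subject parameters

`make_cohort()` draws 19 static and 21 dynamic subjects. A latent
"phenotype depth" normal per subject drives the PC1 score
(`pc1 = sign * (1 + exp(0.2 + 0.6 u))`) and, with correlation 0.9, the
subject's deviation from the group mean of each generative parameter. The
group distributions (truncated normals and log-normals, see
`default_group_params()`) encode the phenotype:

| parameter | static | dynamic | role |
|---|---|---|---|
| IAF (Hz) | median 9.5 | median 10.5 | alpha peak frequency, truncated to 8.9–10.9 Hz |
| eyes-open alpha gain | log-mean log 1.30 | log 0.78 | occipital alpha concentration |
| eyes-closed alpha gain | log 1.60 (both) | log 1.60 (both) | arousal control: identical distributions |
| beta gain | log 0.55 | log 0.80 | frontal beta |
| gamma gain | log 0.28 | log 0.42 | occipital gamma |
| alpha-envelope Hurst | 0.82 | 0.62 | brain LRTC |
| fixation Hurst | 0.85 | 0.65 | behavioural LRTC |
| fixation log-mean (s) | log 0.35 | log 0.22 | fixation durations |

The IAF truncation bounds keep alpha peaks away from the 12 Hz edge of
the alpha integration band: a peak near the edge loses part of its mass
from the band and would masquerade as an eyes-closed group difference
that the design explicitly excludes.

### EEG synthesis

Each channel of `synth_eeg()` sums three parts.

1. **Background + beta + gamma**: one Gaussian field with per-channel
   one-sided PSD `20/f^chi` µV²/Hz (flat below 0.5 Hz, zero above 48 Hz;
   `chi = 1` by default and configurable — the spectral exponent of real
   resting EEG varies and nothing downstream depends on its exact value)
   plus raised-cosine band plateaus for beta (12.5–32 Hz) and gamma
   (32.5–45 Hz) with region-weighted gains (beta frontal, gamma
   occipital). The field is synthesized exactly in the frequency domain
   (Hermitian random spectrum, `E|X_k|^2 = n fs S/2`), spatially smoothed
   across the montage with a Gaussian kernel (sd 30°) *before* the
   regional weights are applied, so neighboring channels correlate like
   volume-conducted EEG without blurring the regional contrasts.
2. **Alpha**: per-channel narrowband carriers with a Gaussian spectral
   peak (sd 0.45 Hz) at the subject's true IAF, synthesized in quadrature
   at a low rate and heterodyned. Carriers are spatially smoothed like
   the background, so alpha coherence decays with electrode distance and
   average re-referencing removes only a weak common mode — a perfectly
   coherent alpha would largely cancel under the average reference. All
   carriers share one amplitude envelope `e(t) = max(1 + 0.7 g(t), 0.12)`
   where `g` is fractional Gaussian noise with the subject's Hurst
   exponent, synthesized at 4 Hz and interpolated: an affine transform
   preserves the fGn's correlation structure exactly (DFA exponent = H),
   and the light tail keeps the realized alpha power stable across
   recordings, unlike an exponential (log-normal) envelope whose
   realized power is dominated by rare excursions.
3. **Regional gain geometry**: the subject's alpha gain acts with full
   exponent over the occipital region and a small diffuse compensating
   exponent (−0.20) elsewhere. A high-gain subject therefore concentrates
   alpha posteriorly rather than adding alpha everywhere; global
   (channel-mean) alpha changes little with gain. This is what lets the
   same cohort show a clear occipital cluster difference *and*
   near-null arousal controls (eyes-closed alpha, alpha reactivity), the
   signature the analysis is designed to reproduce. A side effect is a
   weak diffuse alpha contrast of the opposite sign, which occasionally
   forms its own cluster; reported cluster correlations therefore follow
   the *dominant* cluster, the significant cluster containing the
   peak-|statistic| channel. A per-recording "state" factor (log-sd
   0.28) and per-channel expression jitter (log-sd 0.10) supply
   realistic session-to-session and electrode-to-electrode variability.

Fractional Gaussian noise itself (`synth_fgn()`) uses exact
circulant-embedding (Davies–Harte) synthesis, giving the analytic oracle
DFA exponent = Hurst exponent used throughout the tests.

What the generator does **not** emulate: ocular/muscle artifacts, true
volume conduction or source geometry, non-stationary vigilance drifts,
line noise, or cross-frequency structure. Passing tests on this cohort
show that the *pipeline* recovers the planted structure at the study's
sample size; they do not certify performance on real recordings, where
artifact handling (the `artifact_hook` in `preprocess()`) matters.

### Gaze synthesis

`synth_gaze()` alternates fixations and saccades. Fixation duration of
event `k` is `exp(mu + 0.85 g_k)` with `g` fGn at the subject's fixation
Hurst exponent — long-memory durations make the binary 0/1 series carry
LRTCs — while saccades are short (≈30 ms) with ballistic half-sine
velocity profiles (peaks 120–350 deg/s) over a low fixational drift
(≈2 deg/s), so a 30 deg/s velocity threshold separates the states almost
perfectly. The log-sd of 0.85 gives duration a coefficient of variation
near 1; pilot sweeps showed that with much lighter tails the series'
renewal regularity (anti-persistent, exponent < 0.5) masks the memory.

## Preprocessing

The chain mirrors standard resting-state practice: zero-phase
Kaiser-windowed sinc FIR band-pass 0.5–47 Hz (transition bandwidths 1 and
2 Hz; the stated orders 1812/908 at 500 Hz are scaled with the sampling
rate; the Kaiser beta is derived from order and transition width by the
standard design relations), anti-aliased resampling, bad-channel
detection, spherical-spline interpolation (stiffness m = 4, 50 Legendre
terms, ridge 1e−5), and average re-referencing.

Bad channels are flagged by the union rule: impedance > 100 kΩ, OR
maximum Pearson correlation with channels within 25° below 0.75, OR at
least two of {spectral-deviation z > 4, amplitude-improbability z > 4,
kurtosis z > 7}, all z-scored across channels. Two caveats are worth
stating. First, the kurtosis criterion's cross-channel z-score of a
single outlier is bounded by `(C−1)/sqrt(C)`, so a threshold of 7 can
only ever fire on montages of ≳50 channels — it is a dense-net criterion.
Second, the z-metrics are estimated on every third sample by default
(`decimate`), which leaves the z-scores essentially unchanged at a third
of the cost.

## Spectral analysis

`welch_psd()` uses Hamming-tapered segments of `fs/resolution` samples at
50% overlap (density scaling, µV²/Hz), giving a grid spacing of exactly
the requested resolution (0.5 Hz by default). Relative band power divides
the trapezoidal band integral by the trapezoidal integral over 1–45 Hz —
the outermost analyzed band edges; "whole spectrum" would otherwise be
ambiguous given the 0.5–47 Hz filter. `detect_iaf()` takes the argmax of
the occipital-average eyes-closed spectrum on 7–13 Hz and replaces the
study's manual visual check by an algorithmic rule: the detection is a
*true peak* only if it is a strict local maximum and not a boundary bin;
flagged subjects are excluded from IAF analyses rather than guessed.

## DFA

`dfa()` computes the cumulative-sum profile, splits it into log-spaced
windows (15 scales, 50% overlap), removes a linear trend per window, and
fits the log-log slope of the pooled RMS residuals by ordinary least
squares. Scale ranges: the hard upper cap is a quarter of the series
length (fewer than four windows make `F(s)` unstable); the default upper
scale is an eighth of the length. The EEG envelope wrapper uses 1–20 s at
the envelope rate, common practice for alpha-envelope LRTCs. The
*fixation-series* default is 2–100 s: at sub-second scales the binary
series is renewal-like (its regularity pulls the local slope below 0.5),
and the duration memory expresses at multi-second scales — the choice was
made on generator sweeps, since the underlying study defers these details
to an unavailable supplement.

For the pipeline, the alpha envelope is computed from the analytic signal
of the order-66 zero-phase FIR band-passed data, with the one-sided
spectrum truncated at `fs/(2·8)` so the envelope is obtained directly at
fs/8 — it is band-limited far below that Nyquist, so the multi-second
scaling is unchanged at an eighth of the cost. Edges of half the filter
order are trimmed before DFA.

## Statistics

All permutation procedures are deterministic given a seed and use the
add-one estimator `p = (1 + #{T_perm ≥ T_obs})/(n_perm + 1)`, so p-values
never fall below `1/(n_perm+1)`. Cluster inference forms connected
components of suprathreshold channels (two-tailed forming alpha 0.01,
sign-split, face channels excluded) in a neighbor graph of 30° angular
radius, and compares each observed cluster's *size* against the
permutation distribution of the map-wise maximum cluster size. Spearman
correlations use average ranks, the t approximation for p-values, and
Fisher-transform 95% intervals.

One deliberate departure from the source study's procedure: `run_study()`
computes the scalp cluster tests for the alpha, beta and gamma bands
unconditionally and reports the global band ANOVAs alongside, rather than
using them as a gate. The cluster statistic carries its own family-wise
error control, and gating on a global test throws away the spatially
concentrated effects this design produces (a posterior redistribution of
alpha changes occipital channels strongly while leaving the global mean
nearly unchanged). FDR (Benjamini–Hochberg) is applied across the five
bands within each condition for the global ANOVAs.

## Study defaults and problem sizes

The default simulated study runs 40 subjects (19/21) with 90 s of
eyes-open and 45 s of eyes-closed EEG at 250 Hz on a 64-channel montage,
and 10-minute gaze traces at 500 Hz; permutation tests use 1000
resamples. The eyes-closed recording serves spectral endpoints only
(band power, IAF), hence the shorter duration; the eyes-open recording
must support envelope DFA up to 20-s scales. These sizes are the
package's chosen simulated-study scale — large enough that the planted
effects are detected with high power at n = 19/21 and the scaling
exponents are stable, small enough that a full study run completes in
about a minute.

## Numerical choices and degenerate inputs

* Noise fields are synthesized exactly in the frequency domain; the
  inverse FFT packs two real channels per complex transform.
* `dfa()` refuses constant series (zero fluctuations), scales below 4
  samples, and upper scales beyond a quarter of the length.
* `detect_iaf()` reports boundary maxima with `is_true_peak = FALSE`
  instead of failing.
* `interpolate_bad()` errors when every channel is bad and warns beyond
  25% bad channels; the spline system carries a small ridge (1e−5) for
  conditioning.
* Filters require even orders so the group delay is an integer number of
  samples; cutoffs at or above Nyquist are errors.
* A single global seed fans out to per-subject and per-test substreams by
  a counter-based scheme, so adding a subject never perturbs another
  subject's data.

## Known limitations

The two arousal controls sit near a statistical boundary by design: the
same cohort must show a detectable occipital alpha contrast while its
global eyes-closed alpha and reactivity contrasts stay null at n = 40.
The generator's topographic-redistribution construction keeps the
residual standardized control differences small, but a five-percent-level
test on 40 subjects will still reject occasionally — exactly as a real
null would. The cluster FWER under the null is
conservative (empirically well below the nominal 0.05) because
maximum-cluster-size inference at a strict forming threshold is discrete.
Finally, all claims about real EEG transfer only to the extent that the
generator's simplifications (no artifacts, kernel-based spatial
correlation) are acceptable for the question at hand.
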