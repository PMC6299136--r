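---
title: "Sleep-state hemodynamics and neurovascular coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-state hemodynamics and neurovascular coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

remsurge analyses concurrent functional-ultrasound (fUS) power-Doppler
imaging and hippocampal LFP recorded during natural rodent sleep. The
pipeline scores sleep states, normalizes cerebral blood volume (CBV) to a
quiet-wake baseline, detects brain-wide REM vascular surges, extracts
band-limited LFP power envelopes, and quantifies LFP-to-CBV coupling as
peak pairings, delay distributions and cross-correlation lags. Because no
public reference dataset exists for this modality pairing, the package
ships a seeded generator that produces complete multimodal recordings with
ground truth, and every claim the pipeline makes is validated against that
ground truth in the test suite.

## The measurement model

Power-Doppler intensity is proportional to local cerebral blood volume, so
all vascular quantities are expressed as percent change versus a baseline:
the first 3 minutes of quiet wake (plus the first 3 quiet-wake minutes
after each full recording hour, to absorb slow drift). Each voxel is
normalized independently, `(v - mean_baseline)/mean_baseline * 100`,
before any spatial averaging, then movies are linearly resampled to 1
frame per second. This matches how mixed-rate Doppler sessions (1-3 Hz
native) are usually homogenized.

Raw power-Doppler frames are obtained from complex IQ frame stacks by SVD
clutter rejection: the voxels-by-frames matrix is decomposed and the
leading components — spatially coherent, high-energy tissue motion — are
removed (60 components for the ~kHz ultrafast stacks this mirrors; the
synthetic fixtures use smaller stacks and ranks). The power-Doppler value
is the per-voxel mean squared magnitude of the residual.

## Sleep scoring

Scoring uses 5 s epochs and three signal families: neck EMG RMS, head
accelerometer RMS, and hippocampal LFP band envelopes. The rules are the
classical rodent ones. A sustained low-EMG run longer than 20 s is sleep;
we apply the rule retrospectively over the whole run, because scoring is
offline — this keeps a 15 s EMG dip as wake while a 25 s dip becomes 25 s
of sleep, and brief post-REM awakenings do not erase the surrounding
sleep. Within sleep, REM requires a theta/delta envelope ratio of at least
2 together with a ripple envelope below its threshold; everything else is
NREM. Within wake, accelerometer activity separates active from quiet
wake. Labels are majority-smoothed over 3 epochs, so isolated single-epoch
flips are absorbed; the epoching itself (5 s) keeps the 20 s rule exact.
How sub-epoch transitions are resolved is our choice — the tradition
scores continuously and leaves this open.

The EMG threshold is recording-specific: a two-component Gaussian mixture
is fitted to log epoch EMG RMS (mclust) and the threshold placed at the
antimode. If the two components are not separated by at least two pooled
SDs, the estimator falls back to the median and flags itself; scoring then
deserves manual review. Movement threshold: half the 95th percentile of
epoch accelerometer RMS. Ripple threshold: 75th percentile of the ripple
envelope over provisionally scored sleep.

## LFP processing

Band table: delta 1-4, theta 6-10, low-gamma 20-50, mid-gamma 50-100,
high-gamma 100-150, ripple 150-250 Hz. Filters are 4th-order Butterworth
band-passes applied forward-backward (`signal::filtfilt`), hence exactly
zero-phase — non-negotiable here, because the scientific readout is a
delay of about 1.5 s and any filter group delay would bias it. Narrow
low-frequency bands (upper edge below rate/25) are filtered on a
decimated copy after a zero-phase anti-alias low-pass and linearly
interpolated back; the transfer-function recursion is numerically unstable
at such normalized bandwidths, and the decimated path keeps passband gain
within 1% with ~99 dB attenuation one octave out.

Band power is the squared filtered signal convolved with a unit-area
Gaussian of characteristic width 500 ms. We read "characteristic width" as
the Gaussian sigma, not the FWHM, and expose it as a parameter
(`width_s`). Envelopes keep the input rate; interpolation to the 1 Hz CBV
clock is an explicit caller step so that nothing resamples silently.

Spectrograms use an analytic Morlet continuous wavelet transform. The
classical description (center frequency 2 Hz, window 2 s) under-determines
the wavelet family; we parameterize by cycles per wavelet (`n_cycles`,
default 6) and document rather than guess the original mapping. Each row
is multiplied by its frequency to compensate 1/f attenuation. Theta phase
is the Hilbert (analytic-signal) phase of the theta-filtered trace,
shifted so 0 degrees sits at the trough and 180 at the peak; theta-gamma
coupling is the mean envelope power in 18 phase bins with a
power-weighted circular mean as the preferred phase (flat profiles are
flagged undefined instead of reporting an arbitrary angle).

## Vascular surges

A voxel is active in a frame when its normalized CBV exceeds its own
active-wake mean plus one active-wake SD (Z > 1; population SD by
convention — the choice is stated because nothing pins it down). A surge
is a maximal run of frames in which strictly more than 50% of in-brain
voxels are active, restricted to REM by default, kept when at least 5 s
long. Both inequalities are strict, runs are not gap-merged, and the
frame-by-frame rule is cross-checked against an independent scan oracle in
the tests. Surge metrics: spatial-mean intensity (mean and max over the
surge) and active-voxel ratio (mean and max), summarized per recording as
mean ± population SD with a low-n flag below 5 surges.

## LFP-CBV coupling

Peaks are discrete zero-derivative maxima. The literal rule is noise-
fragile, so peaks can be filtered by topographic prominence (default half
an SD) and minimum separation (1 s for CBV, 0.5 s for envelopes), both
config-exposed with 0 restoring the literal rule. Because 1 Hz frames
quantize peak times, an optional parabolic three-point refinement
(`refine = TRUE`) interpolates peak time and value; the same refinement is
applied around cross-correlogram maxima.

Pairing: for each CBV anchor peak at `t`, LFP candidate peaks within
`[t - 4 s, t + 1 s]` are considered and the closest in time is selected,
the earlier one on exact ties (ties essentially never occur on continuous
data; the rule just makes the algorithm total). Unpaired anchors count in
the pairing-ratio denominator. The LFP-anchored direction uses the
mirrored window `[-1, +4]`. Delays are `t_cbv - t_lfp`, so causal
LFP-to-CBV coupling gives positive delays.

Peak-value correlation pools pairs across recordings after min-max
normalizing each recording's values to [0, 1] — the guard against
between-recording (Yule-Simpson) artifacts. That guard has a price worth
knowing: the min-max ranges are data-dependent, so with few recordings
the pooled r is slightly attenuated and its sampling spread is wider than
the plain-Pearson 1/sqrt(n) (we measure a mean shift of about -0.03 and a
~20% wider spread at 4 recordings of 100 pairs). Recovery checks of the
estimator therefore use a single-recording fixture, where the
normalization is a plain linear map, and the multi-recording guard is
exercised by its own Simpson-construction test. Significance uses the
standard Pearson test, `t = r sqrt(n-2)/sqrt(1-r^2)` with `n-2` df. (One
printed formula in the tradition transposes numerator and denominator;
that version is not a valid test statistic and we implement the standard
one.) Delay distributions are summarized as mean ± SEM with a one-sample
location test against zero reported as the normal approximation of the
Wilcoxon signed-rank Z — the convention behind reported Z-scores of ~20
on thousands of events; groups sharing events are compared by paired
t-tests matched through the common candidate peak.

Cross-correlation lag estimation: per REM episode, Pearson correlation of
the envelope against the regional CBV at every lag within ±10 s on the
frame grid (positive lag = LFP leads), per-episode peak extraction, and a
mean correlogram across episodes whose peak gives the group lag.

One bias is worth stating plainly: the generator's hemodynamic kernel is
a gamma-variate, and when the requested FWHM exceeds the peak delay the
kernel is necessarily right-skewed. Correlation-based lag estimates then
land slightly after the kernel peak (about +0.3 s at the defaults). This
is a property of the estimator on skewed kernels, not an implementation
error; the recovery tests therefore check the kernel-peak lag within
±0.5 s rather than exact equality, and ordering comparisons are unaffected
because the bias is shared across regions.

## Functional connectivity and state statistics

Connectivity is the zero-lag Pearson matrix over the frames of one state
— no Fisher transform, no filtering — averaged entrywise across
recordings for group matrices. Fisher machinery is used only for
inference: `atanh(r) ± 1.96/sqrt(n-3)` confidence intervals and the
two-sample Z, `(atanh(rA)-atanh(rB))/sqrt(1/(nA-3)+1/(nB-3))`. State CBV
levels are summarized from 30 s window means (partial windows dropped)
rather than raw 1 Hz samples: the 1 Hz series is strongly autocorrelated
and raw-sample intervals would be artificially narrow; the tests verify
the widening numerically. Group comparisons versus quiet wake use Cohen's
d (pooled SD) and the two-tailed Mann-Whitney test; whether the original
interval procedure tested window means or raw samples is ambiguous, and
window means are taken as normative here.

## Plane-to-atlas registration

A 2-D imaging plane is registered into a 3-D label volume with 9
parameters: 3 offsets, 3 scalings, 3 rotations. Convention (ours to fix,
serialized with the transform): the image point `(row, col)` embeds as
`(x = col, y = row, z = 0)`, is scaled, rotated about x then y then z, and
translated. Landmarks come in four classes — outer cortex edge, inner
cortex edge, midline, dentate/hippocampus edge — and the cost is the sum
over landmarks of the Euclidean distance to the nearest boundary voxel of
the matching class. The nearest-distance lookup goes through an exact 3-D
Euclidean distance transform per class (EBImage), interpolated
trilinearly, which makes each cost evaluation O(landmarks) and the
Nelder-Mead search (5 starts around the initialization, best kept)
essentially instantaneous. In-plane landmarks cannot constrain the scale
along the plane normal; that parameter is reported but should not be
interpreted. Only the 9-parameter single-plane problem is implemented —
the multiplane (13-parameter) variant is out of scope.

## The synthetic generator

The generator is the package's test bench, and its defaults are the study
conditions, chosen once:

* Sleep architecture: a semi-Markov chain over QW/AW/NREM/REM with
  shifted-exponential dwells (10 s floor, means 60/40/120/60 s), REM
  entered only from NREM and followed by a 15 s awakening; recordings
  open with a quiet-wake bout of at least 200 s so the 3-minute baseline
  always exists (sessions begin awake). A deterministic REM-cycling
  schedule (`rem_cycle_hypnogram`) serves controlled coupling studies.
* LFP: NREM delta plus sporadic ripple packets; AW/REM theta at 8 Hz;
  REM fast-gamma bursts at 4 per REM minute in 80-110 Hz, amplitudes
  maximal on the ascending theta phase (135 degrees from trough), powers
  log-normal. Burst times are thinned to 5 s separation so each event has
  a resolvable vascular response, with a dead-time-corrected intensity so
  the realized rate still matches the configured one. EMG noise is 10x
  larger in wake than sleep; the accelerometer is nonzero only in AW.
* CBV: each voxel is `baseline * (1 + offset/100 + gain/100 * drive +`
  `noise)`; per-state offsets follow the empirical pattern (AW ~ +6%,
  tonic REM at AW levels, NREM at baseline with a mildly hypoactive
  thalamus); `drive` is the burst power train convolved with a
  gamma-variate kernel of unit peak, peak delay 1.3/1.5/1.7 s in
  thalamus/hippocampus/cortex, FWHM 3 s; gain 30% CBV per unit burst
  power; frame noise SD 2% CBV. No quantitative burst-to-surge law exists
  in the literature this emulates — linearity is the simplest choice that
  gives the peak-correlation analysis a known target slope. Ground-truth
  surge intervals apply the surge rule to the noise-free signal.
* IQ stacks are statistical stand-ins (low-rank tissue + sparse blood +
  noise on mutually orthogonal temporal subspaces, so energies add
  exactly and the blood truth is unambiguous); no acoustics are
  simulated. The label volume is a synthetic nested-ellipsoid stand-in
  for an MRI atlas, not a real parcellation.

What passing tests show — and what they do not: the generator's LFP is a
sum of narrowband components with Gaussian noise, its state signatures
are cleanly separable, and its hemodynamics are exactly linear and
stationary. Real recordings carry movement artifacts, electrode drift,
1/f backgrounds, non-stationary coupling gains and imperfect atlas
boundaries. Recovery under the generator therefore demonstrates
correctness of the algorithms, not field performance.

Problem sizes used by the validation suite (our choices): delay recovery
uses one session with 20 REM episodes of 90 s; surge detection 30-50
seeded ~10-minute recordings; scoring 10-20 seeded 10-minute sessions;
calibration checks 2000 replicates; registration 10-20 perturbed starts.

## Determinism and numerics

Every simulation is a deterministic function of its config, including the
seed; per-component RNG sub-streams are derived by fixed offsets so, for
example, burst ground truth is identical whether or not LFP waveforms are
synthesized. The pipeline itself consumes no randomness, and
`run_pipeline` writes a manifest (inputs, thresholds, artifact checksums)
that reproduces byte-identically on re-runs. Degenerate inputs are
explicit: constant series yield empty peak sets or flagged undefined
statistics; zero delta power makes the theta/delta ratio an `Inf`
sentinel with a flag; movies lacking 3 baseline minutes abort by naming
the shortfall rather than baselining on the wrong state.
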