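---
title: "Methods: population-response analysis of VSD imaging under optogenetic and electrical stimulation"
author: "vsdpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-response analysis of VSD imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdpop)
```

## The measurement and the signal model

Mesoscale voltage-sensitive dye imaging (VSDI) reports the summed membrane
potential of neuronal populations as a fractional fluorescence change per
pixel. The acquisition emulated here images a 5 x 5 mm cortical window at
100 x 100 pixels (50 um/pixel) and 100 Hz (10 ms frames). Stimulation is
either a single blue-laser pulse (2, 5 or 10 ms, 15 mW) activating
ChR2-expressing neurons, or intracortical microstimulation (ICMS; ten 80 uA
biphasic pulses at 500 Hz, a 20 ms train). Frame timing is 1-based:
`onset_frame` is the frame at t = 0 ms and a frame "at t = 20 ms" is the
single frame with that timestamp — no binning.

The core signal is delta-f/f. Each trial's pixel values are divided by that
pixel's mean pre-stimulus fluorescence ("frame-zero division") and 1 is
subtracted, so baseline sits at 0. Division alone would put baseline at 1;
the explicit centering makes all downstream time courses start near zero,
and blank subtraction re-centers regardless, so the choice is cosmetic but
stated. The frame-wise mean over blank (no-stimulation) trials is then
subtracted from every stimulated trial, removing heartbeat, slow dye
bleaching and drift that are shared between the two trial types; trials are
averaged last. Because every step is linear, averaging before or after blank
subtraction is numerically identical (asserted in the tests).

Two masking rules follow. For optostimulation, the frames at t = 0 and
t = 10 ms contain the laser light artifact and are invalidated regardless of
pulse duration; ICMS produces no optical artifact, so nothing is removed,
and every cross-modality comparison instead anchors at t >= 20 ms, the
first artifact-free frame, where the response peaks. Second, laser light
photobleaches dye near the fiber tip; pixels within a search radius
(default 500 um) of the stimulation site whose trial-averaged signal drops
below a negative threshold (default -0.002 delta-f/f) in a window just after
laser offset (default 10-40 ms) are invalidated for all frames. Bleach
detection runs on the trial average, not per trial — the averaged signal is
the cleaner detector and the mask must be common to all trials anyway.
Invalid frames and pixels carry `NA` in the data in addition to boolean
masks, and every downstream mean is mask-aware; tests poison masked entries
with absurd values and verify that no result changes.

## The synthetic-session generator

No recordings ship with the package, so a generator produces raw
fluorescence stacks with known ground truth. Raw fluorescence of a trial is

F(x, y, t) = F0(x, y) (1 + drift(t) + heartbeat(t) + R(x, y, t) + laser(t) + bleach(x, y, t)) + eps,

with F0 a 1000 a.u. baseline with mild radial vignetting (only ratios
survive frame-zero division), a linear drift (default -1e-4/frame), a 6 Hz
heartbeat (urethane-anesthetized-rat range; amplitude 5e-4) generated
deterministically and identically in stimulated and blank trials so blank
subtraction removes it exactly, and i.i.d. Gaussian camera noise eps on raw
fluorescence (default SD 1.5 a.u.) — noise lives on the camera, not on
delta-f/f.

The evoked field is separable:

R(x, y, t) = A s(p) T(t) exp(-d(x, y)^2 / (2 sigma(t)^2)),

where d is the distance to the stimulation site. The temporal kernel T rises
with ChR2 opening kinetics (tau_open = 1.92 ms), normalized to reach exactly
1 at a peak pinned to t = 20 ms — every analysis anchors there, and the true
rise is hidden behind the laser artifact, so only the pinned peak matters —
and then decays as a two-component mixture
w_fast exp(-(t-20)/tau_fast) + w_slow exp(-(t-20)/tau_slow), emulating the
early fast decay (informed by the ~17.9 ms ChR2 closing tau) followed by a
slower decline. The spatial width grows linearly after the peak,
sigma(t) = sigma0 + speed (t - 20), emulating lateral spread. Amplitude
scales with pulse duration as s(p) = (p/10)^gamma, with gamma calibrated
once per preset so the normalized 2/5/10 ms peaks reproduce the observed
ratios (~0.4/0.7/1 for short expression, gamma = 0.57; ~0.6/0.8/1 for long
expression, gamma = 0.32).

Three presets define the study conditions and are not tuning knobs:

| preset | amplitude (delta-f/f) | sigma0 (um) | w_slow | tau_fast / tau_slow (ms) |
|---|---|---|---|---|
| `short_exp` | 1.4e-3 | 300 | 0.05 | 12 / 80 |
| `long_exp`  | 3.6e-3 | 450 | 0.45 | 18 / 100 |
| `icms`      | 5.1e-3 | 600 | 0.55 | 20 / 140 |

Amplitudes are the observed grand-average t = 20 ms peaks of the three
conditions; the remaining parameters were chosen once to preserve the
qualitative orderings (amplitude, slow-decay weight and spatial extent all
increasing from short expression to long expression to ICMS) and never
revisited. Optical artifacts exist only in the opto presets: a frame-wide
additive offset (0.05 delta-f/f) during frames overlapping the pulse — its
exact shape is irrelevant because those frames are dropped — and a top-hat
photobleach spot (radius 150 um, depth -0.008 delta-f/f after laser offset).
The depth exceeds the response amplitude so the spot is genuinely darker
than the superimposed response, as bleaching appears in real maps, and a
top-hat makes the masked pixel count exactly predictable in tests. Blank
trial counts and inter-trial drift behavior are free parameters left at
modest defaults (the experiments constrain neither).

## ROI time courses and normalizations

The response center is the argmax pixel of the (3 x 3 boxcar-smoothed,
mask-aware) frame at t = 20 ms; ties break deterministically to the smallest
(row, col). The time course (TC) is the per-frame mean over the valid pixels
of a radius-5-pixel circle (81 pixels, 250 um) centered there, with the
across-trial SEM of per-trial ROI means; grand averages carry the
across-session SEM instead — the two spreads are distinct fields. Three
normalizations are used: none; per-session division by the 10 ms condition's
value at t = 20 ms (which makes that reference exactly 1 with zero SEM
across sessions, and removes staining/expression amplitude variance before
grand averaging); and division of each TC by its own t = 20 ms value, for
comparing decay dynamics across conditions. "Peak response" always means the
t = 20 ms value, not the global maximum — the two coincide once the artifact
frames are removed, and an option to use the true maximum exists for
degenerate cases.

## Ring space-time analysis

Concentric annuli of 50 um width (one pixel) extend to a 2 mm radius around
the response center: ring k holds pixels with center distance
(k-1) 50 < d <= k 50 um, a half-open rule that guarantees disjointness and
exactly 40 rings. The center pixel itself (d = 0) belongs to no ring. The
space-time map is the mask-aware mean per ring per frame; the "central ring"
is the mean of the ring means of rings 1-5 (a minimal-pixel-count choice:
ring 1 alone holds 4 pixels). An alternative central definition — a circle
ROI of radius 150 um — is selectable (`center = "circle150"`), because the
two definitions are both in circulation for this analysis and differ
slightly; the rings-1-5 form is the default. Summed activation adds the
ring means over all 40 rings and the inclusive window t in [20, 100] ms
(9 frames at 10 ms sampling); it sums ring means rather than pixel values,
i.e. rings are not weighted by their pixel count, matching the
"response amplitude per ring" reading. Display conventions (profiles
starting at 150 um) do not affect the sum, which always starts at the
center. Distance-resolved TCs average the elementary rings fully inside the
reported bands: 150-350 um (rings 4-7), 700-900 um (15-18) and
1250-1450 um (26-29).

## Decay-time-to-threshold maps

For each pixel the peak reference is its own t = 20 ms value (per-pixel, not
the ROI peak, so the map is defined everywhere the signal is positive); the
threshold is 70% (fast phase) or 30% (slow phase) of that peak. The decay
time is the first time the descending signal falls below threshold, located
with sub-frame precision by linear interpolation between the last frame at
or above and the first frame below threshold — exact on piecewise-linear
signals, which the tests verify to machine precision on 1000 random
signals, along with two structural invariants: the 30% crossing can never
precede the 70% crossing, and the map is invariant to positive rescaling of
the movie. If re-crossings occur, the first downward crossing is used. The
analysis window ends at the last acquired frame; pixels that never cross are
reported missing and excluded from medians (not right-censored), with their
count retained. Distributions pool per-pixel decay times across sessions for
a central band (ring 1, 150-350 um) and a distal band (ring 3,
1250-1450 um), summarized as median +/- MAD (unscaled median absolute
deviation). Outlier sessions are excluded only via an explicit config list —
no automatic rule, since none is defined.

## YFP expression quantification

In-vivo YFP images are min-max normalized to [0, 1] within the chamber mask
(a percentile-clipped variant is available for hot pixels); the expressing
area is the count of chamber pixels strictly above the image's own
mean + 2 SD. Strict inequality is immaterial for continuous data but keeps
ties deterministic, and the z-score form makes the count invariant to affine
rescaling. The group comparison (long vs short expression) uses a
label-shuffle control: all distinct label assignments are enumerated when
feasible (always, at the experiment's animal counts), otherwise seeded
random permutations, reporting the shuffled mean, SD and a z-like score.

## Statistics

All comparisons are nonparametric: two-sided Wilcoxon rank-sum for
independent samples (exact for combined n <= 20 without ties — covering
every session-level comparison here — normal approximation with tie and
continuity correction otherwise) and Wilcoxon signed-rank for paired samples
(zero differences dropped; all-zero differences leave the test undefined and
raise an error). Bonferroni correction uses an explicit family size — the
number of pairwise comparisons in the reported panel (3 for the pulse
durations or the condition pairs). Summaries are mean +/- SEM by default and
median +/- MAD for decay times. The electrode-integrity check compares
first-trial against last-trial TCs across sessions on two features: the
t = 20 ms peak and the slow-phase amplitude, defined as the mean over
t in [60, 100] ms — the window is not standardized anywhere, so it is a
config-exposed choice placed after the fast decay has completed in all
conditions.

## Numerical choices and test problem sizes

Tests and the acceptance script run entirely on generator data at reduced
problem sizes chosen as the package's own verification conditions: unit
tests mostly use 20 x 20 px, 12-frame sessions; ordering checks use the full
100 x 100 geometry with 3 sessions x 6 stimulated + 4 blank trials per
condition and 5 seeds, comparing grand averages and pooled pixels as the
multi-session analyses do. The decay-constant recovery analysis fits the
bi-exponential (Levenberg-Marquardt, starts w = 0.5, tau = 10/80 ms, taus
ordered after fit) to the true-center-pixel TC of a long-expression session
with 20 stimulated + 20 blank trials, camera noise SD 0.05 a.u. and a 300 ms
recording — bi-exponential fitting is ill-conditioned, and these conditions
give the slow tail enough support for 15%-level recovery; photobleaching is
disabled there because bleached pixels are masked out of any real analysis
and the top-hat would otherwise corrupt the probed center pixel.

## What the generator does and does not emulate

It emulates: stimulus-locked activation spreading from a point with
amplitude scaling over pulse duration and condition, two-phase decay,
laser-artifact frames, a photobleach spot, and drift/heartbeat shared with
blank trials. It does not emulate: propagation delay (the model is
separable, so distal pixels peak simultaneously with the center; combined
with the expanding spatial width, the normalized signal at distal pixels
rises within the window rather than decaying, and many distal pixels never
cross the 30% threshold — they are reported missing, and central-band
orderings are unaffected), anisotropic spread, correlated or multiplicative
noise, motion, hemodynamic signals, or whisker-evoked responses. Passing
tests therefore certify the analysis code and its invariants on data with
these statistics, not the biological conclusions on real recordings.
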