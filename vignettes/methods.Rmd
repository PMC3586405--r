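---
title: "Methods: models, estimators and synthetic fixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and synthetic fixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonolaryn)
```

This vignette documents the models behind each analysis step, the tunable
parameters and their defaults, the synthetic-data generators and what they
do and do not emulate, and the numerical choices made where the design was
genuinely open.

## 1. Acoustic analysis

### Pitch tracking

`estimate_pitch_track()` uses the normalized cross-correlation function
(NCCF): for a frame starting at sample $s$ with window length $W$ and lag
$\tau$,

$$ r(\tau) = \frac{\sum_{t} x_{s+t}\,x_{s+t+\tau}}
  {\sqrt{\sum_t x_{s+t}^2 \sum_t x_{s+t+\tau}^2}}, $$

computed by FFT per frame. Defaults: search band 40–600 Hz (wide enough for
low-pitched dysphonic and high-pitched sung vowels), frame 40 ms (at least
two periods of the lowest F0 of interest), hop 10 ms, voicing threshold
0.45 on the interpolated correlation peak. Among near-tied local maxima
(within 10% of the global peak) the shortest lag wins, which resolves the
period-multiple ambiguity of strongly harmonic vowels; a 7-point running
median over the voiced frames removes isolated residual octave errors. The
peak is refined by a three-point parabola, giving sub-Hertz accuracy on
pure tones across 80–500 Hz.

### Analysis segment

Clinical practice analyses a homogeneous mid-phonation stretch — "about 50
cycles", "a second of the middle portion". `select_analysis_segment()`
takes the longest voiced run, centers a window on its midpoint, and sizes
it to `target_cycles / median F0`, capped at 1 s. Both protocol readings
are therefore available: the 50-cycle default, and `target_cycles` large
enough that the 1-s cap binds. Perturbation statistics computed from
$n$ cycles have relative sampling error $\approx 0.8/\sqrt{n}$, so
cohort-style comparisons of jitter/shimmer use the one-second reading
(about 180 cycles at 178 Hz); this is a statistical-power choice, not a
tuning step.

### Cycle marking

Cycles are marked by peak-picking guided by the local F0 (search window
0.75–1.3 local periods ahead of the previous mark), with two low-pass
filtered views of the segment: timing uses a 2.5 kHz cutoff (keeps the
first two formants of /a/, suppresses wide-band noise that would otherwise
jitter the marks), amplitudes a 4 kHz cutoff. The filters have a soft
Gaussian rolloff — a brick-wall edge rings, and the sinc tails drag mark
timing toward neighboring cycles. The filtered stretch is padded by 1024
samples on both sides so circular-convolution edge ripple falls outside
the analyzed cycles. Marks and amplitudes are refined by three-point
parabolic interpolation.

Alternatives that were implemented and rejected on measurement grounds:
neighbor-to-neighbor waveform matching and whole-cycle template matching
both *underestimate* jitter (the formant carrier, continuous across cycle
boundaries, pulls the alignment; measured shrinkage 0.5–0.85), and
LPC-residual marking is unusable below about 25 dB HNR. Plain guided
peak-picking with parabolic refinement is unbiased here because the
synthesized (and, to good approximation, real) excitation events are sharp
relative to the formant ringing.

### Jitter and shimmer

`jitter_local()` and `shimmer_local()` are the standard local
perturbation measures,
$100\,\overline{|T_i-T_{i-1}|}/\bar T$ and
$100\,\overline{|A_i-A_{i-1}|}/\bar A$. They are zero on perfectly
periodic input, non-negative, shimmer is gain-invariant, and jitter is
invariant under relabeling of the time axis.

### Harmonics-to-noise ratio

The HNR follows the classical cycle-synchronous decomposition: cycles are
aligned rigidly at their marks with fractional-sample (linear)
interpolation, the periodic component is the mean cycle with one free gain
per cycle (absorbing shimmer), and noise power is the residual in the
early 35% of each cycle — the part rigidly locked to the excitation
instant and hence insensitive to period perturbation. Linear interpolation
attenuates white noise by $(1-a)^2+a^2$ for fractional offset $a$; the
estimator divides that back out. $\mathrm{HNR} =
10\log_{10}(P_\mathrm{periodic}/P_\mathrm{noise})$, capped at 40 dB
(numerically pure signals have residuals at interpolation-error level).

A pure autocorrelation HNR ($10\log_{10}(r/(1-r))$ at the cycle lag,
retained as a fallback when fewer than 5 cycles can be marked) is biased
low on perturbed voices: jitter of 0.35% at a 700 Hz first formant costs
$\approx (2\pi f_1 \sigma_T)^2/2 \approx 3\cdot10^{-3}$ of correlation,
about 2.3 dB at a true 23 dB — outside the recovery tolerance this package
holds itself to, which is why the template estimator is the default.

Measurable HNR is intrinsically capped by perturbation: at 3% jitter no
estimator can report 35 dB, because period perturbation itself
decorrelates the signal. Recovery validation therefore uses voices in
which jitter, shimmer and noise worsen jointly (a severity continuum with
±25% independent scatter), the structure clinical cohorts actually show.

### Frequency range

`frequency_range()` is the difference of mean voiced F0 between the
lowest- and highest-pitch sustained /a/; inverted inputs are swapped with
a warning.

## 2. Spectrographic grading

`narrowband_spectrogram()` uses a Hann window of about 46 ms (rounded to
an FFT-friendly length, e.g. 2048 samples at 44.1 kHz) with 75% overlap
and no zero padding, so FFT bins fall on the zeros of the Hann main lobe
and bin spacing (≈21.5 Hz) resolves harmonics of any F0 ≥ 80 Hz.

`band_harmonicity()` quantifies the verbal "harmonic vs noise components"
criteria: per voiced frame and band (F1 region 200–1000 Hz, F2 region
1000–3000 Hz, HF above the conventional 3000 Hz edge), the energy within
1.5 bins of the harmonic comb $kF_0$ — the extent of the Hann main lobe —
minus the broadband floor estimated from the between-harmonic bins, over
the total band energy. The floor subtraction makes a pure voice score ≈1
and pure noise ≈0; without it the comb windows geometrically cover ~40% of
the band and noise could never score below the "predominant" threshold.
The HF noise level is total HF energy over total energy, in dB.

`yanagihara_grade()` evaluates a fixed cascade from most to least severe,
with configurable thresholds (`yanagihara_thresholds()`): "completely
replaced" < 0.15, "predominant" < 0.5, "mixed" < 0.8 on the harmonic
fractions; "intensified" HF noise above −25 dB (grade III) and −15 dB
(grade IV). Exactly one rule fires; the grade is an ordered factor so
severity comparisons work; a recording with no voiced frame at all grades
IV ("no periodic components detectable"), keeping the grade monotone under
increasing noise. A manual override grade can be recorded alongside.

## 3. Stroboscopic image measures

All measures are in pixels (no metric calibration exists for endoscopic
video). Segmentation: Otsu's threshold on a 256-bin histogram spanned by
the data range (hence invariant to uniform intensity offsets), dark side,
optional 3×3 closing, largest 8-connected component; components below 10
px mean "no glottis detected" (area 0, flag).

Lesion sizing compares each fold's per-row medial edge with a robust
baseline: a bisquare loess fit (span ≥ 0.8, locally quadratic) follows
genuine edge curvature (the elliptical gap outline) but refuses localized
bumps; rows deviating into the gap by more than 2 px are flagged, flagged
runs grow by hysteresis at 1 px so bump shoulders are not treated as
baseline, and the summed deviation over flagged rows is the lesion size. A
running median (the obvious first choice) fails here: clinically plausible
lesions span more rows than any window small enough to track edge
curvature. Lesions wider than about a quarter of the visible fold are
underestimated — a documented limitation. Sides are reported in the
patient's frame (patient right = image left unless `mirrored`).

The deviation angle fits each medial edge by total least squares
(principal axis) and reports the inter-line angle in degrees; it is
invariant to scene rotation and intensity offsets.

The movement index over a frame sequence combines the glottal area
waveform's oscillation amplitude $(\max-\min)/(\max+\min)$ with its
regularity (fraction of mean-removed spectral energy at the dominant
frequency); both lie in $[0,1]$, the product is 0 exactly for a constant
series, and frame shuffling lowers the regularity component. The formula
is this package's reconstruction — the original definition was never
published in reusable form.

Closure type (hourglass, posterior, …) is a manual rating; an
experimental suggestion from the row-wise gap profile is provided.

## 4. Clinical scales

Scoring constants are reproduced exactly: VHI items 0–4 (forced by the
printed "0–40 per 10-item group"), subscale bands Low 0–20 / Moderate
21–30 / Severe 31–40, global bands Low 0–30 / Moderate 31–60 / Serious
61–90 / Severe 91–120 (the published band table overlaps Low and Moderate
at 31–39; Moderate's lower edge is kept so the bands partition 0–120).
GRBAS ratings 0–3 with optional A and S. MFT pathological strictly below
10 s; phonorespiratory index pathological strictly above 1.5 (the printed
wording is "below"/"greater than"). Short-form categories use uniform
banding of the 0–10 scale (not printed in the source material;
configurable).

## 5. Vocal profile and persistence

The 13 axes follow the fixed published order; each value is normalized by
a documented normal limit so radius 1.0 is the red threshold circle:
`value/limit` for higher-is-worse axes, `limit/value` for lower-is-worse
(subjective quality, MFT, HNR). Default limits — quality 7/10,
repercussion 3/10, G/R/B 1, MFT 10 s, jitter 1.0%, shimmer 3.8%, HNR
20 dB, stroboscopic ratings 2/10 — are stated, configurable choices: the
original red-circle values were never published, and only the
documented-limit semantics matter for interpretation. The polygon area
$\tfrac12\sin(2\pi/13)\sum_i r_i r_{i+1}$ is the severity summary; it
depends on the (fixed) axis order, is monotone in every radius, and equals
$\tfrac{13}{2}\sin(2\pi/13)\approx 3.037$ at the threshold circle.

Sessions are stored as versioned XML with numerics at 17 significant
digits (lossless round trip); archives load ordered by visit date, and a
missing visit date is a parse error naming the element. Reports are
self-contained HTML with an inline SVG radar, deterministic given a fixed
timestamp.

## 6. Synthetic fixtures: what they emulate, and what not

`synth_voice()` builds a Rosenberg glottal flow pulse train in continuous
time, differentiates it, and applies two fixed formant resonators (700
and 1200 Hz, bandwidths 110/140 Hz) approximating /a/. Period and
amplitude perturbations are i.i.d. Gaussian with
$\sigma = \mathrm{pct}\cdot\sqrt{\pi}/200$, so the expected local measure
equals the request ($E|z_i - z_{i-1}| = 2\sigma/\sqrt{\pi}$); an
`alternating` pattern gives deterministic ±d perturbation for exact
checks. White noise is mixed at
$P_\mathrm{noise} = P_\mathrm{periodic}\cdot10^{-\mathrm{HNR}/10}$, which
*defines* the HNR non-circularly (a bisection against the package's own
estimator would validate nothing).

One generator detail matters for correctness: the pulse is anchored so
that its closing edge ends exactly at the cycle boundary, with open and
closing phases of fixed absolute duration. If the pulse instead scales
with the perturbed period (the textbook parameterization), the glottal
closure instants — the only acoustic landmarks an analyzer can find — sit
at a fixed *fraction* of each cycle, and the closure-to-closure intervals
are a two-tap smoothing of the nominal periods: the declared ground truth
then simply is not present in the waveform (any marker measures about half
the nominal jitter). Anchoring makes the ground-truth periods the
observable event intervals.

The generators do **not** emulate: formant variation across vowels and
speakers, F0 drift/vibrato, additive noise with glottal modulation
(breathiness is approximated by stationary white noise), tremor,
diplophonia, or realistic laryngeal texture and illumination gradients in
the strobe frames (a smooth sinusoidal texture stands in). A green
recovery test therefore establishes that the estimators are correct and
well-conditioned on controlled signals of the assumed structure — not that
they are robust to every clinical recording condition.

A single draw's realized perturbation measures carry sampling error
(relative SE $\approx 0.8/\sqrt{n}$ cycles), so generator self-checks
compare the across-draw mean at tight tolerance and individual draws at
three standard errors; seeds were fixed a priori, never selected on
outcomes.

`synth_strobe_sequence()` renders the gap by ranking pixels by elliptical
distance and darkening exactly the requested count (modulated areas are
nested, connected regions; the pixel-count oracle is exact), or as a
V-shaped chink between straight edges with specified angles and optional
apex width; lesions re-brighten exactly `lesion_px` gap pixels nearest an
edge point. `synth_session()` draws plausible values for every block for
persistence and report testing.

## 7. Numerical choices and degenerate inputs

* FFT inputs are padded to 2-3-5-smooth lengths (R's mixed-radix FFT is
  quadratic on awkward lengths).
* Silence gates: frames with energy below $10^{-6}$ of the recording mean
  are unvoiced; all-zero recordings track as fully unvoiced.
* Cycle extraction requires ≥ 3 complete cycles; unvoiced segments raise
  a condition carrying both the insufficient-cycles and no-voicing
  classes so either can be caught.
* Waveforms outside $[-1,1]$ are rescaled with a warning; stereo WAV is
  down-mixed by averaging with a warning; 16-bit WAV uses the ±32768
  convention with clipping at 32767.
* Ties in peak picking resolve to the earlier sample (`which.max`);
  Otsu's threshold resolves ties to the lowest bin; the profile radar
  clips drawn radii (not stored ones) to the outer ring.
* Lower-is-worse profile axes (quality, MFT, HNR) require positive
  values; non-finite or non-positive values are validation errors, while
  absent blocks give radius 0 with a warning.

## 8. Known limitations

* Jitter/shimmer estimates inherit a small negative bias (~5–8%) from
  formant ringing overlap between adjacent cycles; it is well inside the
  stated recovery tolerances but visible in aggregate.
* Measured HNR saturates below the nominal value for heavily perturbed
  voices (see §1); ranking is preserved under jointly-worsening severity.
* Automatic Yanagihara grading discriminates noise-replacement of whole
  bands; subtler within-band patterns (e.g. subharmonics) are not graded.
* The stroboscopic module assumes one dominant dark gap; double gaps
  (ventricular compression) segment as the larger component only.
* PGM is the only on-disk image format; in-memory matrices from any
  source can be wrapped with `strobe_frame()`.
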