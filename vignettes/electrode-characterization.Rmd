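---
title: "Characterizing dry textile ECG electrodes on a synthetic bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing dry textile ECG electrodes on a synthetic bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgbench)
```

`ecgbench` reproduces the desk-side analysis behind the electrical
characterization of dry (textile) biopotential electrodes: contact-impedance
spectroscopy and its Cole-model summary, polarization drift statistics, ECG
noise and similarity metrics, and a segmentation-based fidelity score. This
vignette explains the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic bench does and does not emulate, and
the package's known limitations.

## The measurement model

### Contact impedance by two-configuration subtraction

The skin–electrode contact impedance cannot be probed in isolation: any
series measurement also includes the tissue between the electrode sites.
The workaround is two measurements of the same series loop. With an AC
source (5 Vpp by default) and a reference resistor `R_ref` sensing the loop
current `I = Vr / R_ref`:

- **Configuration A** probes an intermediate electrode through a
  high-impedance input, so `V21 = Ve2 − Vr` spans one contact plus tissue:
  `Z_sum = Z_contact + Z_tissue`.
- **Configuration B** drives that electrode directly and uses
  `V21 = Vg − Vr`, spanning both contacts: `Z_12 = 2 Z_contact + Z_tissue`.

Subtraction isolates `Z_contact = Z_12 − Z_sum`. This algebra silently
assumes all electrode contacts are identical; `simulate_sweep()` builds its
ground truth under the same assumption, and `decompose_impedance()` flags
(but keeps) results whose real part comes out negative, since with real,
noisy electrodes the subtraction can overshoot and no principled rejection
rule exists at this stage.

The default sweep grid is `freq_grid()`: 10 points per decade from 0.1 Hz
to 10 kHz (51 points). ECG content ends near 150 Hz, but the upper decades
are what pin down the Cole model's high-frequency plateau.

### Phasor estimation

Voltages are reduced to phasors (magnitude, phase). Magnitude comes from
`amplitude_peaks()`: the waveform is split into half-cycles at the zero
crossings of the mean-removed signal and the absolute extremum of each
half-cycle is averaged. Two refinements matter numerically:

- each extremum is re-estimated by a least-squares parabola over ±10% of
  the half-cycle, which removes the sampling-grid bias and — unlike taking
  the raw maximum — does not ride the maximum of additive noise;
- the mean is estimated twice: once over the whole record to find the
  crossings, then again over the integer number of cycles between the
  first and last crossing. A partial trailing cycle would otherwise bias
  the baseline by up to a few percent of the amplitude.

Phase is estimated two ways. The **Lissajous** method reads the trace of
`y` against `x` at its y-axis intercept: `θ = arcsin(y0 / Y0)`, with `y0`
taken at the positive-going zero crossings of `x` (4-point cubic
interpolation between samples — linear interpolation is curvature-biased
precisely at ±90°, where `y` sits on its extremum at the crossing). The
arcsin confines results to [−90°, 90°]; `waveform_to_phasor()` resolves
the quadrant with the sign of the zero-lag cross-correlation, and when
noise pushes `|y0|` above `Y0` the estimate is clamped to ±90° with a
warning rather than failing.

The **cross-correlation** method finds the lag `l` maximizing
`r(l) = Σ x(n) y(n−l)` and converts it to phase by `θ = 360 l F / Fs`.
Three numerical choices: the correlation is computed by FFT (sweeps at
0.1 Hz have 10⁴-sample periods); `x` enters through a core window of whole
cycles with at least half a period of margin, so every lag sees the same
number of terms and `r(l)` is an exact sampled cosine for pure tones; and
the maximizing lag is refined by three-point parabolic interpolation
(disable with `refine = "none"` to keep the literal integer-lag formula,
whose phase is quantized to `360 F / Fs` degrees). Ties break toward the
smallest `|l|` — a minimal-phase prior.

### DC removal

`remove_dc()` implements a 0.05 Hz high-pass FIR of order 2000, applied
zero-phase via centered convolution with mirror padding. At the normalized
cutoffs this package encounters (5·10⁻⁵ down to 10⁻⁷), conventional
fir1-style scaling leaves most of the DC gain in place (we measured a DC
gain of 0.74 at 1 kHz sampling), so the filter is instead built as the
spectral complement of a DC-normalized windowed-sinc lowpass, which nulls
DC exactly. For records shorter than three times the order, the order
drops to a third of the record length with a warning. The sweep pipeline
additionally discards half a filter length at each record end before
phasor estimation, so edge transients never reach the estimators. The
realized passband is flat to ~0.1% (gain 0.9992 at 1 Hz, 1 kHz sampling):
good enough for the pipeline's 2% impedance tolerance, but the filter is
only idempotent to ~10⁻³, which is what the test suite asserts.

## The Cole model

`cole_eval()` and `cole_fit()` use

$$Z(\omega) = R_\infty + \sum_k \frac{R_k}{1 + R_k C_k (j\omega)^{\alpha_k}},
\qquad 0 < \alpha_k \le 1,$$

with the principal branch of the complex power. Conventions differ in the
literature over where the time constant sits; this form is fixed here
because it reduces exactly to a parallel RC branch at α = 1, and the
printed capacitance of the reference parameterization is interpreted under
it. `f = 0` is accepted as the analytic limit `R∞ + ΣR_k`.

Fitting is bounded Levenberg–Marquardt (`minpack.lm`): resistances and
capacitances on a log10 scale, α in (0, 1]. The default objective is the
residual in `log10 |Z|`, matching how such spectra are presented and
compared on Bode magnitude plots; a `complex` mode stacks real and
imaginary residuals scaled by `1/|Z|` for when calibrated phase data are
trusted. Initialization uses plateau heuristics — `R∞` from `min |Z|`, the
dispersion resistance from the plateau difference, `α = 0.8`, and `C`
chosen so the characteristic frequency sits at the grid's geometric
midpoint. For two dispersions a single start proved fragile (one recovery
test converged into a merged-dispersion basin), so the fit runs a
deterministic grid of four characteristic-frequency splits and keeps the
best residual. Non-convergence is reported in `glance()`, not thrown.

Double dispersion is implemented and tested by self-recovery of its own
spectrum, but no reference parameterization exists for it, so nothing
downstream depends on it.

## Polarization statistics

`exchange_ratio()` is the mean absolute first difference of the DC series
(µV per sampling interval; the protocol samples at 10 sps, so per 0.1 s),
and `mean_polarization()` is the mean absolute potential — the
absolute-value convention makes the level polarity-independent, which is
how per-material polarization tables are reported with either electrode
polarity. Outlier removal is Tukey's rule at 1.5×IQR with interpolated
quartiles; the multiplier is a convention choice (the method description
only states "interquartile range") and is exposed as an argument. Raw and
IQR-filtered aggregates are both available because published grand means
of such tables typically do not equal the simple mean of the printed
entries, implying an unstated weighting that we deliberately do not guess.

## ECG filter bank and quality metrics

`design_filter_bank()` builds three order-150 Kaiser-window (β = 0.5) FIR
stages: bandstops at 55–65 and 115–125 Hz (reading the "10 Hz" stop width
as total width) and a 0.05–150 Hz bandpass. β = 0.5 is nearly a
rectangular window, so the stopbands reach only about −20 dB and the
0.05 Hz edge is very shallow at order 150 — the design is implemented as
specified rather than idealized, and `filter_bank_response()` exports the
realized response so users see the true attenuation. The `zero_phase`
column there is the real-valued response a delay-compensated symmetric FIR
actually applies (it can be negative inside a stopband) and is the correct
gain for predicting what `filter_ecg()` does to a tone. Stages are applied
with their group delay removed so annotations stay aligned. Sampling rates
must exceed 240 Hz; below 250 Hz the 120 Hz notch no longer fits under
Nyquist and is omitted with a warning, and a passband edge above Nyquist
is lowered likewise.

`noise_power()` is the mean squared removed component, and
`pearson_similarity()` the product-moment correlation of mean-removed
channels — the former measures how much out-of-band content a channel
carried, the latter whether two simultaneously recorded channels agree in
morphology.

## Segmentation

`detect_qrs()` is a Pan–Tompkins implementation: zero-phase 5–15 Hz
Butterworth bandpass, centered five-point derivative, squaring, 150 ms
moving-window integration, adaptive dual thresholds with a 200 ms
refractory period and a search-back pass at half threshold, then R-peak
refinement to the raw-signal maximum within ±100 ms. `delineate()` places
Q and S as the opposite-polarity extrema within 80 ms of R, and P and T as
dominant smoothed peaks in physiological windows (300–50 ms before Q,
80–450 ms after S) that must exceed 5% of the beat's R amplitude above
local baseline — the floor rejects noise-only peaks and is tunable. Beats
whose windows run off the record are marked incomplete, not errored.

`error_rate()` compares channels by complete-beat counts:
`100 (1 − N_complete_test / N_complete_ref)`, clipped to [0, 100]. The
quoted definition of this ratio is ambiguous about the denominator; the
default uses the reference channel's *complete* beats (consistent with
near-zero error for faithful electrodes), and `denominator = "all"` gives
the other reading. The exact delineator used alongside Pan–Tompkins in the
original workflow is unpublished; equivalence with it is explicitly out of
scope, and the windowed delineator here is validated against the
generator's ground-truth fiducials instead.

## The synthetic bench

Every input is generated with known ground truth:

- `simulate_sweep()` samples the source, reference-resistor and probe
  waveforms of both circuit configurations, with exact circuit phasors
  attached. The sampling policy is `fs = max(1 kHz, 50 f)` capped at
  1 MHz — 50 samples/cycle resolves phase at 10 kHz while keeping 0.1 Hz
  records tractable — and records hold at least 10 cycles. Tissue
  impedance defaults to a purely resistive 1 kΩ (it is never
  characterized separately in this workflow) and contact impedances are
  identical across electrodes, as the subtraction algebra requires.
- `synth_ecg()` builds both channels from one sum-of-Gaussians P-Q-R-S-T
  template (so fiducials are shared and annotated by construction), then
  adds 60/120 Hz powerline, sub-0.5 Hz baseline wander and
  channel-specific white noise. A corruption rule suppresses a named wave
  in a chosen fraction of beats on the test channel only — the controlled
  defect the error rate must recover. Defaults: 1 kHz sampling (an
  acquisition-rate choice; the front-end rate was never stated in the
  original protocol), 300 s records, 70 bpm, 1 mV R waves.
- `synth_polarization()` produces DC series at 10 sps for 30 min:
  offset (default 15.4 mV, a typical textile level), slow drift, optional
  step artifacts, and Gaussian sample noise (default SD 238 µV, chosen so
  the expected exchange ratio `2σ/√π` lands near the ~270 µV per 0.1 s
  scale reported for textile electrodes).

All generators are bit-reproducible under their seed. What the bench does
**not** emulate: heart-rate variability, respiration coupling, electrode
motion artifacts beyond step/suppression rules, electrode-electrolyte
electrochemistry, or inter-subject variability. Passing tests therefore
demonstrate that the *analysis* is correct and self-consistent, not that
real textile electrodes will behave this way; with real data the
variability of the skin–electrode interface dominates.

## Statistical workflow

`assumption_check()` tests normality on residuals about group means
(Shapiro–Wilk below 50 observations, Lilliefors-corrected
Kolmogorov–Smirnov above — the plain KS test is anti-conservative with
estimated parameters) and homoscedasticity by Levene's test centered on
the mean. `select_test()` is the pure decision tree: assumptions met →
ANOVA (repeated-measures for paired/repeated designs); violated →
Kruskal–Wallis for more than two groups, Wilcoxon otherwise (paired when
the design says so). An undefined variance check counts as a violation.
α is fixed at 0.05 and no multiple-testing correction is applied by
default, matching the workflow being reproduced. The dispatcher's type-I
error is property-tested on null data per branch.

`conductivity()` treats a fabric as a thin film: `σ = 1/(R_s · t)` in
S/cm. The phrase "product between thickness and surface resistance" that
usually accompanies this calculation is dimensionally a resistivity; the
reciprocal is what reproduces the conventionally printed S/cm values, and
that is what is implemented.

## Problem sizes and runtime

The test suite generates all data at run time: sweeps on the full 51-point
grid (the largest record is 10⁵ samples at 0.1 Hz), 60–120 s ECG records
across 40–180 bpm, 30-min polarization series, and 100-replicate null
simulations per dispatcher branch. The full suite runs in about two
minutes on one core; the acceptance script (Cole self-recovery on 51
frequencies) in seconds.

## Known limitations

- The identical-contacts assumption is structural: with asymmetric real
  electrodes the decomposition attributes half the asymmetry to tissue.
- Phase estimates degrade near ±90° (arcsin sensitivity) and the
  Lissajous method needs at least two clean cycles.
- The order-150, β = 0.5 filter bank is faithful to its specification,
  not optimal; residual powerline after filtering is ~10% in amplitude.
- The delineator is amplitude-threshold-based; unusual morphologies
  (inverted T, absent Q) will read as incomplete beats by design.
- Powerline is fixed at 60/120 Hz; 50 Hz mains require a re-designed
  bank.
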