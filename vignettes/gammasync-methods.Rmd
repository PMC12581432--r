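---
title: "Analysing in vitro hippocampal gamma oscillations, sharp wave-ripples and evoked responses with gammasync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gammasync methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammasync)
```

## Scope and data model

`gammasync` analyses single-channel extracellular recordings from
hippocampal slices: pharmacologically induced gamma oscillations
(carbachol, DHPG or kainate type), spontaneous sharp wave-ripple (SW-R)
complexes, multi-unit spiking during gamma cycles, and evoked fEPSPs at
the Schaffer collateral-CA1 synapse. All analyses operate on a
`recording` — a uniformly sampled voltage trace in mV with its sampling
rate (5 kHz is the reference rate throughout) — and on artifact-free
two-minute segments cut from longer recordings with
`extract_segment()`. Artifact screening is deliberately out of scope:
window selection mimics the manual selection step of slice
electrophysiology and is the caller's responsibility.

Every numeric constant of the pipeline lives in one `analysis_config()`
object: FFT block size, band edges, inclusion thresholds, detector SDs
and windows. Voltages are mV and times seconds everywhere inside;
spectral power is converted to µV² once, inside `power_spectrum()`,
because the slice-inclusion threshold (10 µV²) is conventionally stated
in µV².

## Gamma spectral metrics

`power_spectrum()` is a Welch-style estimator: 4096-sample blocks at
5 kHz (bin spacing 5000/4096 = 1.2207 Hz), linear detrend and Hann taper
per block, 50% overlap, averaged periodograms. The scaling is chosen so
that a pure sinusoid of amplitude $A$ µV carries band-summed power
$A^2/2$ and the sum over all bins of a stationary signal equals its
variance (a Parseval identity pinned by tests at 1%).

From the spectrum, `gamma_scalar_metrics()` derives the four scalar
gamma descriptors:

* **integrated power**: the discrete sum of per-bin power over 20–80 Hz,
  edges inclusive. We pin the *bin-sum* dialect (not a density integral
  multiplied by the bin width) because the 10 µV² inclusion threshold
  only makes sense on that scale together with the printed 1.221 Hz
  resolution; the choice is enforced by a unit test.
* **peak power / peak frequency**: the maximum-power bin inside the
  band; ties break to the lowest frequency for reproducibility.
* **half band width (HBW)**: the distance between the two half-maximum
  crossings flanking the peak, each located by linear interpolation
  between bins. When a crossing is never reached inside the band the
  HBW is reported missing — never zero.

Bins at or below 1 Hz are excluded from all band metrics, and each
block is linearly detrended, so DC and slow drift cannot leak into the
gamma band. `passes_gamma_inclusion()` implements the slice-inclusion
rule with *strict* inequalities: peak power > 10 µV² and peak
frequency > 20 Hz; both boundary cases are excluded by tests.

## Autocorrelogram synchrony metrics

`autocorrelogram()` computes the biased, normalized autocorrelation of
the mean-subtracted two-minute segment via the Wiener–Khinchin theorem.
The biased normalization keeps all values bounded by 1; the price is
that even a perfect tone reads $1 - \mathrm{lag}/N$ at one period
rather than exactly 1, which at two minutes is a $4\times10^{-4}$
effect.

Two synchrony metrics follow:

* `second_positive_peak()` reports the autocorrelogram value at the
  local maximum nearest one gamma period. The zero-lag maximum counts
  as the first positive peak, so this index measures one-period
  coherence; the two-period alternative is available via `n_periods`
  because the convention is genuinely ambiguous in the field and both
  yield values below 1 for realistic gamma, so published group values
  cannot disambiguate them.
* `fit_tau()` fits $A e^{-\mathrm{lag}/\tau}$ to the oscillatory peaks.
  Two numerical safeguards matter on broadband data. First, a
  one-period moving average of the autocorrelogram is subtracted before
  peaks are measured: broadband 1/f background adds a slowly decaying
  positive baseline that otherwise inflates $\tau$ badly, and because
  the moving average is linear and lag-invariant it rescales a damped
  cosine by a constant without touching its decay constant. Second, the
  rectified troughs are fitted alongside the peaks (for a damped cosine
  their magnitudes lie on the same exponential), doubling the usable
  points inside the well-measured first periods — this is what makes
  $\tau \approx 10$ ms identifiable from a single two-minute segment,
  where the second period peak is already close to the sampling floor
  of the autocorrelogram. Peaks are searched in ±25% windows around
  (half-)multiples of the period, later peaks are down-weighted as
  1/lag² (their sampling error grows with window width and baseline
  wander), and the fit is nonlinear least squares with a log-space
  starting value. Non-decaying peak sequences return a missing value
  with reason `"non_decaying"` rather than a spurious constant.

## Multi-unit activity and gamma-phase coupling

`gamma_phase()` band-passes the segment at 15–45 Hz with a
frequency-domain mask filter (`fft_filter()`: forward FFT, raised-cosine
band edges of 1 Hz, inverse FFT — the filter class of common
acquisition software, zero-phase by construction) and takes the Hilbert
analytic signal. Phase is reported in degrees with **0° at the
filtered-trace trough**, so a cycle runs trough → peak (180°) → trough.

`detect_units()` extracts the 500–3000 Hz component. At 5 kHz the upper
edge exceeds Nyquist, so the band is clipped to 0.9 × Nyquist
(2250 Hz); the full band is honoured for sampling rates above
6.7 kHz. The filtered trace is wavelet-denoised: periodized sym4
discrete wavelet transform, 4 levels, soft thresholding per level with
the threshold chosen by Stein's unbiased risk estimate (falling back to
the universal threshold on near-noise-only levels), and a *per-level*
robust noise scale because the background is far from white across
levels. This follows the behaviour of the standard toolbox denoisers;
the exact wavelet family and threshold rule are pinned here as the
package's dialect since only "wavelet denoising" is conventionally
reported. Detection then takes local extrema of the absolute denoised
trace above the 0.0125 mV floor with a 1 ms refractory period (larger
event wins), detects on absolute value because extracellular spikes may
be negative-going, and stores a ±2 ms waveform snippet per event.
Further evaluation uses the **gated** subset: events with amplitudes at
or above the 75th percentile of all detected amplitudes (ties
included — 100 detections gate exactly 25).

`phase_profile()` bins gated-unit phases into twenty 18° bins,
normalized to a firing-probability distribution; the activation curve
is its cumulative sum from 0°. `average_gamma_cycle()` resamples each
trough-to-trough cycle to 360 points and averages.
`spike_waveform_features()` measures per-event height
(baseline-to-extremum of the snippet), width at half height
(interpolated crossings; events clipped by the snippet edge are
excluded from width statistics but still counted) and their ratio.

## Sharp wave-ripple detection

`detect_sharp_waves()` low-passes the raw segment at 45 Hz and takes
local maxima above mean + 3 SD of the full filtered segment, merging
maxima closer than 100 ms (the larger one wins). The SD is computed
over the whole segment *including* events — the literal reading of the
conventional recipe — with a median/MAD alternative behind a flag.
`sw_area()` integrates (trace − mean) between the two mean-crossings
flanking the maximum, interpolating the exact crossing points; events
whose crossings leave the segment are flagged edge-clipped with a
missing area rather than a truncated number.

`extract_ripples()` band-passes a 125 ms window centred on each SW
maximum at 120–300 Hz, gates ripple troughs inside the stored
sub-window (15 ms before to 10 ms after the maximum) at 3 SD of the
band-passed window, and quantifies each trough by
**triple-point-minimax**: amplitude = mean of the two flanking maxima
minus the trough. This three-point reading is the most literal
interpretation of the term; it is pinned by unit tests as a dialect.
The asymmetry rule excludes ripples whose rising ($r$) and falling
($f$) components differ by more than 75%, implemented as
$|r-f|/\max(r,f) < 0.75$ (the ratio reading $f/r$ is selectable).
Trough times are refined by parabolic interpolation before
`ripple_frequency()` takes the mean reciprocal inter-trough interval,
which keeps tone-burst frequencies exact to a few Hz at 5 kHz sampling.
`swr_summary()` reports incidence as events per second over the
segment.

## Evoked fEPSP metrics

The acquisition conventions give no measurement windows, so
`fepsp_slope()` uses defaults pinned from standard CA3–CA1 latencies:
1.5 ms artifact blanking, fiber-volley window 1.5–4 ms, fEPSP window
3–20 ms post-stimulus, 5 ms pre-stimulus baseline, negative-going
responses by default. The slope is the least-squares line through the
onset limb between 20% and 80% of the baseline-to-extremum amplitude;
because at 5 kHz only a handful of raw samples span that corridor, the
exact 20%/80% crossing times are interpolated and the line is fitted on
a densely resampled corridor — on a curved limb a line through six raw
samples is biased by several percent. The slope is reported in V/s
(numerically equal to mV/ms). In paired-pulse sweeps each response's
window is truncated at the next stimulus, and at short intervals the
decay of the first response is removed by fitting a mono-exponential
tail and subtracting its extrapolation before measuring the second
slope. `transmission_rate()` averages per-sweep slope/FV ratios
(yielding ms⁻¹), excluding sweeps with non-positive fiber volleys;
`io_curve()` assembles input-output tables and flags slices below 1 mV
fEPSP amplitude at 50 µA. How the fiber-volley amplitude is best
measured (peak versus trough-to-peak) is not standardised; the package
uses baseline-to-extremum within the FV window and leaves polysynaptic
contamination to a manual flag.

## Group statistics

`pooled_t_from_summary()` reconstructs Student's pooled two-sample t
from printed (mean, SEM, n) summaries via SD = SEM·√n, with
df = n₁+n₂−2; a property test verifies it agrees with the raw-data t
whenever raw samples realize the summaries. `cohens_d_ci()` uses the
normal-approximation standard error
$\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$ with z = 1.96; this
convention reproduces published intervals to two decimals, which is why
it was adopted over the noncentral-t construction. `route_test()`
implements the normality-routed choice — Student t only when both
groups pass Shapiro–Wilk at α = 0.05, Mann–Whitney otherwise — with the
normality test and Mann–Whitney delegated to base R. Gamma power enters
comparisons as log₁₀ (`log_power()`), reflecting its order-of-magnitude
variability in vitro. `binwise_welch()` compares firing-probability
profiles bin by bin with Welch's t (no equal-SD assumption) and reports
contiguous significant ranges; no multiplicity correction is applied by
default, matching the uncorrected multiple-comparison convention, with
Holm available.

## The synthetic-LFP generators

No public recordings accompany this class of experiment, so the
generators are first-class, tested code that define the study
conditions for every recovery test.

**Gamma** (`gen_gamma_lfp()`): the oscillation is
$-A\,\mathrm{env}(t)\cos\varphi(t)$ where $\varphi$ performs a random
walk around $2\pi f_0$. The diffusion gives an exactly exponential
autocorrelation envelope, $e^{-\mathrm{lag}/\tau}\cos(2\pi f_0\,
\mathrm{lag})$ with $\tau = 2/\sigma^2$, so the ground-truth decay
constant is closed-form; the equivalent cycle-to-cycle period-jitter
fraction is exposed as `phase_jitter`. A literal concatenated-cycle
construction was rejected because independent period jitter
decorrelates *slower* than its nominal constant (the phase lag
saturates over long cycles), leaving no closed-form truth. The
increment noise is band-limited to ~250 Hz (2 ms moving average, DC
gain 1): this leaves the long-lag diffusion constant — hence τ —
untouched but removes sample-scale clicks that would otherwise bleed
into the unit band. The background is 1/f² above a 2 Hz knee (flat
below, as AC-coupled amplifiers deliver); defaults (amplitude 60 µV,
background 20 µV, peak 40 Hz, τ 30 ms) put the integrated 20–80 Hz log
power near 3.2 and τ in the published 13–32 ms range, and leave ~1 µV
RMS in the 500–2250 Hz unit band, typical of good extracellular
recordings. Ground truth records the per-sample phase, the Lorentzian
in-band power (the phase diffusion spreads a fraction of $A^2/2$
outside 20–80 Hz, accounted for in closed form), and the effective τ.

**Units** (`gen_locked_units()`): Poisson spike counts; each spike
draws a phase from a von Mises density (Best–Fisher rejection sampler)
and is placed at the sample of a uniformly chosen cycle whose realized
phase is circularly nearest the drawn angle, so the realized phase
distribution matches the drawn one (first-passage placement was
rejected: it correlates with local phase increments and biased realized
phases by several degrees). Spike heights follow a lognormal spread
(CV 0.4 by default), emulating units at different electrode distances;
this matters because upper-quartile gating is only meaningful when
biological amplitude spread dominates measurement noise — with
identical templates the gate selects on phase-modulated measurement
noise and distorts flat profiles. The template is a Ricker wavelet
(band-friendly biphasic shape) added negative-going.

**SW-R** (`gen_swr_train()`): Poisson event times with an enforced
200 ms separation; each event is a Gaussian sharp wave (0.2 mV, σ
10 ms) plus a flat-core (Tukey) ripple tone burst. The flat core makes
the nominal ripple frequency exact in the stored sub-window — a fully
tapered envelope shifts inter-trough intervals by its own gradient, so
its "ground truth" would be biased by construction. Defaults put the
SW amplitude at six times the SD of the low-frequency background, the
regime in which the detector is benchmarked (recall and precision
≥ 0.95); the analytic event area $a\sigma\sqrt{2\pi}$ is exported.

**fEPSP** (`gen_fepsp_sweeps()`): per-intensity sweeps with a causal
biphasic stimulus artifact, a fast fiber volley at 2.2 ms whose
amplitude scales linearly with intensity, and a
difference-of-exponentials fEPSP (τ_rise 1 ms, τ_decay 6 ms, onset
4.5 ms) scaling linearly with intensity; paired sweeps apply a
configured facilitation ratio per interval, which is the ground-truth
PPR because slope is linear in amplitude for fixed kinetics.

All generators are pure functions of (config, seed): identical seeds
give identical traces, and the caller's RNG stream is restored.

## What the generators do and do not establish

The generators reproduce the *statistical structure* the pipeline
depends on — spectral peaks on 1/f background, exponentially decaying
cycle coherence, phase-locked spikes with amplitude spread, SW-R
complexes at controlled SNR, monotone input-output evoked responses —
so passing recovery tests establishes that each estimator measures what
it claims at realistic SNR. They are phenomenological: no
conductance-based network dynamics, no epileptiform events or
artifacts, no electrode drift, no spike-waveform diversity beyond
amplitude, no interaction between SW-R events and gamma. Conclusions
about detector behaviour on pathological or non-stationary data are
out of reach of these tests.

## Problem sizes and numerical choices

Recovery tests run on two-minute segments at 5 kHz (600 000 samples),
the canonical analysis window; the test suite uses 20–120 s segments
chosen so each check exercises the same code path at adequate SNR, and
the type-I-error simulation uses 2000 replicates of n = 15 per group.
Degenerate inputs are contracts, not crashes: empty detection sets are
valid, undefined HBW/τ/ripple frequency are missing values with reason
codes, constant traces and out-of-range windows raise errors. Ties
break deterministically everywhere (lowest frequency for spectral
peaks, larger event for detector merges, inclusive quartile boundary
for gating).

## Known limitations

The 2nd-peak convention and the triple-point-minimax and asymmetry
readings are pinned dialects of ambiguous conventions, each with the
alternative implemented behind a flag. The detector thresholds
(3 SD) include event contributions in the SD, so very high event
densities raise the bar slightly; the robust mode trades that for a
different bias. The tau fit assumes a single dominant rhythm near the
spectral peak; nested rhythms would need a different model. fEPSP
windows assume standard CA3–CA1 latencies and will need reconfiguring
for other pathways.
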