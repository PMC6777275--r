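---
title: "Methods: pulse rate variability from shift-long wrist PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse rate variability from shift-long wrist PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftpulse)
```

## Scope and data model

`shiftpulse` analyses pulse rate variability (PRV) from wrist
photoplethysmography (PPG) worn across long work shifts. Each session
contributes two device exports: the raw blood-volume-pulse (BVP) waveform,
sampled at 64 Hz with amplitudes in nanowatts, and an interbeat-interval
(IBI) log of `(offset, interval)` pairs. The IBI convention is fixed as
*interval ending at the offset beat*: every entry satisfies
`offset_s >= ibi_s`, offsets are strictly increasing, and intervals are
positive. Fixing the convention matters because run-contiguity logic — two
entries are consecutive beats exactly when
`|offset_i − offset_{i−1} − ibi_i|` is at most one sample period — depends
on which end of the interval the offset marks. The session start acts as
the reference beat, so a log may cover time from `t = 0`.

PRV is treated throughout as the PPG surrogate of heart rate variability:
intervals between pulse arrivals stand in for R-R intervals, with all the
usual caveats about peripheral measurement (pulse transit time variation,
motion sensitivity) that motivate the package's emphasis on quality
screening and yield accounting.

## The synthetic session generator

Real shift recordings are not redistributable, so the generator is a
first-class module: every downstream stage is validated against sessions
whose ground truth is known exactly.

**Beat process.** Beats come from an integral pulse frequency modulation
(IPFM) model: the instantaneous rate

$$r(t) = 1/\bar{RR} + a_{LF}\sin(2\pi f_{LF} t + \varphi_{LF})
       + a_{HF}\sin(2\pi f_{HF} t + \varphi_{HF}) + \varepsilon(t)$$

is integrated and a beat fires at each integer crossing. IPFM is preferred
over direct RR sampling because it yields self-consistent beat times and
waveform placement — the rendered pulse peaks are exactly where the log
says beats happened. The integrator step is 1/256 s with linear
interpolation at crossings, keeping beat-time quantisation far below the
1/64 s sample period; with zero modulation and noise the emitted beats are
exact multiples of the mean interval to floating-point precision. The
phases $\varphi$ are drawn uniformly per session (from the seed): a shift's
start time is arbitrary relative to the wearer's physiological rhythms, and
pinning all sessions to phase zero creates degenerate resonances (for
instance, session durations that are integer multiples of both modulation
periods make the session-mean interval nearly deterministic, which
distorts the sampling distribution of cohort statistics).

**Defaults as study conditions.** Sessions default to 9 hours
(the 14:00–23:00 shift window), a mean interval of 0.8 s, modulation at
0.10 Hz (LF) and 0.25 Hz (HF) — band centres of the standard LF
(0.05–0.15 Hz) and HF (0.15–0.40 Hz) ranges — with rate amplitudes 0.13
and 0.20 s⁻¹. To first order a rate amplitude $a$ gives an RR amplitude
$a\bar{RR}^2$, so these defaults put roughly 83 ms of LF and 128 ms of HF
interval modulation into a clean session: interval SD near 0.11 s, HF power
dominating LF, LHR near 0.4 — the variability regime typical of long
ambulatory recordings in this population. White rate jitter
(SD 0.1 s⁻¹ per integrator step) adds broadband beat-to-beat noise of a
few milliseconds.

**Artifact dropout.** The session is divided into cells of
`dropout_block_s` (default 60 s) and a `dropout_fraction` share of cells
(default 0.9) is made undetectable: no beats are logged there, no interval
may span a dropped cell, and the rendered waveform is replaced by white
noise with no pulse-band structure. Burst-like dropout mimics
motion-artifact episodes; the 0.9 default reproduces the under-10%
usable-time regime characteristic of wrist PPG worn during active clinical
work. Kept coverage is exact up to cell rounding because cells are sampled
without replacement.

**What the generator does not emulate.** Second-order statistics only: no
baroreflex coupling, no explicit respiration signal, no pulse-morphology
changes with posture or vascular tone, no slow circadian trend, and
dropout is independent of the beat process (real artifact correlates with
motion and hence possibly with heart rate). Passing tests therefore
demonstrate correctness of the estimators under a controlled variability
structure, not robustness to every failure mode of field data.

**Prescribed-RR fixtures.** For spectral validation the generator also
provides `beats_from_rr()`, which builds a beat sequence whose interval
series follows a prescribed function exactly at the beats (fixed-point
solution of `t_k = t_{k−1} + RR(t_k)`). This exists because IPFM slightly
attenuates interval-domain modulation: averaging the rate sinusoid over
one beat multiplies the recovered RR amplitude by
$\mathrm{sinc}(\pi f \bar{RR})$ — about 0.94 at 0.25 Hz and 0.8 s, i.e.
roughly 12% in power. A closed-form band-power check ("amplitude $A$ ms at
$f$ Hz carries $A^2/2$ ms² in its band") is only exact against a fixture
whose tachogram *is* that sinusoid, so those checks use `beats_from_rr()`
while band-localisation and ratio-recovery properties are tested on the
IPFM path with tolerances that absorb the sinc factor.

## Beat detection

The detector stands in for a wearable's proprietary onboard algorithm, and
no attempt is made to reproduce any vendor's exact output. It is a
deliberately simple, fully specified chain:

1. zero-phase order-2 Butterworth bandpass, 0.5–8 Hz (pulse fundamental
   plus a few harmonics, DC and drift removed, no phase distortion);
2. per-window SNR gate: consecutive 10 s windows are accepted when
   passband power exceeds 3× the out-of-band power of the raw window.
   White noise scores about the bandwidth ratio (≈0.3), clean pulse trains
   score far above 10, so the default threshold separates the regimes with
   an order-of-magnitude margin on each side;
3. local-maximum picking above an adaptive per-window threshold (half the
   98th percentile of absolute filtered amplitude), greedy refractory
   suppression (0.25 s) favouring larger peaks, and parabolic sub-sample
   refinement of each surviving peak. Refinement matters for exactness
   tests: without it, baseline noise flips the argmax to a neighbouring
   sample often enough to breach a one-sample match tolerance;
4. interval assembly: an interval is emitted only when its two beats fall
   in accepted windows with no rejected window between them, and its
   duration lies in [0.25, 3.0] s. Beats bordering a rejected window
   therefore contribute no interval, which is the behaviour the screening
   stage assumes: corrupted segments produce gaps, never spurious entries.

## Screening and cohort selection

Three rules decide inclusion, each recorded separately so an exclusion log
can attribute the violated rule: (1) the recording must overlap its
scheduled shift (any positive overlap by default; a minimum-overlap option
exists for stricter designs); (2) at least 300 registered beats, boundary
inclusive — exactly 300 passes; (3) not flagged by the manual visual
inspection of the waveform/marker overlay plot. The adjudication itself is
a human judgment: the package exports the overlay data and honours the
flag, it never sets it. A participant enters the paired cohort only with
an included session in both Q1 and Q4; with several candidates in one
quarter the earliest-dated recording is chosen, a deterministic tie-break
so repeated runs analyse the same sessions.

## Time-domain metrics

MPR, MRRI and SDNN use *every* logged interval; RMSSD alone is computed on
the single longest stretch of consecutive beats, because successive
differences across detection gaps are not physiologic. Conventions fixed
for exactness: sample (n−1) SD; even-count medians average the two middle
values; contiguity tolerance defaults to one sample period (1/64 s), so a
one-sample bookkeeping discrepancy keeps a run intact and two samples
split it; equal-length runs resolve to the earliest. Degenerate inputs
raise errors rather than silently degrade (empty logs, runs shorter than
two intervals), except in the convenience wrapper
`time_domain_metrics()`, which reports RMSSD as `NA` with a warning when
no run of two beats exists.

## Frequency-domain metrics

Spectra are computed from the interval series, not the raw 64 Hz waveform:
band powers in ms² are quantities of the tachogram, and the raw waveform's
spectrum is dominated by the pulse fundamental near 1.25 Hz, far above
both bands. The longest contiguous run (the whole log is available as a
config switch) supplies `(offset, interval)` knots; a cubic spline
interpolates them onto a uniform 4 Hz grid — comfortably above twice the
upper HF edge — and Welch's method (Hann windows, 300 s segments, 50%
overlap, per-segment linear detrend) estimates the one-sided PSD of the
interval series in milliseconds. Band power integrates the PSD by
trapezoid over half-open bands `[lo, hi)`, so the shared 0.15 Hz edge is
counted once. Runs shorter than two segments shrink the segment to the run
length (single-segment periodogram, reported via a message); runs shorter
than ~13 s are rejected as unable to resolve the bands at all. A constant
run yields zero power after detrending; HF power of zero makes the ratio
an error rather than an infinity.

Numerical behaviour worth knowing: spline resampling rolls off tachogram
content above the beat-rate Nyquist (~0.6 Hz at 0.8 s intervals), which is
harmless for bands ending at 0.40 Hz; and Welch windowing makes the
Parseval identity approximate (within ~10% on white input), which bounds
how exactly band powers can be compared across estimators.

## Yield

Coverage is per-sample at the recording rate: a sample is covered when it
falls inside some logged interval `[offset − ibi, offset]` (closed;
adjacent intervals share an endpoint but the boolean union counts each
sample once). The quotient is 100·covered/total. A literal 1-second-bin
reading ("a bin is covered if any covered sample falls in it", bins
anchored at t = 0) is available as a sensitivity-analysis mode; the
per-sample reading is primary because it has a unique answer independent
of bin anchoring. Across sessions the quotient is *pooled* —
Σcovered/Σtotal, quarters of an hour of dead recording weigh against the
total — rather than averaging per-session percentages; with equal-length
sessions the two coincide, otherwise pooling is the time-weighted reading
of "interpretable share of all recorded time".

## Cohort statistics

Each of the seven metrics (MPR, MRRI, SDNN, RMSSD, LF, HF, LHR) enters a
two-sided paired Student t test on Q4 − Q1 differences. Post-hoc power is
the noncentral-t power at the observed standardized paired effect
$d_z = \bar{d}/s_d$: with $T \sim t(n-1,\; \sqrt{n}\,d_z)$ and two-sided
critical value $t_{crit}$, power = $P(|T| > t_{crit})$. This is the
standard definition, validated in the test suite against a Monte-Carlo
oracle of 10⁵ simulated experiments rather than against any published
table. A zero observed effect gives power exactly α, the correct
degenerate value. Identical pairs give t = 0, p = 1; zero-variance
differences with nonzero mean report infinite t with p → 0 and a warning.
No multiple-testing correction is applied across the seven tests — the
comparison is deliberately reported as uncorrected repeated univariate
tests, and the printed table says so.

## Problem sizes used in validation

The test suite exercises the statistics at the sizes the methods are meant
for while keeping fixtures cheap to regenerate: oracle equivalence on
1,000 random logs; spectral recovery on 1-hour prescribed-RR sessions;
detector fidelity (sensitivity and precision at a one-sample match
tolerance) on 2-minute clean sessions; type-I calibration on 200 null
cohorts of 21 participants with 5-minute sessions; p-value uniformity on
5,000 simulated null cohorts; power validation against 10⁵-replicate
Monte-Carlo oracles; and end-to-end effect recovery (a one-SD mean-interval
shift at n = 21) over 100 replicate cohorts of 7-minute sessions run
through the full waveform → detector → metrics path. Session lengths in
cohort simulations are the package's choice of fixture scale; the
estimators themselves carry no hidden dependence on them beyond the
documented run-length requirements.

## Known limitations

- The detector is designed for the generator's pulse template family;
  field PPG with strong baseline wander, morphology variation or
  arrhythmia would need retuning (bandpass edges, SNR threshold) and
  possibly template-based delineation, which is out of scope.
- IBI-derived PRV is a surrogate for HRV; nothing here corrects for pulse
  transit time variability.
- The frequency pipeline assumes the analysed run is stationary; no
  time-varying (wavelet/Lomb-Scargle) alternative is provided.
- Yield attributes no cause to missing coverage (motion vs contact vs
  detector conservatism); it is a single descriptive quotient.
- Post-hoc power at the observed effect is reported because the design
  calls for it; it is a deterministic transform of the p value and should
  be read as such, not as independent evidence.
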