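# shiftpulse

Pulse rate variability (PRV) analysis for wearable wrist photoplethysmography
(PPG) recordings collected over long work shifts.

Wrist-worn PPG biosensors promise a low-burden, scalable way to track
autonomic markers of workplace stress — for example in emergency physicians
over an academic year — but ambulatory wrist recordings are dominated by
motion artifact and intermittent skin contact, so only a small fraction of
the recorded time yields interpretable beat data. `shiftpulse` provides the
complete analysis path such a study needs, with every stage tested against
independent oracles:

- **Session I/O** — strict readers/writers for the two per-shift exports: a
  raw blood-volume-pulse (BVP) waveform at 64 Hz and an interbeat-interval
  (IBI) log of `(beat offset, interval)` pairs, plus a JSON metadata sidecar.
- **Synthetic sessions with exact ground truth** — an integral pulse
  frequency modulation (IPFM) beat process with LF (0.05–0.15 Hz) and HF
  (0.15–0.40 Hz) rate modulation, white rate jitter, burst-like artifact
  dropout, and a rendered pulse waveform; used both as test oracle and
  cohort simulator.
- **Beat detection** — zero-phase Butterworth bandpass, adaptive peak
  picking with refractory suppression and parabolic sub-sample refinement,
  and a per-window SNR gate so corrupted segments emit no intervals.
- **Screening** — the inclusion rules of a paired repeated-measures design:
  shift-overlap check, a minimum of 300 registered beats (inclusive), a
  manual-exclusion flag from visual inspection, and selection of
  participants with one satisfactory recording in both Q1 (July–September)
  and Q4 (April–June).
- **Time-domain metrics** — median pulse rate (MPR), mean R-R interval
  (MRRI), SDNN, and RMSSD, the last computed on the single longest stretch
  of consecutive beats.
- **Frequency-domain metrics** — the IBI series of the longest run is
  cubic-spline resampled to a uniform 4 Hz tachogram; Welch's method
  (300 s Hann segments, 50% overlap, linear detrend) gives LF and HF power
  in ms² and their ratio LHR = LF/HF.
- **Yield** — the interpretable-time quotient: the share of the grand total
  recording time covered by detected beat-to-beat intervals, pooled across
  sessions as Σcovered/Σtotal.
- **Cohort statistics** — paired Student t tests on Q4 − Q1 differences for
  all seven metrics, with post-hoc power from the noncentral t distribution
  at the observed standardized effect.

## Core model

Time-domain statistics over the logged intervals `RR_i` (seconds):

    MPR   = median(60 / RR_i)                      [beats/min]
    MRRI  = mean(RR_i)                             [s]
    SDNN  = sd(RR_i)            (n − 1 denominator)
    RMSSD = sqrt(mean((RR_{i+1} − RR_i)^2))        [longest contiguous run]

Frequency domain: band power is the trapezoid integral of the one-sided
Welch PSD of the tachogram (in ms) over `[0.05, 0.15)` Hz (LF) and
`[0.15, 0.40)` Hz (HF); a sinusoidal interval modulation of amplitude `A` ms
carries `A²/2` ms² into its band. The paired comparison uses
`t = mean(d)/(sd(d)/√n)` on `d = Q4 − Q1` with `n − 1` df, and post-hoc
power `P(|T| > t_crit)` for `T ~ t(n − 1, ncp = √n·mean(d)/sd(d))`.

## Worked example

```r
library(shiftpulse)

# one 30-minute session with 50% artifact dropout, known ground truth
cfg   <- synth_config(duration_s = 1800, dropout_fraction = 0.5, seed = 42)
truth <- generate_rr_series(cfg)
ibi   <- truth_to_ibi(truth)          # device-style interbeat log

time_domain_metrics(ibi)
#> <time_domain_metrics> MPR 76.5 bpm | MRRI 0.800 s | SDNN 0.104 s | RMSSD 0.109 s (run of 225 / 1117 beats)
freq_domain_metrics(ibi)
#> <freq_domain_metrics> LF 3.63e+03 ms^2 | HF 7.45e+03 ms^2 | LHR 0.488 (run: 225 beats, 179 s)
session_yield(ibi, cfg$duration_s)
#> <yield_report> 893.4 of 1800.0 s interpretable (49.63%) over 1 session(s)
```

The mean interval is recovered at 0.800 s, SDNN/RMSSD sit near 0.10 s, the
LF:HF ratio near 0.5 reflects the HF-dominant modulation the generator
injects, and the yield quotient tracks the injected 50% dropout.

A paired cohort with an injected Q4 effect (+0.05 s mean interval, clean
10-minute sessions):

```r
co <- make_cohort(8, effect = list(mean_rr_s = 0.05), seed = 7,
                  base_config = synth_config(duration_s = 600, dropout_fraction = 0))
summarize_cohort(cohort_metrics(co))
#> Paired Q1 vs Q4 comparison (all, alpha = 0.05)
#>  metric                  q1                  q4 t_stat  p_value power n_pairs
#>     MPR         76.3 (5.14)           72 (4.48) -16.87 6.31e-07 1.000       8
#>    MRRI      0.803 (0.0524)      0.853 (0.0523) 736.52 2.25e-18 1.000       8
#>    SDNN      0.104 (0.0198)      0.116 (0.0217)  18.06 3.95e-07 1.000       8
#>   RMSSD      0.105 (0.0216)      0.124 (0.0245)  17.53 4.83e-07 1.000       8
#>      LF 4.57e+03 (3.74e+03) 5.79e+03 (4.72e+03)   3.52 9.70e-03 0.854       8
#>      HF 6.76e+03 (2.37e+03) 8.41e+03 (2.92e+03)   8.15 8.11e-05 1.000       8
#>     LHR       0.798 (0.911)       0.825 (0.961)   1.46 1.87e-01 0.244       8
#> Note: P values are from uncorrected paired t tests; no multiple-testing correction is applied.
```

The injected interval shift is detected decisively (MRRI row), drags MPR in
the opposite direction as expected, and the ratio metric LHR — which the
shift leaves invariant to first order — stays null.

`run_pipeline(run_config(...))` orchestrates the same stages end to end
from files on disk (simulate → detect → screen → metrics → yield →
compare), persisting every intermediate as CSV/JSON.

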