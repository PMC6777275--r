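#' Spectral analysis configuration
#'
#' Parameters of the frequency-domain pipeline: cubic-spline resampling of
#' the beat-interval series to a uniform tachogram, Welch's averaged
#' periodogram, and trapezoid integration of the PSD over the standard
#' low-frequency (0.05-0.15 Hz) and high-frequency (0.15-0.40 Hz) bands.
#' Intervals are expressed in milliseconds before squaring so band powers
#' come out in ms^2. Band membership is half-open `[lo, hi)` so the shared
#' 0.15 Hz edge is never counted twice.
#'
#' @param lf_band,hf_band Length-2 band edges in Hz; `lf_band[2]` must not
#'   exceed `hf_band[1]`.
#' @param resample_rate_hz Uniform tachogram rate; must exceed twice the
#'   upper HF edge.
#' @param psd_segment_s Welch segment length in seconds (Hann window). When
#'   a run is shorter than two segments the segment shrinks to the run
#'   length (single-segment periodogram) with a message.
#' @param psd_overlap Fractional overlap of consecutive segments.
#' @param detrend `"linear"` (default) or `"constant"` per-segment detrend.
#' @param use_longest_run If `TRUE` (default) spectra are computed from the
#'   longest contiguous beat run; if `FALSE`, from the whole log treated as
#'   one knot series.
#' @return Object of class `spectral_config`.
#' @export
spectral_config <- function(lf_band = c(0.05, 0.15), hf_band = c(0.15, 0.40),
                            resample_rate_hz = 4, psd_segment_s = 300,
                            psd_overlap = 0.5,
                            detrend = c("linear", "constant"),
                            use_longest_run = TRUE) {
  detrend <- match.arg(detrend)
  stopifnot(length(lf_band) == 2L, length(hf_band) == 2L)
  if (any(c(lf_band, hf_band) <= 0) || lf_band[1] >= lf_band[2] ||
      hf_band[1] >= hf_band[2]) {
    stopf("band edges must be positive and increasing")
  }
  if (lf_band[2] > hf_band[1] + 1e-12) {
    stopf("LF band must not extend beyond the lower HF edge")
  }
  check_scalar(resample_rate_hz, "resample_rate_hz", lower = 1e-6)
  if (resample_rate_hz <= 2 * hf_band[2]) {
    stopf("resample_rate_hz must exceed 2 * upper HF edge (%g Hz)",
          2 * hf_band[2])
  }
  check_scalar(psd_segment_s, "psd_segment_s", lower = 1)
  check_scalar(psd_overlap, "psd_overlap", lower = 0)
  if (psd_overlap >= 1) stopf("`psd_overlap` must be < 1")
  structure(
    list(lf_band = as.numeric(lf_band), hf_band = as.numeric(hf_band),
         resample_rate_hz = resample_rate_hz, psd_segment_s = psd_segment_s,
         psd_overlap = psd_overlap, detrend = detrend,
         use_longest_run = use_longest_run),
    class = "spectral_config"
  )
}

#' Evenly resampled RR tachogram
#'
#' Cubic-spline interpolation of the `(beat offset, interval)` knots of a
#' contiguous beat run onto a uniform grid. The interpolant passes through
#' every knot, so a constant run yields a constant tachogram and the grid
#' values track the underlying modulation.
#'
#' @param run A [longest_contiguous_run()] result (or an [ibi_log()], whose
#'   entries are then used as knots directly).
#' @param cfg A [spectral_config()].
#' @return Object of class `rr_tachogram`: `time_s`, `rr_s`, `fs_hz`.
#' @export
tachogram <- function(run, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  if (inherits(run, "beat_run")) {
    t_knot <- run$offset_s
    y_knot <- run$rr_s
  } else if (inherits(run, "ibi_log")) {
    t_knot <- run$offset_s
    y_knot <- run$ibi_s
  } else {
    stopf("`run` must be a beat_run or ibi_log")
  }
  if (length(t_knot) < 4L) stopf("tachogram needs at least 4 beats")
  span <- t_knot[length(t_knot)] - t_knot[1]
  if (span < 2 / cfg$hf_band[1]) {
    stopf("run spans %.1f s; need at least %.1f s to resolve the LF band",
          span, 2 / cfg$hf_band[1])
  }
  f <- splinefun(t_knot, y_knot, method = "fmm")
  grid <- seq(t_knot[1], t_knot[length(t_knot)], by = 1 / cfg$resample_rate_hz)
  structure(list(time_s = grid, rr_s = f(grid), fs_hz = cfg$resample_rate_hz),
            class = "rr_tachogram")
}

# Welch averaged periodogram: Hann window, per-segment detrend, one-sided
# PSD in x^2/Hz. No installed R package exposes this estimator, so it is
# implemented here on top of stats::fft.
welch_psd <- function(x, fs, segment_s, overlap = 0.5,
                      detrend = c("linear", "constant")) {
  detrend <- match.arg(detrend)
  n <- length(x)
  if (n < 16L) stopf("series too short for a PSD estimate (%d samples)", n)
  target <- round(segment_s * fs)
  L <- min(target, n)
  if (L < target) {
    message(sprintf("PSD segment shrunk from %g s to %.1f s (series length)",
                    segment_s, L / fs))
  }
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L))
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  idx <- seq_len(L)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (detrend == "constant") {
      seg <- seg - mean(seg)
    } else {
      mx <- mean(idx)
      my <- mean(seg)
      b <- sum((idx - mx) * (seg - my)) / sum((idx - mx)^2)
      seg <- seg - (my + b * (idx - mx))
    }
    p <- Mod(fft(seg * w)[seq_len(nf)])^2 / (fs * U)
    acc <- acc + p
  }
  psd <- acc / length(starts)
  # one-sided: double all interior bins (not DC, not Nyquist when L even)
  last_interior <- if (L %% 2L == 0L) nf - 1L else nf
  if (last_interior >= 2L) {
    psd[2:last_interior] <- 2 * psd[2:last_interior]
  }
  list(freq_hz = (seq_len(nf) - 1L) * fs / L, psd = psd)
}

#' Band power of an RR tachogram (ms^2)
#'
#' Welch PSD of the tachogram (intervals converted to milliseconds first)
#' integrated over `[lo, hi)` by the trapezoid rule on the discrete
#' frequency grid. A pure sinusoidal modulation of amplitude `A` ms yields
#' `A^2 / 2` ms^2 in its band.
#'
#' @param tacho An [tachogram()] result.
#' @param band Length-2 numeric `(lo, hi)` in Hz; must sit below the
#'   tachogram Nyquist rate.
#' @param cfg A [spectral_config()] supplying the Welch parameters.
#' @return Band power in ms^2 (non-negative).
#' @export
band_power <- function(tacho, band, cfg = spectral_config()) {
  stopifnot(inherits(tacho, "rr_tachogram"), inherits(cfg, "spectral_config"))
  stopifnot(length(band) == 2L)
  if (band[1] <= 0 || band[2] <= band[1]) {
    stopf("band edges must be positive and increasing")
  }
  if (band[2] > tacho$fs_hz / 2 + 1e-12) {
    stopf("band [%g, %g] Hz exceeds the tachogram Nyquist rate %g Hz",
          band[1], band[2], tacho$fs_hz / 2)
  }
  dur <- tacho$time_s[length(tacho$time_s)] - tacho$time_s[1]
  if (dur < 2 / band[1]) {
    stopf("tachogram spans %.1f s; need >= %.1f s to resolve %g Hz",
          dur, 2 / band[1], band[1])
  }
  sp <- welch_psd(tacho$rr_s * 1000, tacho$fs_hz, cfg$psd_segment_s,
                  cfg$psd_overlap, cfg$detrend)
  sel <- sp$freq_hz >= band[1] & sp$freq_hz < band[2]
  if (sum(sel) < 2L) stopf("fewer than 2 PSD bins fall inside the band")
  max(trapz(sp$freq_hz[sel], sp$psd[sel]), 0)
}

#' LF:HF ratio
#'
#' @param lf_power,hf_power Band powers in ms^2; `hf_power` must be
#'   positive.
#' @return Dimensionless ratio `lf_power / hf_power`.
#' @export
lf_hf_ratio <- function(lf_power, hf_power) {
  check_scalar(lf_power, "lf_power", lower = 0)
  check_scalar(hf_power, "hf_power", lower = 0)
  if (hf_power == 0) stopf("LF:HF ratio undefined: HF power is zero")
  lf_power / hf_power
}

#' Frequency-domain metrics of a session
#'
#' Computes LF power, HF power and their ratio from an IBI log: the longest
#' contiguous run (or the whole log, per the config) is spline-resampled to
#' a uniform tachogram and Welch band powers are integrated over the LF and
#' HF bands.
#'
#' @param ibi An [ibi_log()].
#' @param cfg A [spectral_config()].
#' @param contiguity_tol Run contiguity tolerance passed to
#'   [longest_contiguous_run()].
#' @return Object of class `freq_domain_metrics`: `lf_power_ms2`,
#'   `hf_power_ms2`, `lhr`, `run_beats`, `run_span_s`.
#' @export
freq_domain_metrics <- function(ibi, cfg = spectral_config(),
                                contiguity_tol = 1 / 64) {
  stopifnot(inherits(ibi, "ibi_log"))
  src <- if (cfg$use_longest_run) {
    longest_contiguous_run(ibi, contiguity_tol)
  } else {
    ibi
  }
  tacho <- tachogram(src, cfg)
  lf <- band_power(tacho, cfg$lf_band, cfg)
  hf <- band_power(tacho, cfg$hf_band, cfg)
  structure(
    list(lf_power_ms2 = lf, hf_power_ms2 = hf,
         lhr = lf_hf_ratio(lf, hf),
         run_beats = if (inherits(src, "beat_run")) src$n_beats else beat_count(src),
         run_span_s = tacho$time_s[length(tacho$time_s)] - tacho$time_s[1]),
    class = "freq_domain_metrics"
  )
}

#' @export
print.freq_domain_metrics <- function(x, ...) {
  cat(sprintf("<freq_domain_metrics> LF %.3g ms^2 | HF %.3g ms^2 | LHR %.3f (run: %d beats, %.0f s)\n",
              x$lf_power_ms2, x$hf_power_ms2, x$lhr, x$run_beats, x$run_span_s))
  invisible(x)
}
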