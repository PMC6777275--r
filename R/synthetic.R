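#' Configuration for the synthetic session generator
#'
#' Defines one simulated wrist-PPG session. Beat times come from an integral
#' pulse frequency modulation (IPFM) process: the instantaneous pulse rate
#'
#' \deqn{r(t) = 1/\bar{RR} + a_{LF}\sin(2\pi f_{LF} t)
#'            + a_{HF}\sin(2\pi f_{HF} t) + \epsilon(t)}
#'
#' is integrated and a beat fires each time the integral crosses an integer.
#' The two sinusoidal terms place rate modulation inside the standard
#' low-frequency (0.05-0.15 Hz) and high-frequency (0.15-0.40 Hz) bands of
#' short-term variability analysis; \eqn{\epsilon(t)} is white rate jitter
#' held constant over each integrator step. To first order a rate modulation
#' of amplitude `a` produces an RR modulation of amplitude
#' `a * mean_rr_s^2` seconds.
#'
#' The default modulation amplitudes (0.13 s^-1 LF, 0.20 s^-1 HF at a mean
#' interval of 0.8 s, i.e. RR amplitudes of roughly 83 and 128 ms) are
#' chosen so that a clean default session lands in the variability regime
#' typical of long ambulatory wrist recordings: interval SD near 0.11 s and
#' an LF:HF ratio near 0.4, with high-frequency (respiratory-band) power
#' dominating.
#'
#' Artifact dropout emulates the motion-artifact bursts that dominate
#' real-world wrist recordings: the session is divided into cells of
#' `dropout_block_s` seconds and a `dropout_fraction` share of cells is
#' rendered undetectable (no beats logged, waveform replaced by
#' detection-defeating noise). The default `dropout_fraction = 0.9`
#' reproduces the regime reported for ambulatory emergency-department
#' recordings, where under 10% of recorded time yields usable beat data.
#'
#' @param duration_s Session length in seconds (default 32400 = the 9-hour
#'   14:00-23:00 shift).
#' @param mean_rr_s Mean interbeat interval in seconds (0.25-3.0).
#' @param lf_mod,hf_mod Length-2 numeric `c(freq_hz, amp)`; modulation
#'   frequency must lie inside the LF (0.05-0.15 Hz) / HF (0.15-0.40 Hz)
#'   band respectively; amplitude is in rate units (beats/s).
#' @param white_noise_sd SD of the white rate jitter (beats/s per integrator
#'   step).
#' @param dropout_fraction Fraction of session time rendered undetectable,
#'   in `[0, 1)`.
#' @param dropout_block_s Length of one dropout cell in seconds; adjacent
#'   sampled cells merge into longer bursts.
#' @param pulse_amp Peak amplitude of the per-beat waveform template
#'   (nanowatts).
#' @param pulse_width_s Gaussian width (SD) of the template's systolic peak.
#' @param baseline_noise_sd SD of additive baseline noise on the rendered
#'   waveform.
#' @param dropout_noise_sd SD of the white noise that replaces the waveform
#'   inside dropout blocks.
#' @param sampling_rate_hz Waveform sampling rate (64 Hz for the emulated
#'   device).
#' @param integrator_step_s IPFM integrator step; the default 1/256 s keeps
#'   beat-time quantisation well below the 1/64 s sample period.
#' @param seed Integer RNG seed; every stochastic element of the session is
#'   a pure function of the config including this seed.
#' @return An object of class `synth_config`.
#' @seealso [generate_rr_series()], [render_bvp()], [make_cohort()]
#' @export
synth_config <- function(duration_s = 32400, mean_rr_s = 0.8,
                         lf_mod = c(0.10, 0.13), hf_mod = c(0.25, 0.20),
                         white_noise_sd = 0.1, dropout_fraction = 0.9,
                         dropout_block_s = 60, pulse_amp = 1,
                         pulse_width_s = 0.06, baseline_noise_sd = 0.05,
                         dropout_noise_sd = 0.5, sampling_rate_hz = 64,
                         integrator_step_s = 1 / 256, seed = 1L) {
  check_scalar(duration_s, "duration_s", lower = 0)
  check_scalar(mean_rr_s, "mean_rr_s", lower = 0.25, upper = 3.0)
  stopifnot(length(lf_mod) == 2L, length(hf_mod) == 2L)
  if (lf_mod[2] != 0 && (lf_mod[1] <= 0.05 || lf_mod[1] >= 0.15)) {
    stopf("lf_mod frequency must lie in (0.05, 0.15) Hz, got %g", lf_mod[1])
  }
  if (hf_mod[2] != 0 && (hf_mod[1] <= 0.15 || hf_mod[1] >= 0.40)) {
    stopf("hf_mod frequency must lie in (0.15, 0.40) Hz, got %g", hf_mod[1])
  }
  check_scalar(white_noise_sd, "white_noise_sd", lower = 0)
  check_scalar(dropout_fraction, "dropout_fraction", lower = 0)
  if (dropout_fraction >= 1) stopf("`dropout_fraction` must be < 1")
  check_scalar(dropout_block_s, "dropout_block_s", lower = 1e-6)
  check_scalar(integrator_step_s, "integrator_step_s", lower = 1e-9)
  structure(
    list(duration_s = duration_s, mean_rr_s = mean_rr_s,
         lf_mod = as.numeric(lf_mod), hf_mod = as.numeric(hf_mod),
         white_noise_sd = white_noise_sd,
         dropout_fraction = dropout_fraction,
         dropout_block_s = dropout_block_s,
         pulse_amp = pulse_amp, pulse_width_s = pulse_width_s,
         baseline_noise_sd = baseline_noise_sd,
         dropout_noise_sd = dropout_noise_sd,
         sampling_rate_hz = sampling_rate_hz,
         integrator_step_s = integrator_step_s,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate ground-truth beat times from an IPFM process
#'
#' Integrates the modulated instantaneous rate of `config` and emits a beat
#' at every integer crossing of the integral (session start acts as the
#' reference beat at t = 0, so the first interval ends at the first emitted
#' beat). Dropout blocks are drawn here as well so that the whole ground
#' truth is fixed by the config.
#'
#' @param config A [synth_config()].
#' @return An object of class `ground_truth`: `beat_times` (strictly
#'   increasing, within `(0, duration_s]`), `rr_s` (true interval series,
#'   `diff(c(0, beat_times))`), `dropout_blocks` (two-column matrix of
#'   merged `[start, end)` intervals), `coverage_fraction`, and
#'   `expected_rr_amp_ms` / `expected_band_power_ms2` (first-order
#'   closed-form LF/HF tachogram amplitudes and band powers implied by the
#'   modulation).
#' @export
#' @examples
#' cfg <- synth_config(duration_s = 60, dropout_fraction = 0,
#'                     white_noise_sd = 0, seed = 7)
#' truth <- generate_rr_series(cfg)
#' range(truth$rr_s)
generate_rr_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dt <- config$integrator_step_s
  n_steps <- ceiling(config$duration_s / dt)
  if (n_steps < 1L) stopf("session too short for the integrator step")
  base_rate <- 1 / config$mean_rr_s

  beats <- with_seed(derive_seed(config$seed, 1L), {
    out <- vector("list", 16L)
    k <- 0L
    chunk <- 1000000L
    t_prev <- 0
    cum_prev <- 0
    i0 <- 1L
    # session start is arbitrary relative to the physiological rhythms, so
    # each modulation component starts at a random (seed-fixed) phase
    phi <- if (config$lf_mod[2] > 0 || config$hf_mod[2] > 0) {
      runif(2, 0, 2 * pi)
    } else c(0, 0)
    while (i0 <= n_steps) {
      i1 <- min(i0 + chunk - 1L, n_steps)
      tt <- (i0:i1) * dt
      r <- base_rate +
        config$lf_mod[2] * sin(2 * pi * config$lf_mod[1] * tt + phi[1]) +
        config$hf_mod[2] * sin(2 * pi * config$hf_mod[1] * tt + phi[2])
      if (config$white_noise_sd > 0) {
        r <- r + rnorm(length(tt), sd = config$white_noise_sd)
      }
      r <- pmax(r, 1 / 3.0)  # rate floor keeps the integral increasing
      cum <- cum_prev + cumsum(r * dt)
      targets <- seq.int(floor(cum_prev) + 1L, floor(cum[length(cum)]))
      if (length(targets) && targets[1] <= cum[length(cum)]) {
        bt <- approx(c(cum_prev, cum), c(t_prev, tt), xout = targets,
                     ties = "ordered")$y
        k <- k + 1L
        if (k > length(out)) out <- c(out, vector("list", length(out)))
        out[[k]] <- bt
      }
      t_prev <- tt[length(tt)]
      cum_prev <- cum[length(cum)]
      i0 <- i1 + 1L
    }
    unlist(out[seq_len(k)])
  })
  beats <- beats[beats <= config$duration_s + 1e-12]

  blocks <- draw_dropout_blocks(config)
  rr <- diff(c(0, beats))
  structure(
    list(beat_times = beats, rr_s = rr, duration_s = config$duration_s,
         dropout_blocks = blocks,
         coverage_fraction = 1 - blocked_time(blocks) / config$duration_s,
         expected_rr_amp_ms = c(
           lf = 1000 * config$lf_mod[2] * config$mean_rr_s^2,
           hf = 1000 * config$hf_mod[2] * config$mean_rr_s^2),
         expected_band_power_ms2 = c(
           lf = (1000 * config$lf_mod[2] * config$mean_rr_s^2)^2 / 2,
           hf = (1000 * config$hf_mod[2] * config$mean_rr_s^2)^2 / 2),
         config = config),
    class = "ground_truth"
  )
}

# Contiguous random dropout blocks on a fixed cell grid. Returns a merged
# two-column matrix of [start, end) intervals; the dropped share of cells
# equals round(dropout_fraction * n_cells) so the kept fraction is exact up
# to cell rounding.
draw_dropout_blocks <- function(config) {
  if (config$dropout_fraction <= 0 || config$duration_s <= 0) {
    return(matrix(numeric(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  n_cells <- max(1L, round(config$duration_s / config$dropout_block_s))
  cell_len <- config$duration_s / n_cells
  n_drop <- round(config$dropout_fraction * n_cells)
  n_drop <- min(n_drop, n_cells - 1L)  # never drop the whole session
  if (n_drop < 1L) {
    return(matrix(numeric(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  dropped <- with_seed(derive_seed(config$seed, 2L),
                       sort(sample.int(n_cells, n_drop)))
  # merge adjacent cells into bursts
  grp <- cumsum(c(1L, diff(dropped) != 1L))
  starts <- (dropped[!duplicated(grp)] - 1L) * cell_len
  ends <- dropped[rev(!duplicated(rev(grp)))] * cell_len
  cbind(start = starts, end = ends)
}

blocked_time <- function(blocks) {
  if (!nrow(blocks)) 0 else sum(blocks[, 2] - blocks[, 1])
}

# TRUE for times falling inside any [start, end) dropout block.
in_dropout <- function(times, blocks) {
  if (!nrow(blocks) || !length(times)) return(rep(FALSE, length(times)))
  edges <- as.vector(t(blocks))  # start1, end1, start2, end2, ...
  findInterval(times, edges) %% 2L == 1L
}

#' Per-sample coverage mask of a ground-truth session
#'
#' @param truth A [generate_rr_series()] result.
#' @param sampling_rate_hz Sample grid rate; defaults to the config's.
#' @return Logical vector, one element per waveform sample, `TRUE` where the
#'   session is outside every dropout block (beats are renderable there).
#' @export
coverage_mask <- function(truth, sampling_rate_hz = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  fs <- if (is.null(sampling_rate_hz)) truth$config$sampling_rate_hz else sampling_rate_hz
  n <- round(truth$duration_s * fs)
  !in_dropout((seq_len(n) - 1) / fs, truth$dropout_blocks)
}

#' Device-style IBI log implied by a ground-truth session
#'
#' Emulates the wearable's onboard logging under the session's dropout
#' pattern: beats inside dropout blocks are never registered, and an
#' interval is logged only when it joins two registered beats without
#' crossing a dropout block (intervals longer than `max_gap_s` are treated
#' as detector restarts and discarded).
#'
#' @param truth A [generate_rr_series()] result.
#' @param max_gap_s Longest loggable interval in seconds.
#' @param session_start Epoch start time stamped on the log.
#' @return An [ibi_log()].
#' @export
truth_to_ibi <- function(truth, max_gap_s = 3.0, session_start = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  beats <- c(0, truth$beat_times)  # session start is the reference beat
  keep <- !in_dropout(beats, truth$dropout_blocks)
  beats <- beats[keep]
  if (length(beats) < 2L) return(ibi_log(session_start = session_start))
  ta <- beats[-length(beats)]
  tb <- beats[-1]
  gap_ok <- (tb - ta) <= max_gap_s
  blocks <- truth$dropout_blocks
  if (nrow(blocks)) {
    n_starts <- findInterval(tb, blocks[, 1]) - findInterval(ta, blocks[, 1])
    clean <- n_starts == 0L
  } else {
    clean <- rep(TRUE, length(ta))
  }
  sel <- gap_ok & clean
  ibi_log(tb[sel], tb[sel] - ta[sel], session_start)
}

#' Render a BVP waveform for a ground-truth session
#'
#' Places a fixed difference-of-Gaussians pulse template (sharp systolic
#' peak plus a delayed, smaller dicrotic bump) at every beat falling outside
#' the dropout blocks, adds baseline noise, and replaces dropout blocks with
#' structureless white noise so a downstream detector's quality gate has
#' genuine artifact segments to reject.
#'
#' @param truth A [generate_rr_series()] result.
#' @param config The same [synth_config()]; rendering noise is seeded from
#'   it, so `render_bvp()` is deterministic given `(truth, config)`.
#' @param start_time Epoch start stamped on the recording.
#' @return A [bvp_recording()] of `round(duration_s * sampling_rate_hz)`
#'   samples.
#' @export
render_bvp <- function(truth, config = truth$config, start_time = 0) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "synth_config"))
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  mask <- coverage_mask(truth, fs)
  sigma <- config$pulse_width_s
  delay <- 3 * sigma      # dicrotic bump delay
  lo <- -4 * sigma
  hi <- delay + 4 * 1.8 * sigma
  x <- with_seed(derive_seed(config$seed, 3L), {
    x <- rnorm(n, sd = config$baseline_noise_sd)
    render_beats <- truth$beat_times[!in_dropout(truth$beat_times,
                                                 truth$dropout_blocks)]
    for (tb in render_beats) {
      i0 <- max(1L, floor((tb + lo) * fs) + 1L)
      i1 <- min(n, ceiling((tb + hi) * fs) + 1L)
      if (i0 > i1) next
      tau <- (seq.int(i0, i1) - 1) / fs - tb
      x[i0:i1] <- x[i0:i1] + config$pulse_amp *
        (exp(-tau^2 / (2 * sigma^2)) -
           0.35 * exp(-(tau - delay)^2 / (2 * (1.8 * sigma)^2)))
    }
    if (any(!mask)) {
      x[!mask] <- rnorm(sum(!mask), sd = config$dropout_noise_sd)
    }
    x
  })
  bvp_recording(x, fs, start_time)
}

#' Beat sequence following a prescribed RR function
#'
#' Builds beat times such that the interval ending at each beat equals
#' `rr_fn` evaluated at that beat (solved by fixed-point iteration), so the
#' logged `(offset, ibi)` knots lie exactly on the prescribed RR curve. This
#' is the fixture generator used to validate spectral estimators against
#' closed-form sinusoid power: for
#' `rr_fn = function(t) 0.8 + A * sin(2 * pi * f * t)` the tachogram is the
#' stated sinusoid and its band power is `(1000 * A)^2 / 2` ms^2.
#'
#' @param rr_fn Function mapping time (s) to interval duration (s); must
#'   return values in (0.25, 3).
#' @param duration_s Session length in seconds.
#' @return A list with `beat_times` and `rr_s` (class `rr_track`), directly
#'   convertible with [ibi_log()].
#' @export
#' @examples
#' trk <- beats_from_rr(function(t) 0.8 + 0.01 * sin(2 * pi * 0.25 * t), 60)
#' log <- ibi_log(trk$beat_times, trk$rr_s)
beats_from_rr <- function(rr_fn, duration_s) {
  check_scalar(duration_s, "duration_s", lower = 1e-6)
  beats <- numeric(ceiling(duration_s / 0.25) + 1L)
  k <- 0L
  t_prev <- 0
  repeat {
    g <- t_prev + rr_fn(t_prev)
    for (it in 1:6) g <- t_prev + rr_fn(g)
    if (!is.finite(g) || g - t_prev <= 0.25 - 1e-9 || g - t_prev >= 3 + 1e-9) {
      stopf("rr_fn produced an interval outside (0.25, 3) s at t = %.3f", t_prev)
    }
    if (g > duration_s) break
    k <- k + 1L
    beats[k] <- g
    t_prev <- g
  }
  beats <- beats[seq_len(k)]
  structure(list(beat_times = beats, rr_s = diff(c(0, beats))),
            class = "rr_track")
}

#' Simulate a paired Q1/Q4 cohort
#'
#' Draws per-participant generating parameters around the supplied base
#' config (between-participant spread in mean interval and modulation
#' amplitudes), then applies the stated Q4 - Q1 parameter shift to the Q4
#' session of every participant. Residents and attendings are assigned in
#' a roughly even split (`floor(n/2)` residents).
#'
#' @param n_participants Number of paired participants (>= 2).
#' @param effect Named list of additive Q4 - Q1 shifts applied to generating
#'   parameters; recognised names: `mean_rr_s`, `lf_amp`, `hf_amp`,
#'   `white_noise_sd`. Empty list = null cohort.
#' @param seed Integer seed; the whole cohort is a pure function of it.
#' @param base_config [synth_config()] giving the population-typical session.
#' @param between_sd Named list of between-participant spreads:
#'   `mean_rr_s` (additive SD, s) and `amp_rel` (log-normal relative SD on
#'   both modulation amplitudes).
#' @return Object of class `prv_cohort`: a list of participants, each with
#'   `participant_id`, `role`, `pgy_level`, and `q1`/`q4` [synth_config()]s
#'   differing exactly by `effect`.
#' @export
make_cohort <- function(n_participants, effect = list(), seed = 1L,
                        base_config = synth_config(),
                        between_sd = list(mean_rr_s = 0.05, amp_rel = 0.2)) {
  if (!is_scalar_number(n_participants) || n_participants < 2) {
    stopf("`n_participants` must be >= 2")
  }
  n <- as.integer(n_participants)
  bad <- setdiff(names(effect), c("mean_rr_s", "lf_amp", "hf_amp",
                                  "white_noise_sd"))
  if (length(bad)) stopf("unknown effect fields: %s", paste(bad, collapse = ", "))
  n_res <- n %/% 2L
  roles <- c(rep("resident", n_res), rep("attending", n - n_res))
  participants <- with_seed(derive_seed(seed, 101L), {
    lapply(seq_len(n), function(i) {
      mean_rr_i <- min(max(rnorm(1, base_config$mean_rr_s,
                                 between_sd$mean_rr_s), 0.4), 1.5)
      amp_fac <- exp(rnorm(2, 0, between_sd$amp_rel))
      lf_i <- c(base_config$lf_mod[1], base_config$lf_mod[2] * amp_fac[1])
      hf_i <- c(base_config$hf_mod[1], base_config$hf_mod[2] * amp_fac[2])
      mk <- function(quarter_shift, qseed) {
        sh <- function(nm, cur) cur + if (!is.null(quarter_shift[[nm]])) quarter_shift[[nm]] else 0
        cfg <- base_config
        cfg$mean_rr_s <- min(max(sh("mean_rr_s", mean_rr_i), 0.3), 2.5)
        cfg$lf_mod <- c(lf_i[1], max(sh("lf_amp", lf_i[2]), 0))
        cfg$hf_mod <- c(hf_i[1], max(sh("hf_amp", hf_i[2]), 0))
        cfg$white_noise_sd <- max(sh("white_noise_sd", base_config$white_noise_sd), 0)
        cfg$seed <- qseed
        cfg
      }
      list(participant_id = sprintf("P%02d", i), role = roles[i],
           pgy_level = if (roles[i] == "resident") ((i - 1L) %% 3L) + 1L else NA_integer_,
           q1 = mk(list(), derive_seed(seed, i, 1L)),
           q4 = mk(effect, derive_seed(seed, i, 2L)))
    })
  })
  structure(participants, class = "prv_cohort")
}
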