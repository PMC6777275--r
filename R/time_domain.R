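#' Median pulse rate (beats per minute)
#'
#' Median of the instantaneous rates `60 / ibi_s` over all entries. For an
#' even number of entries the median is the mean of the two middle values
#' (the [stats::median()] convention, fixed here so results are exactly
#' testable).
#'
#' @param ibi An [ibi_log()] with at least one entry.
#' @return Median pulse rate in beats/min.
#' @export
#' @examples
#' median_pulse_rate(ibi_log(c(0.8, 1.6), c(0.8, 0.8)))  # 75
median_pulse_rate <- function(ibi) {
  stopifnot(inherits(ibi, "ibi_log"))
  if (beat_count(ibi) < 1L) stopf("cannot compute MPR of an empty IBI log")
  median(60 / ibi$ibi_s)
}

#' Mean R-R interval (seconds)
#'
#' Arithmetic mean of all interval durations in the log.
#'
#' @param ibi An [ibi_log()] with at least one entry.
#' @return Mean interval in seconds.
#' @export
mean_rr <- function(ibi) {
  stopifnot(inherits(ibi, "ibi_log"))
  if (beat_count(ibi) < 1L) stopf("cannot compute MRRI of an empty IBI log")
  mean(ibi$ibi_s)
}

#' Standard deviation of R-R intervals (SDNN, seconds)
#'
#' Sample standard deviation (n-1 denominator, the convention of the
#' short-term variability standards literature) of all interval durations.
#'
#' @param ibi An [ibi_log()] with at least two entries.
#' @return SDNN in seconds.
#' @export
sdnn <- function(ibi) {
  stopifnot(inherits(ibi, "ibi_log"))
  if (beat_count(ibi) < 2L) stopf("SDNN requires at least 2 beats")
  sd(ibi$ibi_s)
}

#' Longest contiguous run of beats
#'
#' Finds the single longest stretch of consecutive heart beats in the log.
#' Two successive entries are contiguous when the later interval accounts
#' for the gap between their offsets:
#' `|offset_i - offset_{i-1} - ibi_i| <= contiguity_tol`. The default
#' tolerance of one sample period (1/64 s) absorbs the device's beat-time
#' quantisation — a discrepancy of exactly one sample still counts as
#' contiguous; two samples splits the run. Among equally long maximal runs
#' the earliest is returned.
#'
#' @param ibi An [ibi_log()] with at least two entries.
#' @param contiguity_tol Tolerance in seconds (default `1/64`).
#' @return Object of class `beat_run`: `start_index`, `end_index` (into the
#'   log entries), `offset_s`, `rr_s` (the run's interval values),
#'   `n_beats`, and `duration_s` (first interval start to last beat).
#' @export
#' @examples
#' log <- ibi_log(c(0.8, 1.6, 5.0, 5.8, 6.6, 7.4), c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8))
#' longest_contiguous_run(log)$n_beats  # the 5.0..7.4 run of 4 beats
longest_contiguous_run <- function(ibi, contiguity_tol = 1 / 64) {
  stopifnot(inherits(ibi, "ibi_log"))
  n <- beat_count(ibi)
  if (n < 2L) stopf("need at least 2 beats to isolate a run")
  check_scalar(contiguity_tol, "contiguity_tol", lower = 0)
  disc <- abs(diff(ibi$offset_s) - ibi$ibi_s[-1L])
  linked <- disc <= contiguity_tol
  run_id <- cumsum(c(1L, !linked))
  lens <- tabulate(run_id)
  best <- which.max(lens)  # which.max returns the first (earliest) maximum
  if (lens[best] < 2L) {
    stopf("no contiguous run of length >= 2 (largest run has 1 beat)")
  }
  idx <- which(run_id == best)
  structure(
    list(start_index = idx[1], end_index = idx[length(idx)],
         offset_s = ibi$offset_s[idx], rr_s = ibi$ibi_s[idx],
         n_beats = length(idx),
         duration_s = ibi$offset_s[idx[length(idx)]] -
           (ibi$offset_s[idx[1]] - ibi$ibi_s[idx[1]])),
    class = "beat_run"
  )
}

#' Root mean square of successive differences (RMSSD, seconds)
#'
#' `sqrt(mean((rr_{i+1} - rr_i)^2))` over a contiguous beat run. RMSSD is
#' the one headline statistic computed on the longest contiguous run only —
#' successive differences across detection gaps would be meaningless — while
#' MPR, MRRI and SDNN use every logged interval.
#'
#' @param run A [longest_contiguous_run()] result (or a plain numeric vector
#'   of contiguous interval durations) with at least 2 intervals.
#' @return RMSSD in seconds.
#' @export
#' @examples
#' rmssd(longest_contiguous_run(ibi_log(c(0.8, 1.7, 2.5), c(0.8, 0.9, 0.8))))
rmssd <- function(run) {
  rr <- if (inherits(run, "beat_run")) run$rr_s else as.numeric(run)
  if (length(rr) < 2L) stopf("RMSSD requires a run of at least 2 intervals")
  sqrt(mean(diff(rr)^2))
}

#' All four time-domain metrics of a session
#'
#' Convenience wrapper computing MPR, MRRI and SDNN over every entry in the
#' log and RMSSD over the longest contiguous run. If no run of at least two
#' beats exists, RMSSD is `NA` with a warning.
#'
#' @param ibi An [ibi_log()] with at least two entries.
#' @param contiguity_tol See [longest_contiguous_run()].
#' @return Object of class `time_domain_metrics`: `mpr` (beats/min), `mrri`,
#'   `sdnn`, `rmssd` (s), `n_beats_used`, `longest_run_beats`.
#' @export
time_domain_metrics <- function(ibi, contiguity_tol = 1 / 64) {
  stopifnot(inherits(ibi, "ibi_log"))
  if (beat_count(ibi) < 2L) stopf("time-domain metrics require >= 2 beats")
  run <- tryCatch(longest_contiguous_run(ibi, contiguity_tol),
                  error = function(e) NULL)
  if (is.null(run)) {
    warning("no contiguous run of >= 2 beats; RMSSD is NA", call. = FALSE)
  }
  structure(
    list(mpr = median_pulse_rate(ibi), mrri = mean_rr(ibi),
         sdnn = sdnn(ibi),
         rmssd = if (is.null(run)) NA_real_ else rmssd(run),
         n_beats_used = beat_count(ibi),
         longest_run_beats = if (is.null(run)) 1L else run$n_beats),
    class = "time_domain_metrics"
  )
}

#' @export
print.time_domain_metrics <- function(x, ...) {
  cat(sprintf(paste0("<time_domain_metrics> MPR %.1f bpm | MRRI %.3f s | ",
                     "SDNN %.3f s | RMSSD %.3f s (run of %d / %d beats)\n"),
              x$mpr, x$mrri, x$sdnn, x$rmssd, x$longest_run_beats,
              x$n_beats_used))
  invisible(x)
}
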