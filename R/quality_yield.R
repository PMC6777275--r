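#' Per-sample beat coverage of a recording
#'
#' Transforms an IBI log into a boolean time vector at the recording's
#' sampling rate: a sample at time `t = (k-1)/fs` is covered when it falls
#' inside some logged interval `[offset - ibi, offset]` (the interval
#' between consecutive beats counts as detected time). Overlap of adjacent
#' intervals at shared endpoints collapses in the boolean union, so each
#' sample is counted once.
#'
#' `mode = "bin_1s"` offers the coarser literal reading of coverage in
#' 1-second bins (anchored at t = 0, a bin is covered when any covered
#' sample falls in it), for sensitivity analysis.
#'
#' @param ibi An [ibi_log()].
#' @param total_duration_s Grand total recording time in seconds; must be at
#'   least the last beat offset.
#' @param sampling_rate_hz Grid rate (64 Hz for the emulated device).
#' @param mode `"sample"` (default, one element per waveform sample) or
#'   `"bin_1s"` (one element per 1-second bin).
#' @return Logical vector.
#' @export
#' @examples
#' cov <- coverage_vector(ibi_log(1.0, 0.5), total_duration_s = 2)
#' sum(cov)  # 33 samples: t = 0.5, ..., 1.0
coverage_vector <- function(ibi, total_duration_s, sampling_rate_hz = 64,
                            mode = c("sample", "bin_1s")) {
  stopifnot(inherits(ibi, "ibi_log"))
  mode <- match.arg(mode)
  check_scalar(total_duration_s, "total_duration_s", lower = 0)
  fs <- sampling_rate_hz
  check_scalar(fs, "sampling_rate_hz", lower = 1e-6)
  n <- round(total_duration_s * fs)
  if (beat_count(ibi) && max(ibi$offset_s) > total_duration_s + 1 / fs) {
    stopf("IBI offsets extend past the recording (%.2f s > %.2f s)",
          max(ibi$offset_s), total_duration_s)
  }
  cov <- logical(n)
  if (beat_count(ibi) && n > 0L) {
    start <- ibi$offset_s - ibi$ibi_s
    end <- ibi$offset_s
    k0 <- pmax(1L, ceiling(start * fs - 1e-9) + 1L)
    k1 <- pmin(n, floor(end * fs + 1e-9) + 1L)
    keep <- k1 >= k0
    if (any(keep)) {
      cov[sequence(k1[keep] - k0[keep] + 1L, from = k0[keep])] <- TRUE
    }
  }
  if (mode == "bin_1s") {
    nbin <- ceiling(total_duration_s)
    bin <- pmin(floor((seq_len(n) - 1L) / fs) + 1L, nbin)
    return(as.logical(tapply(cov, factor(bin, levels = seq_len(nbin)), any,
                             default = FALSE)))
  }
  cov
}

#' Interpretable-data yield quotient (percent)
#'
#' `100 * covered / total` over a coverage vector: the share of the grand
#' total recording time during which pulse beats were detected.
#'
#' @param cov Logical coverage vector from [coverage_vector()] (non-empty).
#' @return Percent in `[0, 100]`.
#' @export
yield_quotient <- function(cov) {
  if (!length(cov)) stopf("cannot compute a yield quotient of an empty vector")
  100 * sum(cov) / length(cov)
}

#' Yield report for one session
#'
#' @param ibi An [ibi_log()].
#' @param total_duration_s Grand total recording time (s).
#' @param sampling_rate_hz Coverage grid rate.
#' @param session_id Optional identifier carried into aggregated reports.
#' @return Object of class `yield_report`: `covered_s`, `total_s`,
#'   `quotient_pct` and a one-row `sessions` breakdown.
#' @export
session_yield <- function(ibi, total_duration_s, sampling_rate_hz = 64,
                          session_id = NA_character_) {
  cov <- coverage_vector(ibi, total_duration_s, sampling_rate_hz)
  covered_s <- sum(cov) / sampling_rate_hz
  total_s <- length(cov) / sampling_rate_hz
  structure(
    list(covered_s = covered_s, total_s = total_s,
         quotient_pct = yield_quotient(cov),
         sessions = data.frame(session_id = session_id,
                               covered_s = covered_s, total_s = total_s,
                               quotient_pct = yield_quotient(cov),
                               stringsAsFactors = FALSE)),
    class = "yield_report"
  )
}

#' Pool yield reports across sessions
#'
#' Pooled, not averaged: covered and total seconds are summed and the
#' quotient recomputed from the sums, so the result is the overall share of
#' all recorded time that was interpretable (a 10-of-100 s session pooled
#' with a 0-of-100 s session gives 5%, not the 5%-of-means coincidence but
#' the time-weighted quotient).
#'
#' @param reports Non-empty list of [session_yield()] reports (a single
#'   report may be passed bare).
#' @return A `yield_report` whose `sessions` field stacks the per-session
#'   breakdowns.
#' @export
aggregate_yield <- function(reports) {
  if (inherits(reports, "yield_report")) reports <- list(reports)
  if (!length(reports)) stopf("need at least one yield report")
  stopifnot(all(vapply(reports, inherits, logical(1), "yield_report")))
  covered <- sum(vapply(reports, `[[`, numeric(1), "covered_s"))
  total <- sum(vapply(reports, `[[`, numeric(1), "total_s"))
  if (total <= 0) stopf("total recording time is zero")
  structure(
    list(covered_s = covered, total_s = total,
         quotient_pct = 100 * covered / total,
         sessions = do.call(rbind, lapply(reports, `[[`, "sessions"))),
    class = "yield_report"
  )
}

#' @export
print.yield_report <- function(x, ...) {
  cat(sprintf("<yield_report> %.1f of %.1f s interpretable (%.2f%%) over %d session(s)\n",
              x$covered_s, x$total_s, x$quotient_pct, nrow(x$sessions)))
  invisible(x)
}
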