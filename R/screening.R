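#' Shift overlap check
#'
#' Compares the timing of a recording with the scheduled shift and returns
#' the length of their intersection. The inclusion rule's purpose is to
#' verify that the data reflect physiology while providing care; by default
#' any positive overlap passes, with `min_overlap_s` available for stricter
#' designs.
#'
#' @param bvp A [bvp_recording()].
#' @param shift A [shift_window()].
#' @param min_overlap_s Minimum overlap (s) required; `0` means any positive
#'   overlap.
#' @return List with `overlap_ok` (logical) and `overlap_s` (seconds).
#' @export
#' @examples
#' sh <- shift_window(0, 32400)
#' rec <- bvp_recording(numeric(64 * 3600), 64, start_time = -3600)
#' check_shift_overlap(rec, sh)  # 13:00-14:00 recording vs 14:00 shift start
check_shift_overlap <- function(bvp, shift, min_overlap_s = 0) {
  stopifnot(inherits(bvp, "bvp_recording"), inherits(shift, "shift_window"))
  check_scalar(min_overlap_s, "min_overlap_s", lower = 0)
  rec_start <- bvp$start_time
  rec_end <- bvp$start_time + bvp_duration(bvp)
  overlap_s <- max(0, min(rec_end, shift$end) - max(rec_start, shift$start))
  ok <- if (min_overlap_s > 0) overlap_s >= min_overlap_s else overlap_s > 0
  list(overlap_ok = ok, overlap_s = overlap_s)
}

#' Beat density check
#'
#' Screens an IBI log for the minimum number of registered beats required
#' for inclusion. The default threshold is 300 beats, boundary inclusive:
#' exactly 300 beats passes.
#'
#' @param ibi An [ibi_log()].
#' @param threshold Minimum beat count (default 300).
#' @return List with `density_ok` (logical) and `beat_count` (integer).
#' @export
check_beat_density <- function(ibi, threshold = 300L) {
  stopifnot(inherits(ibi, "ibi_log"))
  check_scalar(threshold, "threshold", lower = 0)
  n <- beat_count(ibi)
  list(density_ok = n >= threshold, beat_count = n)
}

#' Overlay plot data: waveform plus registered-beat markers
#'
#' Builds the data behind the visual-inspection plot used during screening:
#' the raw BVP trace against time with the beats registered in the IBI log
#' marked on the same axis. The adjudication itself is a human judgment; the
#' outcome enters screening through the `manually_excluded` metadata flag.
#'
#' @param bvp A [bvp_recording()].
#' @param ibi The [ibi_log()] from the same session.
#' @param start_tol_s Maximum tolerated difference between the two files'
#'   session start stamps before the pair is rejected as mismatched.
#' @return Object of class `ppg_overlay`: `time_s`, `amplitude` (the
#'   waveform) and `marker_times_s` (one per registered beat, all within
#'   `[0, duration]`).
#' @export
overlay_plot_data <- function(bvp, ibi, start_tol_s = 0.5) {
  stopifnot(inherits(bvp, "bvp_recording"), inherits(ibi, "ibi_log"))
  if (abs(bvp$start_time - ibi$session_start) > start_tol_s) {
    stopf("session mismatch: BVP starts at %.3f but IBI log at %.3f",
          bvp$start_time, ibi$session_start)
  }
  dur <- bvp_duration(bvp)
  if (beat_count(ibi) && max(ibi$offset_s) > dur + 1 / bvp$sampling_rate_hz) {
    stopf("IBI log extends beyond the recording (%.2f s > %.2f s)",
          max(ibi$offset_s), dur)
  }
  structure(
    list(time_s = (seq_along(bvp$samples) - 1) / bvp$sampling_rate_hz,
         amplitude = bvp$samples,
         marker_times_s = ibi$offset_s),
    class = "ppg_overlay"
  )
}

#' @export
plot.ppg_overlay <- function(x, ...) {
  graphics::plot(x$time_s, x$amplitude, type = "l", col = "steelblue",
                 xlab = "Time (s)", ylab = "BVP amplitude (nW)", ...)
  if (length(x$marker_times_s)) {
    graphics::points(x$marker_times_s, rep(min(x$amplitude), length(x$marker_times_s)),
                     pch = "|", col = "red")
  }
  invisible(x)
}

#' Screen one session against the inclusion criteria
#'
#' Applies the three inclusion rules — shift overlap, minimum beat density
#' (default 300 beats, inclusive), and the manual-exclusion flag from visual
#' inspection — and records which rules a failing session violated. A
#' session is included iff it overlaps the shift, meets the beat threshold,
#' and was not manually excluded.
#'
#' @param bvp,ibi,meta The session's [bvp_recording()], [ibi_log()] and
#'   [session_meta()].
#' @param min_beats Beat-count threshold (inclusive).
#' @param min_overlap_s See [check_shift_overlap()].
#' @return One-row data.frame (class `screening_result`): session and
#'   participant identifiers, `overlap_ok`, `overlap_s`, `beat_count`,
#'   `density_ok`, `manually_excluded`, `included`, `session_start` and a
#'   comma-joined `reasons` string naming each violated rule (empty when
#'   included).
#' @export
screen_session <- function(bvp, ibi, meta, min_beats = 300L,
                           min_overlap_s = 0) {
  stopifnot(inherits(meta, "session_meta"))
  ov <- check_shift_overlap(bvp, meta$shift, min_overlap_s)
  dens <- check_beat_density(ibi, min_beats)
  included <- ov$overlap_ok && dens$density_ok && !meta$manually_excluded
  reasons <- c(if (!ov$overlap_ok) "no_shift_overlap",
               if (!dens$density_ok) "below_min_beats",
               if (meta$manually_excluded) "manually_excluded")
  out <- data.frame(
    session_id = meta$session_id, participant_id = meta$participant_id,
    role = meta$role, quarter = meta$quarter,
    session_start = bvp$start_time,
    overlap_ok = ov$overlap_ok, overlap_s = ov$overlap_s,
    beat_count = dens$beat_count, density_ok = dens$density_ok,
    manually_excluded = meta$manually_excluded, included = included,
    reasons = paste(reasons, collapse = ","),
    stringsAsFactors = FALSE
  )
  class(out) <- c("screening_result", class(out))
  out
}

#' Select the analyzable paired cohort
#'
#' Implements the repeated-measures inclusion rule: a participant enters the
#' cohort only with at least one included session in *both* Q1 and Q4. When
#' a quarter has several included sessions the earliest-dated one is chosen
#' (a deterministic tie-break so that repeated runs always analyse the same
#' session set).
#'
#' @param screening A data.frame of [screen_session()] rows (one per
#'   candidate session). Session ids must be unique.
#' @return Object of class `cohort_selection`: `cohort` (one row per
#'   included participant with the chosen `q1_session` / `q4_session`) and
#'   `exclusions` (one row per excluded session or participant with the
#'   attributed rule).
#' @export
select_cohort <- function(screening) {
  stopifnot(is.data.frame(screening))
  need <- c("session_id", "participant_id", "quarter", "included",
            "session_start", "reasons")
  miss <- setdiff(need, names(screening))
  if (length(miss)) stopf("screening frame lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(screening$session_id)) {
    stopf("duplicate session ids: %s",
          paste(unique(screening$session_id[duplicated(screening$session_id)]),
                collapse = ", "))
  }
  excl <- data.frame(level = character(), id = character(),
                     reason = character(), stringsAsFactors = FALSE)
  bad <- screening[!screening$included, , drop = FALSE]
  if (nrow(bad)) {
    excl <- rbind(excl, data.frame(level = "session", id = bad$session_id,
                                   reason = bad$reasons,
                                   stringsAsFactors = FALSE))
  }
  ok <- screening[screening$included, , drop = FALSE]
  rows <- list()
  for (pid in unique(screening$participant_id)) {
    mine <- ok[ok$participant_id == pid, , drop = FALSE]
    pick <- function(q) {
      cand <- mine[mine$quarter == q, , drop = FALSE]
      if (!nrow(cand)) return(NA_character_)
      cand$session_id[which.min(cand$session_start)]
    }
    q1 <- pick("Q1")
    q4 <- pick("Q4")
    if (is.na(q1) || is.na(q4)) {
      reason <- paste(c(if (is.na(q1)) "no included Q1 session",
                        if (is.na(q4)) "no included Q4 session"),
                      collapse = "; ")
      excl <- rbind(excl, data.frame(level = "participant", id = pid,
                                     reason = reason, stringsAsFactors = FALSE))
    } else {
      role <- screening$role[screening$participant_id == pid][1]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, role = role, q1_session = q1, q4_session = q4,
        stringsAsFactors = FALSE)
    }
  }
  cohort <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(participant_id = character(), role = character(),
               q1_session = character(), q4_session = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(cohort = cohort, exclusions = excl),
            class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("<cohort_selection> %d participants included, %d exclusions\n",
              nrow(x$cohort), nrow(x$exclusions)))
  if (nrow(x$cohort)) print(x$cohort, row.names = FALSE)
  if (nrow(x$exclusions)) {
    cat("Exclusions:\n")
    print(x$exclusions, row.names = FALSE)
  }
  invisible(x)
}
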