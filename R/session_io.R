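#' Construct a BVP recording
#'
#' A `bvp_recording` holds a raw blood-volume-pulse (PPG) waveform sampled at
#' a fixed rate (64 Hz on the wrist device emulated here), with amplitudes in
#' nanowatts and a session start time in UTC epoch seconds.
#'
#' @param samples Numeric vector of waveform amplitudes (nanowatts), ordered
#'   in time. May be empty.
#' @param sampling_rate_hz Sampling rate in samples/second. Must be positive.
#' @param start_time Session start as UTC epoch seconds (fractional allowed).
#'
#' @return An object of class `bvp_recording` with fields `start_time`,
#'   `sampling_rate_hz` and `samples`.
#' @seealso [read_bvp()], [write_bvp()], [bvp_duration()]
#' @export
#' @examples
#' rec <- bvp_recording(sin(2 * pi * 1.2 * (0:639) / 64), 64, 0)
#' bvp_duration(rec)  # 10 s
bvp_recording <- function(samples, sampling_rate_hz = 64, start_time = 0) {
  check_scalar(sampling_rate_hz, "sampling_rate_hz")
  if (sampling_rate_hz <= 0) stopf("`sampling_rate_hz` must be > 0")
  check_scalar(start_time, "start_time")
  samples <- as.numeric(samples)
  if (length(samples) && any(!is.finite(samples))) {
    stopf("all BVP samples must be finite; first bad sample at index %d",
          which(!is.finite(samples))[1])
  }
  structure(
    list(start_time = as.numeric(start_time),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         samples = samples),
    class = "bvp_recording"
  )
}

#' Duration of a BVP recording in seconds
#'
#' @param bvp A [bvp_recording()].
#' @return Length of the recording in seconds (`n_samples / sampling_rate`).
#' @export
bvp_duration <- function(bvp) {
  stopifnot(inherits(bvp, "bvp_recording"))
  length(bvp$samples) / bvp$sampling_rate_hz
}

#' @export
print.bvp_recording <- function(x, ...) {
  cat(sprintf("<bvp_recording> %d samples @ %g Hz (%.1f s), start %.3f\n",
              length(x$samples), x$sampling_rate_hz, bvp_duration(x),
              x$start_time))
  invisible(x)
}

#' Construct an interbeat-interval (IBI) log
#'
#' An `ibi_log` is the device-style record of detected pulse beats: for each
#' registered beat, the time offset from session start at which the beat
#' occurred and the duration of the interval *ending* at that beat. The
#' wearable-device convention is followed: the offset marks the beat that
#' closes the interval, so `offset_s >= ibi_s` always (the interval cannot
#' begin before the session).
#'
#' Invariants enforced: offsets strictly increasing, all intervals positive,
#' and `offset_s >= ibi_s` entry-wise.
#'
#' @param offset_s Numeric vector of beat offsets in seconds from
#'   `session_start`, strictly increasing.
#' @param ibi_s Numeric vector (same length) of interval durations in seconds.
#' @param session_start Session start as UTC epoch seconds.
#' @return An object of class `ibi_log` with fields `session_start`,
#'   `offset_s`, `ibi_s`.
#' @seealso [read_ibi()], [write_ibi()]
#' @export
#' @examples
#' log <- ibi_log(c(0.8, 1.6, 2.4), c(0.8, 0.8, 0.8))
#' beat_count(log)
ibi_log <- function(offset_s = numeric(), ibi_s = numeric(), session_start = 0) {
  check_scalar(session_start, "session_start")
  offset_s <- as.numeric(offset_s)
  ibi_s <- as.numeric(ibi_s)
  if (length(offset_s) != length(ibi_s)) {
    stopf("`offset_s` and `ibi_s` must have equal length (%d vs %d)",
          length(offset_s), length(ibi_s))
  }
  if (length(offset_s)) {
    if (any(!is.finite(offset_s)) || any(!is.finite(ibi_s))) {
      stopf("IBI offsets and intervals must all be finite")
    }
    if (any(diff(offset_s) <= 0)) {
      i <- which(diff(offset_s) <= 0)[1]
      stopf("IBI offsets must be strictly increasing; violation at entry %d (%.6f after %.6f)",
            i + 1L, offset_s[i + 1L], offset_s[i])
    }
    if (any(ibi_s <= 0)) {
      stopf("all IBI durations must be positive; violation at entry %d",
            which(ibi_s <= 0)[1])
    }
    if (any(offset_s - ibi_s < -1e-9)) {
      stopf("interval extends before session start at entry %d (offset %.6f < ibi %.6f)",
            which(offset_s - ibi_s < -1e-9)[1],
            offset_s[which(offset_s - ibi_s < -1e-9)[1]],
            ibi_s[which(offset_s - ibi_s < -1e-9)[1]])
    }
  }
  structure(
    list(session_start = as.numeric(session_start),
         offset_s = offset_s, ibi_s = ibi_s),
    class = "ibi_log"
  )
}

#' Number of beats registered in an IBI log
#' @param ibi An [ibi_log()].
#' @return Integer count of entries.
#' @export
beat_count <- function(ibi) {
  stopifnot(inherits(ibi, "ibi_log"))
  length(ibi$offset_s)
}

#' @export
print.ibi_log <- function(x, ...) {
  cat(sprintf("<ibi_log> %d beats, start %.3f", beat_count(x), x$session_start))
  if (beat_count(x)) {
    cat(sprintf(", span [%.2f, %.2f] s, mean IBI %.3f s",
                x$offset_s[1], x$offset_s[beat_count(x)], mean(x$ibi_s)))
  }
  cat("\n")
  invisible(x)
}

#' Session metadata
#'
#' Shift-schedule metadata attached to one recording session: who wore the
#' sensor, their role, the academic-year quarter, and the scheduled shift
#' window. Q1 covers July-September and Q4 April-June of the same academic
#' year, matching the repeated-measures design the screening module selects
#' for.
#'
#' @param participant_id Opaque participant identifier.
#' @param role `"resident"` or `"attending"`.
#' @param quarter `"Q1"` or `"Q4"`.
#' @param shift Shift window from [shift_window()].
#' @param session_id Unique session identifier; defaults to
#'   `<participant>_<quarter>`.
#' @param pgy_level Optional postgraduate-year level (1-3) for residents.
#' @param manually_excluded Logical flag set by a human reviewer after visual
#'   inspection of the overlay plot; screening honours but never sets it.
#' @return An object of class `session_meta`.
#' @export
session_meta <- function(participant_id, role = c("resident", "attending"),
                         quarter = c("Q1", "Q4"), shift,
                         session_id = NULL, pgy_level = NA_integer_,
                         manually_excluded = FALSE) {
  role <- match.arg(role)
  quarter <- match.arg(quarter)
  stopifnot(inherits(shift, "shift_window"))
  if (!is.na(pgy_level)) {
    pgy_level <- as.integer(pgy_level)
    if (pgy_level < 1L || pgy_level > 3L) stopf("`pgy_level` must be 1, 2 or 3")
  }
  if (is.null(session_id)) session_id <- paste0(participant_id, "_", quarter)
  structure(
    list(participant_id = as.character(participant_id), role = role,
         pgy_level = pgy_level, quarter = quarter, shift = shift,
         session_id = as.character(session_id),
         manually_excluded = isTRUE(manually_excluded)),
    class = "session_meta"
  )
}

#' Shift window
#'
#' Scheduled shift start and end. The supported design is a 9-hour shift
#' (14:00-23:00 local time); times are stored as UTC epoch seconds, and
#' [shift_window_local()] builds one from local wall-clock strings plus a
#' configured UTC offset, which keeps tests free of timezone-database
#' lookups.
#'
#' @param start,end Shift start/end as UTC epoch seconds. `end > start`.
#' @return An object of class `shift_window` with `start`, `end`,
#'   `duration_s`.
#' @export
shift_window <- function(start, end) {
  check_scalar(start, "start")
  check_scalar(end, "end")
  if (end <= start) stopf("shift `end` must be after `start`")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 duration_s = as.numeric(end - start)),
            class = "shift_window")
}

#' @rdname shift_window
#' @param date Date string `"YYYY-MM-DD"`.
#' @param start_hm,end_hm Local wall-clock times `"HH:MM"`; defaults give the
#'   study's 9-hour 14:00-23:00 shift.
#' @param utc_offset_hours Signed offset of local time from UTC, in hours.
#' @export
shift_window_local <- function(date, start_hm = "14:00", end_hm = "23:00",
                               utc_offset_hours = 0) {
  to_epoch <- function(hm) {
    t <- as.POSIXct(paste(date, hm), tz = "UTC", format = "%Y-%m-%d %H:%M")
    if (is.na(t)) stopf("cannot parse local time '%s %s'", date, hm)
    as.numeric(t) - utc_offset_hours * 3600
  }
  shift_window(to_epoch(start_hm), to_epoch(end_hm))
}

# ---- File I/O --------------------------------------------------------------
# Vendor-style dialect (frozen):
#   BVP file : line 1 = start epoch seconds, line 2 = rate Hz, lines 3.. =
#              one amplitude per line, 6 decimals.
#   IBI file : line 1 = "<epoch seconds>, IBI", lines 2.. = "<offset>,<ibi>"
#              relative to the line-1 timestamp, 9 decimals.
#   Metadata : JSON sidecar (participant, role, pgy, quarter, shift ISO-8601).

parse_num <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stopf("%s: line %d: non-numeric %s '%s'", path, lineno[bad[1]], what,
          x[bad[1]])
  }
  v
}

#' Read / write a BVP waveform file
#'
#' The on-disk dialect is a plain-text CSV: line 1 the session start (UTC
#' epoch seconds), line 2 the sampling rate in Hz, then one amplitude per
#' line. Malformed headers and non-numeric samples raise errors naming the
#' offending line.
#'
#' @param path File path.
#' @return `read_bvp()` returns a validated [bvp_recording()]; `write_bvp()`
#'   invisibly returns `path`.
#' @export
read_bvp <- function(path) {
  if (!file.exists(path)) stopf("BVP file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) {
    stopf("%s: malformed header: need start-time and rate lines", path)
  }
  start_time <- parse_num(lines[1], path, 1L, "start timestamp")
  rate <- parse_num(lines[2], path, 2L, "sampling rate")
  if (rate <= 0) stopf("%s: line 2: sampling rate must be > 0", path)
  data <- lines[-(1:2)]
  data <- data[nzchar(trimws(data))]
  samples <- if (length(data)) {
    parse_num(data, path, seq_along(data) + 2L, "sample")
  } else numeric()
  bvp_recording(samples, rate, start_time)
}

#' @rdname read_bvp
#' @param bvp A [bvp_recording()] to serialise (samples written with 6
#'   decimal places).
#' @export
write_bvp <- function(bvp, path) {
  stopifnot(inherits(bvp, "bvp_recording"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("%.6f", bvp$start_time),
               sprintf("%.6f", bvp$sampling_rate_hz),
               sprintf("%.6f", bvp$samples)),
             con, sep = "\n")
  invisible(path)
}

#' Read / write an IBI log file
#'
#' Line 1 is `"<epoch seconds>, IBI"`; each following line is
#' `"<offset_s>,<ibi_s>"` with offsets relative to the line-1 timestamp.
#' All [ibi_log()] invariants are enforced on read, so any file accepted
#' here yields a valid log (non-monotone offsets or non-positive intervals
#' are rejected with the line number).
#'
#' @param path File path.
#' @return `read_ibi()` returns a validated [ibi_log()]; `write_ibi()`
#'   invisibly returns `path`.
#' @export
read_ibi <- function(path) {
  if (!file.exists(path)) stopf("IBI file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stopf("%s: missing header line", path)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(hdr) != 2L || trimws(hdr[2]) != "IBI") {
    stopf("%s: line 1: expected '<epoch seconds>, IBI' header", path)
  }
  session_start <- parse_num(trimws(hdr[1]), path, 1L, "session start")
  data <- lines[-1]
  keep <- nzchar(trimws(data))
  data <- data[keep]
  if (!length(data)) return(ibi_log(session_start = session_start))
  parts <- strsplit(data, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    stopf("%s: line %d: expected '<offset>,<ibi>'", path,
          which(nfield != 2L)[1] + 1L)
  }
  m <- matrix(trimws(unlist(parts)), ncol = 2L, byrow = TRUE)
  lineno <- seq_along(data) + 1L
  offs <- parse_num(m[, 1], path, lineno, "offset")
  ibis <- parse_num(m[, 2], path, lineno, "interval")
  ibi_log(offs, ibis, session_start)
}

#' @rdname read_ibi
#' @param ibi An [ibi_log()] to serialise (values written with 9 decimal
#'   places, so round trips preserve 1e-9 s).
#' @export
write_ibi <- function(ibi, path) {
  stopifnot(inherits(ibi, "ibi_log"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("%.6f, IBI", ibi$session_start),
               sprintf("%.9f,%.9f", ibi$offset_s, ibi$ibi_s)),
             con, sep = "\n")
  invisible(path)
}

#' Read / write the session metadata sidecar (JSON)
#'
#' @param path File path of the JSON sidecar.
#' @param utc_offset_hours UTC offset used to interpret the stored local
#'   shift times.
#' @return `read_session_meta()` returns a [session_meta()];
#'   `write_session_meta()` invisibly returns `path`.
#' @export
read_session_meta <- function(path, utc_offset_hours = 0) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("participant_id", "role", "quarter", "shift_start", "shift_end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("%s: missing metadata fields: %s", path,
                          paste(miss, collapse = ", "))
  parse_iso <- function(s) {
    t <- as.POSIXct(s, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    if (is.na(t)) stopf("%s: cannot parse ISO-8601 time '%s'", path, s)
    as.numeric(t) - utc_offset_hours * 3600
  }
  session_meta(
    participant_id = x$participant_id, role = x$role, quarter = x$quarter,
    shift = shift_window(parse_iso(x$shift_start), parse_iso(x$shift_end)),
    session_id = if (!is.null(x$session_id)) x$session_id else NULL,
    pgy_level = if (!is.null(x$pgy_level)) x$pgy_level else NA_integer_,
    manually_excluded = isTRUE(x$manually_excluded)
  )
}

#' @rdname read_session_meta
#' @param meta A [session_meta()].
#' @export
write_session_meta <- function(meta, path, utc_offset_hours = 0) {
  stopifnot(inherits(meta, "session_meta"))
  iso <- function(epoch) {
    format(as.POSIXct(epoch + utc_offset_hours * 3600,
                      origin = "1970-01-01", tz = "UTC"),
           "%Y-%m-%dT%H:%M:%S")
  }
  x <- list(participant_id = meta$participant_id, role = meta$role,
            quarter = meta$quarter, session_id = meta$session_id,
            shift_start = iso(meta$shift$start), shift_end = iso(meta$shift$end),
            manually_excluded = meta$manually_excluded)
  if (!is.na(meta$pgy_level)) x$pgy_level <- meta$pgy_level
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
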