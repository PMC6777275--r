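#' All seven headline metrics of one session
#'
#' @param ibi An [ibi_log()].
#' @param spectral_cfg A [spectral_config()].
#' @param contiguity_tol Run contiguity tolerance (s).
#' @return One-row data.frame: `mpr`, `mrri`, `sdnn`, `rmssd`, `lf_power`,
#'   `hf_power`, `lhr`, `n_beats`, `longest_run_beats`. Frequency metrics
#'   are `NA` (with a warning) when the longest run is too short for
#'   spectral analysis.
#' @export
compute_session_metrics <- function(ibi, spectral_cfg = spectral_config(),
                                    contiguity_tol = 1 / 64) {
  td <- time_domain_metrics(ibi, contiguity_tol)
  fd <- tryCatch(
    suppressMessages(freq_domain_metrics(ibi, spectral_cfg, contiguity_tol)),
    error = function(e) {
      warning(sprintf("frequency-domain metrics unavailable: %s",
                      conditionMessage(e)), call. = FALSE)
      list(lf_power_ms2 = NA_real_, hf_power_ms2 = NA_real_, lhr = NA_real_)
    })
  data.frame(mpr = td$mpr, mrri = td$mrri, sdnn = td$sdnn, rmssd = td$rmssd,
             lf_power = fd$lf_power_ms2, hf_power = fd$hf_power_ms2,
             lhr = fd$lhr, n_beats = td$n_beats_used,
             longest_run_beats = td$longest_run_beats,
             stringsAsFactors = FALSE)
}

#' Metric table of a simulated cohort
#'
#' Generates every participant's Q1 and Q4 session from a [make_cohort()]
#' specification and computes the seven headline metrics per session. With
#' `use_detection = FALSE` (default) the device-style IBI log implied by the
#' ground truth is analysed directly — the configuration matching how field
#' data arrive, where the wearable's onboard detector supplies the log.
#' With `use_detection = TRUE` the full waveform path is exercised: render
#' the BVP, run [detect_beats()], analyse its output.
#'
#' @param cohort A [make_cohort()] result.
#' @param use_detection Run the rendered-waveform + detector path.
#' @param spectral_cfg,detector_cfg,contiguity_tol Analysis settings.
#' @return Data.frame with one row per participant-quarter:
#'   `participant_id`, `role`, `quarter`, the metric columns of
#'   [compute_session_metrics()].
#' @export
cohort_metrics <- function(cohort, use_detection = FALSE,
                           spectral_cfg = spectral_config(),
                           detector_cfg = detector_config(),
                           contiguity_tol = 1 / 64) {
  stopifnot(inherits(cohort, "prv_cohort"))
  rows <- lapply(cohort, function(p) {
    per_q <- lapply(c("q1", "q4"), function(q) {
      cfg <- p[[q]]
      truth <- generate_rr_series(cfg)
      ibi <- if (use_detection) {
        detect_beats(render_bvp(truth, cfg), detector_cfg)
      } else {
        truth_to_ibi(truth)
      }
      m <- compute_session_metrics(ibi, spectral_cfg, contiguity_tol)
      cbind(data.frame(participant_id = p$participant_id, role = p$role,
                       quarter = toupper(q), stringsAsFactors = FALSE), m)
    })
    do.call(rbind, per_q)
  })
  do.call(rbind, rows)
}

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: simulation of a paired cohort
#' (or ingestion of an existing session directory), detection, screening,
#' metric computation, yield, and the paired comparison. The seed fixes
#' every stochastic element, so a run is a pure function of its config.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_participants,effect,duration_s,dropout_fraction,base_config
#'   Simulated-cohort settings (see [make_cohort()], [synth_config()]);
#'   ignored when `sessions_dir` is supplied.
#' @param sessions_dir Optional directory of existing sessions
#'   (`<id>_bvp.csv`, `<id>_ibi.csv`, `<id>_meta.json` triples); when given,
#'   simulation is skipped.
#' @param detector,spectral A [detector_config()] and [spectral_config()].
#' @param min_beats,min_overlap_s,contiguity_tol Screening and run
#'   thresholds.
#' @param subgroup Comparison subgroup (`"all"`, `"residents"`,
#'   `"attendings"`).
#' @param seed Integer master seed.
#' @param utc_offset_hours Local-time offset for shift metadata.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, n_participants = 6, effect = list(),
                       duration_s = 420, dropout_fraction = 0,
                       base_config = NULL, sessions_dir = NULL,
                       detector = detector_config(),
                       spectral = spectral_config(),
                       min_beats = 300L, min_overlap_s = 0,
                       contiguity_tol = 1 / 64,
                       subgroup = c("all", "residents", "attendings"),
                       seed = 1L, utc_offset_hours = 0) {
  subgroup <- match.arg(subgroup)
  stopifnot(inherits(detector, "detector_config"),
            inherits(spectral, "spectral_config"))
  if (is.null(base_config)) {
    base_config <- synth_config(duration_s = duration_s,
                                dropout_fraction = dropout_fraction,
                                seed = as.integer(seed))
  }
  structure(
    list(out_dir = out_dir, n_participants = n_participants, effect = effect,
         base_config = base_config, sessions_dir = sessions_dir,
         detector = detector, spectral = spectral, min_beats = min_beats,
         min_overlap_s = min_overlap_s, contiguity_tol = contiguity_tol,
         subgroup = subgroup, seed = as.integer(seed),
         utc_offset_hours = utc_offset_hours),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (unless ingesting) -> detect -> screen -> metrics
#' -> yield -> compare, persisting every intermediate as plain CSV/JSON so
#' each stage is independently auditable: `sessions/` (BVP, device IBI,
#' metadata), `detected/` (detector IBI logs), `screening.csv`,
#' `metrics/<session>.json`, `yield.csv` (per-session rows plus a pooled
#' `POOLED` footer row), `tables.csv` (the paired comparison) and
#' `manifest.json` (seed and configuration echo). Stage failures abort with
#' a message naming the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `out_dir`, `screening`, `selection`,
#'   `metrics` (per-session table), `yield` (pooled report) and
#'   `comparison`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  sessions_dir <- config$sessions_dir
  if (is.null(sessions_dir)) {
    sessions_dir <- file.path(out, "sessions")
    stage("simulate", simulate_session_dir(config, sessions_dir))
  }
  ids <- session_ids(sessions_dir)
  if (!length(ids)) stopf("pipeline stage 'ingest' failed: no sessions in %s",
                          sessions_dir)

  det_dir <- file.path(out, "detected")
  dir.create(det_dir, showWarnings = FALSE)
  yields <- list()
  detected <- list()
  metas <- list()
  bvp_durs <- numeric()
  screening <- stage("detect+screen", {
    rows <- lapply(ids, function(sid) {
      bvp <- read_bvp(file.path(sessions_dir, paste0(sid, "_bvp.csv")))
      meta <- read_session_meta(file.path(sessions_dir, paste0(sid, "_meta.json")),
                                config$utc_offset_hours)
      ibi <- detect_beats(bvp, config$detector)
      write_ibi(ibi, file.path(det_dir, paste0(sid, "_ibi.csv")))
      detected[[sid]] <<- ibi
      metas[[sid]] <<- meta
      bvp_durs[sid] <<- bvp_duration(bvp)
      # yield uses offsets relative to session start on the recording grid
      rel <- ibi_log(ibi$offset_s, ibi$ibi_s, 0)
      yields[[sid]] <<- session_yield(rel, bvp_duration(bvp),
                                      bvp$sampling_rate_hz, session_id = sid)
      screen_session(bvp, ibi, meta, config$min_beats, config$min_overlap_s)
    })
    do.call(rbind, rows)
  })
  write.csv(screening, file.path(out, "screening.csv"), row.names = FALSE)

  selection <- stage("select_cohort", select_cohort(screening))
  jsonlite::write_json(
    list(cohort = selection$cohort, exclusions = selection$exclusions),
    file.path(out, "cohort.json"), auto_unbox = TRUE, pretty = TRUE)

  met_dir <- file.path(out, "metrics")
  dir.create(met_dir, showWarnings = FALSE)
  metrics <- stage("metrics", {
    included <- unlist(selection$cohort[c("q1_session", "q4_session")],
                       use.names = FALSE)
    rows <- lapply(included, function(sid) {
      m <- compute_session_metrics(detected[[sid]], config$spectral,
                                   config$contiguity_tol)
      meta <- metas[[sid]]
      row <- cbind(data.frame(session_id = sid,
                              participant_id = meta$participant_id,
                              role = meta$role, quarter = meta$quarter,
                              stringsAsFactors = FALSE), m)
      jsonlite::write_json(as.list(row), file.path(met_dir, paste0(sid, ".json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      row
    })
    do.call(rbind, rows)
  })

  pooled <- stage("yield", aggregate_yield(unname(yields)))
  ytab <- pooled$sessions
  ytab <- rbind(ytab, data.frame(session_id = "POOLED",
                                 covered_s = pooled$covered_s,
                                 total_s = pooled$total_s,
                                 quotient_pct = pooled$quotient_pct,
                                 stringsAsFactors = FALSE))
  write.csv(ytab, file.path(out, "yield.csv"), row.names = FALSE)

  comparison <- stage("compare",
                      summarize_cohort(metrics, config$subgroup))
  write.csv(as.data.frame(comparison), file.path(out, "tables.csv"),
            row.names = FALSE)

  jsonlite::write_json(
    list(seed = config$seed, subgroup = config$subgroup,
         n_sessions = length(ids), n_pairs = nrow(selection$cohort),
         min_beats = config$min_beats,
         package_version = as.character(utils::packageVersion("shiftpulse")),
         detector = unclass(config$detector),
         spectral = unclass(config$spectral),
         base_config = unclass(config$base_config)),
    file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = out, screening = screening, selection = selection,
                 metrics = metrics, yield = pooled, comparison = comparison))
}

# Write a simulated cohort as session file triples.
simulate_session_dir <- function(config, sessions_dir) {
  dir.create(sessions_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- make_cohort(config$n_participants, config$effect, config$seed,
                        config$base_config)
  dates <- c(q1 = "2016-07-15", q4 = "2017-05-15")
  for (p in cohort) {
    for (q in c("q1", "q4")) {
      cfg <- p[[q]]
      shift <- shift_window_local(dates[[q]],
                                  utc_offset_hours = config$utc_offset_hours)
      truth <- generate_rr_series(cfg)
      bvp <- render_bvp(truth, cfg, start_time = shift$start)
      ibi <- truth_to_ibi(truth, session_start = shift$start)
      meta <- session_meta(p$participant_id, p$role, toupper(q), shift,
                          session_id = paste0(p$participant_id, "_", toupper(q)),
                          pgy_level = p$pgy_level)
      base <- file.path(sessions_dir, meta$session_id)
      write_bvp(bvp, paste0(base, "_bvp.csv"))
      write_ibi(ibi, paste0(base, "_ibi.csv"))
      write_session_meta(meta, paste0(base, "_meta.json"),
                         config$utc_offset_hours)
    }
  }
  invisible(sessions_dir)
}

session_ids <- function(sessions_dir) {
  f <- list.files(sessions_dir, pattern = "_bvp\\.csv$")
  sort(sub("_bvp\\.csv$", "", f))
}
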