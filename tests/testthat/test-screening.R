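make_session <- function(participant, quarter, n_beats = 350,
                         start_offset_s = 0, manually_excluded = FALSE,
                         session_id = NULL, shift_date = NULL) {
  if (is.null(shift_date)) shift_date <- if (quarter == "Q1") "2016-07-15" else "2017-05-15"
  sh <- shift_window_local(shift_date)
  dur <- max(n_beats, 1) * 0.8 + 10
  bvp <- bvp_recording(numeric(round(dur * 64)), 64,
                       start_time = sh$start + start_offset_s)
  ibi <- if (n_beats > 0) constant_log(n_beats) else ibi_log()
  meta <- session_meta(participant, "resident", quarter, sh,
                       session_id = session_id,
                       manually_excluded = manually_excluded)
  list(bvp = bvp, ibi = ibi, meta = meta)
}

test_that("shift overlap is exact interval arithmetic", {
  sh <- shift_window_local("2016-07-15")  # 14:00-23:00
  full <- bvp_recording(numeric(64 * 32400), 64, start_time = sh$start)
  ov <- check_shift_overlap(full, sh)
  expect_true(ov$overlap_ok)
  expect_equal(ov$overlap_s, 32400)

  night <- bvp_recording(numeric(64 * 3600), 64,
                         start_time = sh$start - 13 * 3600)  # 01:00-02:00
  ov2 <- check_shift_overlap(night, sh)
  expect_false(ov2$overlap_ok)
  expect_equal(ov2$overlap_s, 0)

  early <- bvp_recording(numeric(64 * 7200), 64,
                         start_time = sh$start - 3600)  # 13:00-15:00
  ov3 <- check_shift_overlap(early, sh)
  expect_true(ov3$overlap_ok)
  expect_equal(ov3$overlap_s, 3600)

  expect_false(check_shift_overlap(early, sh, min_overlap_s = 7200)$overlap_ok)
})

test_that("the 300-beat density threshold is boundary inclusive", {
  expect_true(check_beat_density(constant_log(300))$density_ok)
  expect_false(check_beat_density(constant_log(299))$density_ok)
  r0 <- check_beat_density(ibi_log())
  expect_false(r0$density_ok)
  expect_equal(r0$beat_count, 0L)
})

test_that("overlay plot data pairs waveform with beat markers", {
  bvp <- bvp_recording(rnorm(64 * 10), 64, 100)
  ibi <- ibi_log(c(0.8, 1.6, 2.4), rep(0.8, 3), session_start = 100)
  ov <- overlay_plot_data(bvp, ibi)
  expect_length(ov$marker_times_s, 3)
  expect_equal(ov$marker_times_s, c(0.8, 1.6, 2.4))
  expect_true(all(ov$marker_times_s >= 0 & ov$marker_times_s <= 10))

  empty <- overlay_plot_data(bvp, ibi_log(session_start = 100))
  expect_length(empty$marker_times_s, 0)

  expect_error(overlay_plot_data(bvp, ibi_log(0.8, 0.8, session_start = 500)),
               "session mismatch")
})

test_that("overlay markers of a synthetic session coincide with rendered peaks", {
  # low-noise rendering: this checks marker/peak geometry, not detector
  # robustness to noise (that is test-detection's job)
  cfg <- synth_config(duration_s = 30, dropout_fraction = 0,
                      baseline_noise_sd = 0.005, seed = 21)
  truth <- generate_rr_series(cfg)
  bvp <- render_bvp(truth, cfg)
  ibi <- truth_to_ibi(truth)
  ov <- overlay_plot_data(bvp, ibi)
  fs <- 64
  for (m in ov$marker_times_s) {
    # local argmax of the waveform within half a beat of the marker
    win <- which(abs(ov$time_s - m) <= 0.2)
    peak_t <- ov$time_s[win][which.max(ov$amplitude[win])]
    expect_lt(abs(peak_t - m), 1 / fs + 1e-9)
  }
})

test_that("paired cohort selection keeps only participants with both quarters", {
  ses <- list(
    make_session("A", "Q1"), make_session("A", "Q4"),
    make_session("B", "Q1"),                       # missing Q4
    make_session("C", "Q1", session_id = "C_Q1a"),
    make_session("C", "Q1", start_offset_s = -60, session_id = "C_Q1b"),
    make_session("C", "Q4")
  )
  scr <- do.call(rbind, lapply(ses, function(s)
    screen_session(s$bvp, s$ibi, s$meta)))
  sel <- select_cohort(scr)
  expect_setequal(sel$cohort$participant_id, c("A", "C"))
  expect_equal(sel$exclusions$reason[sel$exclusions$id == "B"],
               "no included Q4 session")
  # earliest-dated Q1 recording wins the tie
  expect_equal(sel$cohort$q1_session[sel$cohort$participant_id == "C"],
               "C_Q1b")
})

test_that("duplicate session ids are rejected", {
  s <- make_session("A", "Q1")
  scr <- rbind(screen_session(s$bvp, s$ibi, s$meta),
               screen_session(s$bvp, s$ibi, s$meta))
  expect_error(select_cohort(scr), "duplicate session ids")
})

test_that("cohort size is monotone non-increasing as the beat threshold tightens", {
  ses <- list(
    make_session("A", "Q1", n_beats = 500), make_session("A", "Q4", n_beats = 500),
    make_session("B", "Q1", n_beats = 350), make_session("B", "Q4", n_beats = 350),
    make_session("C", "Q1", n_beats = 305), make_session("C", "Q4", n_beats = 600)
  )
  sizes <- sapply(c(300, 320, 400, 550), function(th) {
    scr <- do.call(rbind, lapply(ses, function(s)
      screen_session(s$bvp, s$ibi, s$meta, min_beats = th)))
    nrow(select_cohort(scr)$cohort)
  })
  expect_equal(sizes, c(3, 2, 1, 0))
  expect_true(all(diff(sizes) <= 0))
})
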