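test_that("unmodulated IPFM process fires beats at exact multiples of mean RR", {
  cfg <- synth_config(duration_s = 8, mean_rr_s = 0.8, lf_mod = c(0.1, 0),
                      hf_mod = c(0.25, 0), white_noise_sd = 0,
                      dropout_fraction = 0, seed = 1)
  truth <- generate_rr_series(cfg)
  expect_equal(truth$beat_times, seq(0.8, 8.0, by = 0.8), tolerance = 1e-9)
  expect_equal(truth$rr_s, rep(0.8, 10), tolerance = 1e-9)
})

test_that("generator is deterministic under a fixed seed and varies across seeds", {
  cfg <- synth_config(duration_s = 120, seed = 33)
  a <- generate_rr_series(cfg)
  b <- generate_rr_series(cfg)
  expect_identical(a$beat_times, b$beat_times)
  expect_identical(a$dropout_blocks, b$dropout_blocks)
  cfg2 <- synth_config(duration_s = 120, seed = 34)
  expect_false(isTRUE(all.equal(a$beat_times,
                                generate_rr_series(cfg2)$beat_times)))
})

test_that("single-band modulation concentrates tachogram power in that band", {
  # oracle: plain DFT of a linearly interpolated RR tachogram, no package
  # spectral code involved
  band_frac <- function(truth, band) {
    t4 <- seq(truth$beat_times[1], max(truth$beat_times), by = 0.25)
    rr <- approx(truth$beat_times, truth$rr_s, xout = t4)$y
    rr <- rr - mean(rr)
    p <- Mod(fft(rr))^2
    f <- (seq_along(p) - 1) / length(p) * 4
    half <- f <= 2
    lfhf <- f >= 0.05 & f < 0.40 & half
    inband <- f >= band[1] & f < band[2] & half
    sum(p[inband]) / sum(p[lfhf])
  }
  hf_only <- generate_rr_series(synth_config(
    duration_s = 600, lf_mod = c(0.1, 0), hf_mod = c(0.25, 0.04),
    white_noise_sd = 0, dropout_fraction = 0, seed = 5))
  expect_gt(band_frac(hf_only, c(0.15, 0.40)), 0.90)
  lf_only <- generate_rr_series(synth_config(
    duration_s = 600, lf_mod = c(0.1, 0.04), hf_mod = c(0.25, 0),
    white_noise_sd = 0, dropout_fraction = 0, seed = 5))
  expect_gt(band_frac(lf_only, c(0.05, 0.15)), 0.90)
})

test_that("downstream estimates recover generator ground truth on clean sessions", {
  cfg <- synth_config(duration_s = 3600, dropout_fraction = 0, seed = 17)
  truth <- generate_rr_series(cfg)
  ibi <- truth_to_ibi(truth)
  expect_lt(abs(mean_rr(ibi) - cfg$mean_rr_s) / cfg$mean_rr_s, 0.01)
  # SDNN oracle: long-run empirical SD of an independent realisation
  long <- generate_rr_series(synth_config(duration_s = 7200,
                                          dropout_fraction = 0, seed = 99))
  expect_lt(abs(sdnn(ibi) - sd(long$rr_s)) / sd(long$rr_s), 0.10)
})

test_that("dropout blocks cover the configured fraction of the session", {
  cfg <- synth_config(duration_s = 1800, dropout_fraction = 0.4,
                      dropout_block_s = 60, seed = 8)
  truth <- generate_rr_series(cfg)
  expect_equal(truth$coverage_fraction, 0.6,
               tolerance = cfg$mean_rr_s / 1800)
  mask <- coverage_mask(truth)
  expect_equal(mean(mask), truth$coverage_fraction, tolerance = 1e-6)
})

test_that("rendering produces the right sample count and honours dropout", {
  cfg0 <- synth_config(duration_s = 10, dropout_fraction = 0, seed = 2)
  truth0 <- generate_rr_series(cfg0)
  bvp <- render_bvp(truth0)
  expect_length(bvp$samples, 640)
  expect_true(all(coverage_mask(truth0)))
  cfg9 <- synth_config(duration_s = 300, dropout_fraction = 0.5,
                       dropout_block_s = 30, seed = 2)
  truth9 <- generate_rr_series(cfg9)
  expect_equal(mean(coverage_mask(truth9)), 0.5, tolerance = 0.01)
})

test_that("beats_from_rr places interval knots exactly on the prescribed curve", {
  f <- function(t) 0.8 + 0.01 * sin(2 * pi * 0.25 * t)
  trk <- beats_from_rr(f, 120)
  expect_true(all(diff(trk$beat_times) > 0))
  expect_lt(max(abs(trk$rr_s - f(trk$beat_times))), 1e-9)
})

test_that("cohort simulator applies the stated Q4 - Q1 parameter shift", {
  co0 <- make_cohort(6, effect = list(), seed = 4,
                     base_config = synth_config(duration_s = 60))
  for (p in co0) {
    expect_equal(p$q1$mean_rr_s, p$q4$mean_rr_s)
    expect_equal(p$q1$hf_mod, p$q4$hf_mod)
    expect_false(p$q1$seed == p$q4$seed)
  }
  co <- make_cohort(6, effect = list(mean_rr_s = 0.05), seed = 4,
                    base_config = synth_config(duration_s = 60))
  for (p in co) expect_equal(p$q4$mean_rr_s - p$q1$mean_rr_s, 0.05)
  expect_identical(make_cohort(6, seed = 4), make_cohort(6, seed = 4))
  expect_error(make_cohort(1), ">= 2")
  expect_error(make_cohort(4, effect = list(bogus = 1)), "unknown effect")
})

test_that("injected MRRI shift propagates to the measured cohort difference", {
  co <- make_cohort(20, effect = list(mean_rr_s = 0.05), seed = 10,
                    base_config = synth_config(duration_s = 300,
                                               dropout_fraction = 0))
  m <- cohort_metrics(co)
  d <- m$mrri[m$quarter == "Q4"] - m$mrri[m$quarter == "Q1"]
  expect_equal(mean(d), 0.05, tolerance = 0.01)
})

test_that("invalid generator configs are rejected", {
  expect_error(synth_config(mean_rr_s = 0.1), "mean_rr_s")
  expect_error(synth_config(lf_mod = c(0.2, 0.05)), "lf_mod")
  expect_error(synth_config(hf_mod = c(0.1, 0.05)), "hf_mod")
  expect_error(synth_config(dropout_fraction = 1), "< 1")
})
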