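test_that("median pulse rate follows the stated conventions", {
  expect_equal(median_pulse_rate(constant_log(5, 0.8)), 75.0)
  expect_equal(median_pulse_rate(ibi_log(c(0.5, 1.5, 3.0), c(0.5, 1.0, 1.5))),
               60.0)
  # even count: mean of the two middle instantaneous rates
  expect_equal(median_pulse_rate(ibi_log(c(0.5, 1.5), c(0.5, 1.0))), 90.0)
  expect_error(median_pulse_rate(ibi_log()), "empty")
})

test_that("mean RR and SDNN match closed forms and brute-force oracles", {
  expect_equal(mean_rr(constant_log(4, 0.8)), 0.8)
  expect_equal(mean_rr(ibi_log(c(0.7, 1.6), c(0.7, 0.9))), 0.8)
  expect_equal(sdnn(constant_log(10, 0.8)), 0)
  expect_equal(sdnn(ibi_log(c(0.7, 1.6), c(0.7, 0.9))), sqrt(2 * 0.01),
               tolerance = 1e-12)
  expect_error(sdnn(ibi_log(0.8, 0.8)), "at least 2")

  set.seed(42)
  for (i in 1:20) {
    fx <- random_ibi_fixture()
    log <- ibi_log(fx$offset_s, fx$ibi_s)
    expect_equal(mean_rr(log), oracle_mean(fx$ibi_s), tolerance = 1e-12)
    expect_equal(sdnn(log), oracle_sd(fx$ibi_s), tolerance = 1e-12)
    expect_equal(median_pulse_rate(log), oracle_mpr(fx$ibi_s),
                 tolerance = 1e-12)
  }
})

test_that("longest contiguous run isolates the correct stretch", {
  # perfectly contiguous log: the run is the whole log
  run <- longest_contiguous_run(constant_log(100))
  expect_equal(run$n_beats, 100L)
  expect_equal(run$start_index, 1L)

  # a 5-second gap after beat 40 of 100: run = beats 41..100
  offs <- cumsum(rep(0.8, 100))
  offs[41:100] <- offs[41:100] + 5
  log <- ibi_log(offs, rep(0.8, 100))
  run2 <- longest_contiguous_run(log)
  expect_equal(run2$start_index, 41L)
  expect_equal(run2$end_index, 100L)
  expect_equal(run2$n_beats, 60L)

  # two equal-length runs: the earlier one is returned
  offs3 <- cumsum(rep(0.8, 10))
  offs3[6:10] <- offs3[6:10] + 5
  run3 <- longest_contiguous_run(ibi_log(offs3, rep(0.8, 10)))
  expect_equal(run3$start_index, 1L)
  expect_equal(run3$n_beats, 5L)

  expect_error(longest_contiguous_run(ibi_log(0.8, 0.8)), "at least 2")
})

test_that("runs agree with the brute-force scan on random gapped logs", {
  set.seed(77)
  for (i in 1:25) {
    fx <- random_ibi_fixture()
    log <- ibi_log(fx$offset_s, fx$ibi_s)
    oracle <- oracle_longest_run(fx$offset_s, fx$ibi_s, 1 / 64)
    if (length(oracle) < 2) {
      expect_error(longest_contiguous_run(log), "no contiguous run")
    } else {
      run <- longest_contiguous_run(log)
      expect_equal(run$start_index, oracle[1])
      expect_equal(run$end_index, oracle[length(oracle)])
    }
  }
})

test_that("RMSSD matches closed forms and the brute-force oracle", {
  expect_equal(rmssd(longest_contiguous_run(constant_log(10))), 0)
  # alternating 0.8/0.9: all successive differences are +-0.1
  rr <- rep(c(0.8, 0.9), 5)
  run <- longest_contiguous_run(ibi_log(cumsum(rr), rr))
  expect_equal(rmssd(run), 0.1, tolerance = 1e-12)
  set.seed(5)
  rr2 <- runif(50, 0.6, 1.1)
  run2 <- longest_contiguous_run(ibi_log(cumsum(rr2), rr2))
  expect_equal(rmssd(run2), oracle_rmssd(rr2), tolerance = 1e-12)
  expect_error(rmssd(longest_contiguous_run(constant_log(2))), NA)
  expect_error(rmssd(0.8), "at least 2")
})

test_that("metrics obey scale equivariance and permutation properties", {
  set.seed(9)
  rr <- runif(40, 0.5, 1.2)
  log <- ibi_log(cumsum(rr), rr)
  c_ <- 1.7
  log_c <- ibi_log(cumsum(rr) * c_, rr * c_)
  expect_equal(mean_rr(log_c), c_ * mean_rr(log), tolerance = 1e-12)
  expect_equal(sdnn(log_c), c_ * sdnn(log), tolerance = 1e-12)
  expect_equal(rmssd(longest_contiguous_run(log_c)),
               c_ * rmssd(longest_contiguous_run(log)), tolerance = 1e-12)
  expect_equal(median_pulse_rate(log_c), median_pulse_rate(log) / c_,
               tolerance = 1e-12)

  # permutation invariance of MPR/MRRI/SDNN ...
  perm <- sample(rr)
  log_p <- ibi_log(cumsum(perm), perm)
  expect_equal(mean_rr(log_p), mean_rr(log), tolerance = 1e-12)
  expect_equal(sdnn(log_p), sdnn(log), tolerance = 1e-12)
  expect_equal(median_pulse_rate(log_p), median_pulse_rate(log),
               tolerance = 1e-12)
  # ... but not of RMSSD: a sorted run has strictly smaller RMSSD than an
  # alternating extreme arrangement of the same values
  sorted_rr <- sort(rr)
  alt_rr <- as.vector(rbind(sort(rr)[1:20], sort(rr)[40:21]))
  r_sorted <- rmssd(longest_contiguous_run(ibi_log(cumsum(sorted_rr), sorted_rr)))
  r_alt <- rmssd(longest_contiguous_run(ibi_log(cumsum(alt_rr), alt_rr)))
  expect_lt(r_sorted, r_alt)

  # RMSSD bounded by the extreme successive differences
  run <- longest_contiguous_run(log)
  d <- abs(diff(run$rr_s))
  expect_gte(rmssd(run), min(d) - 1e-12)
  expect_lte(rmssd(run), max(d) + 1e-12)
})

test_that("time_domain_metrics recovers generator truth on a clean session", {
  cfg <- synth_config(duration_s = 3600, dropout_fraction = 0, seed = 31)
  truth <- generate_rr_series(cfg)
  m <- time_domain_metrics(truth_to_ibi(truth))
  expect_lt(abs(m$mrri - cfg$mean_rr_s) / cfg$mean_rr_s, 0.01)
  expect_equal(m$n_beats_used, length(truth$beat_times))
  expect_equal(m$longest_run_beats, m$n_beats_used)  # no dropout, one run
  expect_lt(abs(m$sdnn - sd(truth$rr_s)) / sd(truth$rr_s), 1e-9)
})
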