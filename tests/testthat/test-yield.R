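test_that("coverage vector marks exactly the beat-to-beat intervals", {
  # empty log -> all false
  expect_false(any(coverage_vector(ibi_log(), 2)))
  expect_length(coverage_vector(ibi_log(), 2), 128)

  # single entry (offset 1.0, ibi 0.5) at 64 Hz over 2 s: samples at
  # t = 0.5 .. 1.0 inclusive -> 33 samples
  cov <- coverage_vector(ibi_log(1.0, 0.5), 2)
  expect_equal(sum(cov), 33)
  t <- (seq_along(cov) - 1) / 64
  expect_true(all(t[cov] >= 0.5 - 1e-9 & t[cov] <= 1.0 + 1e-9))

  # contiguous log covering the whole recording -> all true
  cov_full <- coverage_vector(constant_log(10, 0.8), 8)
  expect_true(all(cov_full))

  expect_error(coverage_vector(ibi_log(5, 0.5), 2), "extend past")
})

test_that("yield quotient is plain percent arithmetic", {
  cov <- c(rep(TRUE, 2160), rep(FALSE, 25200 - 2160))
  expect_equal(yield_quotient(cov), 100 * 2160 / 25200, tolerance = 1e-12)
  expect_equal(yield_quotient(rep(TRUE, 10)), 100)
  expect_error(yield_quotient(logical(0)), "empty")
})

test_that("aggregation pools covered and total time, never averages quotients", {
  # equal totals: pooled quotient is the mean of the two
  r1 <- session_yield(ibi_log(10.0, 10.0), 100, sampling_rate_hz = 1,
                      session_id = "a")  # ~10 of 100 s
  r2 <- session_yield(ibi_log(), 100, sampling_rate_hz = 1, session_id = "b")
  pooled <- aggregate_yield(list(r1, r2))
  expect_equal(pooled$quotient_pct,
               100 * (r1$covered_s + r2$covered_s) / 200, tolerance = 1e-12)
  # unequal totals: pooling is time-weighted, not the mean of quotients
  r3 <- session_yield(ibi_log(), 300, sampling_rate_hz = 1, session_id = "c")
  pooled2 <- aggregate_yield(list(r1, r3))
  expect_equal(pooled2$quotient_pct, 100 * r1$covered_s / 400,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pooled2$quotient_pct,
                                mean(c(r1$quotient_pct, r3$quotient_pct)))))
  # single report is the identity
  single <- aggregate_yield(list(r1))
  expect_equal(single$quotient_pct, r1$quotient_pct)
  expect_equal(nrow(pooled$sessions), 2)
})

test_that("pooled quotient lies between the per-session extremes and is order invariant", {
  set.seed(30)
  reports <- lapply(1:6, function(i) {
    fx <- random_ibi_fixture(30)
    session_yield(ibi_log(fx$offset_s, fx$ibi_s),
                  max(fx$offset_s) + runif(1, 1, 20))
  })
  pooled <- aggregate_yield(reports)
  qs <- sapply(reports, `[[`, "quotient_pct")
  expect_gte(pooled$quotient_pct, min(qs) - 1e-9)
  expect_lte(pooled$quotient_pct, max(qs) + 1e-9)
  shuffled <- aggregate_yield(reports[sample(6)])
  expect_equal(pooled$quotient_pct, shuffled$quotient_pct, tolerance = 1e-12)
  expect_equal(pooled$covered_s, sum(sapply(reports, `[[`, "covered_s")))
})

test_that("sample-count coverage approximates analytic covered length", {
  set.seed(66)
  for (i in 1:10) {
    fx <- random_ibi_fixture(25)
    log <- ibi_log(fx$offset_s, fx$ibi_s)
    total <- max(fx$offset_s) + 2
    cov <- coverage_vector(log, total)
    # analytic union length of [offset - ibi, offset]: entries never overlap
    # except at shared endpoints because offsets increase and intervals gap
    starts <- pmax(fx$offset_s - fx$ibi_s, 0)
    ends <- fx$offset_s
    merged <- 0
    cur_s <- starts[1]; cur_e <- ends[1]
    for (k in seq_along(starts)[-1]) {
      if (starts[k] <= cur_e) cur_e <- max(cur_e, ends[k])
      else { merged <- merged + cur_e - cur_s; cur_s <- starts[k]; cur_e <- ends[k] }
    }
    merged <- merged + cur_e - cur_s
    expect_lt(abs(sum(cov) / 64 - merged), 2 * length(starts) / 64)
  }
})

test_that("1-second binned mode marks any bin containing covered samples", {
  log <- ibi_log(1.0, 0.5)  # covers [0.5, 1.0]
  bins <- coverage_vector(log, 4, mode = "bin_1s")
  expect_length(bins, 4)
  expect_equal(bins, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("synthetic dropout maps onto the yield quotient", {
  # yield ~ 100 * (1 - d) with a slack of a few beat lengths
  cfg <- synth_config(duration_s = 600, dropout_fraction = 0.5,
                      dropout_block_s = 300, seed = 12)
  truth <- generate_rr_series(cfg)
  ibi <- truth_to_ibi(truth)
  q <- session_yield(ibi, 600)$quotient_pct
  expect_lt(abs(q - 50), 100 * 4 * cfg$mean_rr_s / 600)
})
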