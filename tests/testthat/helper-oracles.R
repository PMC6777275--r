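# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive every quantity from first principles (sorting,
# explicit loops, O(n^2) scans) so they share no code path with the package.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

oracle_mpr <- function(ibi_s) oracle_median(60 / ibi_s)

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_rmssd <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  sqrt(sum(d^2) / length(d))
}

# All maximal contiguous runs by explicit forward scan; returns a list of
# index vectors.
oracle_runs <- function(offset_s, ibi_s, tol) {
  n <- length(offset_s)
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n &&
           abs(offset_s[j + 1L] - offset_s[j] - ibi_s[j + 1L]) <= tol) {
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

# Longest run (earliest among ties) via the oracle scan.
oracle_longest_run <- function(offset_s, ibi_s, tol) {
  runs <- oracle_runs(offset_s, ibi_s, tol)
  lens <- vapply(runs, length, integer(1))
  runs[[which.max(lens)]]
}

# Random IBI log with occasional detection gaps.
random_ibi_fixture <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:60, 1)
  rr <- runif(n, 0.4, 1.5)
  offs <- cumsum(rr)
  # insert gaps after ~15% of beats by shifting all later offsets
  gap_after <- which(runif(n - 1) < 0.15)
  for (g in rev(gap_after)) {
    offs[(g + 1):n] <- offs[(g + 1):n] + runif(1, 0.5, 8)
  }
  list(offset_s = offs, ibi_s = rr)
}

# Greedy one-to-one matching of detected to true beat times at a tolerance;
# returns sensitivity and precision.
match_beats <- function(detected, truth, tol) {
  used <- logical(length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) {
      used[j[which.min(abs(truth[j] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(sensitivity = tp / length(truth), precision = tp / length(detected))
}

# Evenly spaced log: n beats at constant rr (offsets from rr).
constant_log <- function(n, rr = 0.8) {
  ibi_log(seq_len(n) * rr, rep(rr, n))
}
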