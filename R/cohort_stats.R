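#' Paired Student t test
#'
#' Two-sided paired t test on differences oriented Q4 - Q1:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Identical vectors give `t = 0, p = 1`; zero-variance differences with a
#' nonzero mean are a degenerate case reported as infinite `t` with
#' `p = 0` and a warning.
#'
#' @param q1_values,q4_values Equal-length numeric vectors (n >= 2), paired
#'   by participant.
#' @return List with `t`, `df`, `p`, `mean_diff`, `sd_diff`, `n`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(1.5, 2.1, 3.4))
paired_t <- function(q1_values, q4_values) {
  q1 <- as.numeric(q1_values)
  q4 <- as.numeric(q4_values)
  if (length(q1) != length(q4)) {
    stopf("paired vectors differ in length (%d vs %d)", length(q1), length(q4))
  }
  n <- length(q1)
  if (n < 2L) stopf("paired t test requires n >= 2 pairs")
  if (any(!is.finite(q1)) || any(!is.finite(q4))) {
    stopf("paired t test requires finite values")
  }
  d <- q4 - q1
  m <- mean(d)
  s <- sd(d)
  df <- n - 1L
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, df = df, p = 1, mean_diff = 0, sd_diff = 0, n = n))
    }
    warning("zero variance of differences with nonzero mean; t is infinite",
            call. = FALSE)
    return(list(t = sign(m) * Inf, df = df, p = 0, mean_diff = m, sd_diff = 0,
                n = n))
  }
  t_stat <- m / (s / sqrt(n))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df),
       mean_diff = m, sd_diff = s, n = n)
}

#' Post-hoc power of a paired t test
#'
#' Power at the observed standardized paired effect, from the noncentral t
#' distribution: with `ncp = (mean(d)/sd(d)) * sqrt(n)` and the two-sided
#' critical value `t_crit` at `alpha`,
#' `power = P(T < -t_crit) + P(T > t_crit)` for
#' `T ~ t(df = n - 1, ncp)`. A zero observed effect returns exactly
#' `alpha`; power increases monotonically in `|ncp|` and in `n` at fixed
#' effect size.
#'
#' @param q1_values,q4_values Paired metric values as in [paired_t()].
#' @param alpha Two-sided significance level.
#' @return Power estimate in `[0, 1]`.
#' @export
posthoc_power <- function(q1_values, q4_values, alpha = 0.05) {
  q1 <- as.numeric(q1_values)
  q4 <- as.numeric(q4_values)
  if (length(q1) != length(q4)) {
    stopf("paired vectors differ in length (%d vs %d)", length(q1), length(q4))
  }
  n <- length(q1)
  if (n < 2L) stopf("power calculation requires n >= 2 pairs")
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  d <- q4 - q1
  if (sd(d) == 0) stopf("zero variance of differences; effect size undefined")
  power_paired_t(n, mean(d) / sd(d), alpha)
}

# Noncentral-t power of a two-sided paired t test at standardized effect
# size `dz` (Cohen's d_z) and n pairs.
power_paired_t <- function(n, dz, alpha = 0.05) {
  df <- n - 1
  ncp <- dz * sqrt(n)
  t_crit <- qt(1 - alpha / 2, df)
  pt(-t_crit, df, ncp = ncp) + pt(t_crit, df, ncp = ncp, lower.tail = FALSE)
}

# Canonical metric order and the mapping onto per-session metric columns.
prv_metric_columns <- c(MPR = "mpr", MRRI = "mrri", SDNN = "sdnn",
                        RMSSD = "rmssd", LF = "lf_power", HF = "hf_power",
                        LHR = "lhr")

#' Paired Q1-vs-Q4 cohort comparison
#'
#' Builds the headline comparison table: one row per metric (MPR, MRRI,
#' SDNN, RMSSD, LF, HF, LHR) with quarter means and sample SDs, the paired
#' t statistic oriented Q4 - Q1, its two-sided p value, and post-hoc power
#' at the observed effect. The seven tests are deliberately left
#' uncorrected for multiple comparisons, by design; the
#' print method states this.
#'
#' @param metrics Data.frame of per-session metric values with columns
#'   `participant_id`, `role`, `quarter` (`"Q1"`/`"Q4"`), `mpr`, `mrri`,
#'   `sdnn`, `rmssd`, `lf_power`, `hf_power`, `lhr`. One row per
#'   participant-quarter; participants missing either quarter (or with any
#'   non-finite metric value) are dropped pairwise.
#' @param subgroup `"all"`, `"residents"` or `"attendings"`.
#' @param alpha Significance level used for the power column.
#' @return Data.frame of class `prv_comparison` with columns `metric`,
#'   `q1_mean`, `q1_sd`, `q4_mean`, `q4_sd`, `t_stat`, `df`, `p_value`,
#'   `power`, `n_pairs`.
#' @export
summarize_cohort <- function(metrics,
                             subgroup = c("all", "residents", "attendings"),
                             alpha = 0.05) {
  subgroup <- match.arg(subgroup)
  stopifnot(is.data.frame(metrics))
  need <- c("participant_id", "role", "quarter", unname(prv_metric_columns))
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stopf("metrics frame lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (subgroup != "all") {
    want <- sub("s$", "", subgroup)  # residents -> resident
    metrics <- metrics[metrics$role == want, , drop = FALSE]
  }
  q1 <- metrics[metrics$quarter == "Q1", , drop = FALSE]
  q4 <- metrics[metrics$quarter == "Q4", , drop = FALSE]
  common <- intersect(q1$participant_id, q4$participant_id)
  if (length(common) < 2L) {
    stopf("subgroup '%s' has %d complete pairs; need >= 2", subgroup,
          length(common))
  }
  q1 <- q1[match(common, q1$participant_id), , drop = FALSE]
  q4 <- q4[match(common, q4$participant_id), , drop = FALSE]
  rows <- lapply(names(prv_metric_columns), function(lab) {
    col <- prv_metric_columns[[lab]]
    v1 <- q1[[col]]
    v4 <- q4[[col]]
    ok <- is.finite(v1) & is.finite(v4)
    v1 <- v1[ok]
    v4 <- v4[ok]
    if (length(v1) < 2L) {
      stopf("metric %s has %d complete pairs; need >= 2", lab, length(v1))
    }
    tt <- paired_t(v1, v4)
    pw <- if (tt$sd_diff > 0) posthoc_power(v1, v4, alpha) else NA_real_
    data.frame(metric = lab, q1_mean = mean(v1), q1_sd = sd(v1),
               q4_mean = mean(v4), q4_sd = sd(v4),
               t_stat = tt$t, df = tt$df, p_value = tt$p, power = pw,
               n_pairs = length(v1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "subgroup") <- subgroup
  attr(out, "alpha") <- alpha
  class(out) <- c("prv_comparison", class(out))
  out
}

#' @export
print.prv_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Paired Q1 vs Q4 comparison (%s, alpha = %g)\n",
              attr(x, "subgroup"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$q1 <- sprintf("%.3g (%.3g)", df$q1_mean, df$q1_sd)
  df$q4 <- sprintf("%.3g (%.3g)", df$q4_mean, df$q4_sd)
  print(df[, c("metric", "q1", "q4", "t_stat", "p_value", "power", "n_pairs")],
        row.names = FALSE, digits = digits)
  cat("Note: P values are from uncorrected paired t tests;",
      "no multiple-testing correction is applied.\n")
  invisible(x)
}
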