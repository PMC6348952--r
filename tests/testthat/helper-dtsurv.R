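# Shared fixtures and independent oracles for the test suite.

# Interval index of a failure time on a grid: first j with t < t_j,
# clamped into the last interval (mirrors the half-open convention but is
# computed directly from the boundaries, independent of encode_survival).
failure_interval <- function(t, boundaries) {
  j <- findInterval(t, boundaries, left.open = FALSE) + 1L
  min(j, length(boundaries))
}

# Direct per-individual discrete-time log likelihood, summing log h_j and
# log(1 - h_i) from interval indices: events contribute log h_j plus the
# survived intervals before j; censored individuals contribute log(1 - h_i)
# for every interval whose midpoint their censoring time reaches.
oracle_loglik <- function(time, event, boundaries, pred) {
  mids <- (c(0, boundaries[-length(boundaries)]) + boundaries) / 2
  sum(vapply(seq_along(time), function(i) {
    p <- pred[i, ]
    if (event[i] == 1) {
      j <- failure_interval(time[i], boundaries)
      log(1 - p[j]) + sum(log(p[seq_len(j - 1L)]))
    } else {
      sum(log(p[time[i] >= mids]))
    }
  }, numeric(1)))
}

# Life-table hazard estimates d_j / r_j from an encoding: r_j counts the
# individuals exposed in interval j (those that survive it or fail in it).
life_table_hazards <- function(enc) {
  d <- colSums(enc$surv_f)
  r <- colSums(enc$surv_s + enc$surv_f)
  d / r
}

# Small random censored cohort with continuous times (no ties).
random_cohort <- function(n, seed, censor_rate = 1 / 200) {
  set.seed(seed)
  t_true <- rexp(n, 1 / 150)
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  data.frame(time = pmin(t_true, t_cens),
             event = as.integer(t_true <= t_cens))
}

expect_binary_matrix <- function(m) {
  expect_true(all(m %in% c(0, 1)))
}
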