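#' Two-group exponential cohort
#'
#' Simulates the one-binary-covariate validation cohort: the first half of
#' the patients carry covariate 0 (poor prognosis, exponential survival with
#' median `median0` days) and the second half covariate 1 (good prognosis,
#' median `median1` days). Censoring times are drawn independently from an
#' exponential distribution with median (half-life) `censor_median` days;
#' the observed time is the minimum and the event indicator records whether
#' the failure was observed.
#'
#' @param n Cohort size (default 5000).
#' @param median0,median1 Median survival (days) of the covariate-0 and
#'   covariate-1 groups (defaults 200 and 400).
#' @param censor_median Median of the exponential censoring distribution in
#'   days (default 400).
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   cohort exactly.
#' @return A data frame with columns `time`, `event`, `x`, plus a `latent`
#'   attribute (data frame of the uncensored survival and censoring times)
#'   and a `seed` attribute.
#' @export
simulate_two_group <- function(n = 5000L, median0 = 200, median1 = 400,
                               censor_median = 400, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(n >= 0, median0 > 0, median1 > 0, censor_median > 0)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  n0 <- ceiling(n / 2)
  x <- rep(c(0, 1), c(n0, n - n0))
  med <- ifelse(x == 0, median0, median1)
  t_true <- stats::rexp(n, rate = log(2) / med)
  t_cens <- stats::rexp(n, rate = log(2) / censor_median)
  out <- data.frame(time = pmin(t_true, t_cens),
                    event = as.integer(t_true <= t_cens),
                    x = x)
  attr(out, "latent") <- data.frame(true_time = t_true, censor_time = t_cens)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Default Weibull scales for the binary-covariate cohort
#'
#' Solves for group scale parameters such that the pooled (50/50 mixture)
#' median survival equals `pooled_median` while the group medians stand in
#' the given ratio. Used as the documented defaults of
#' [simulate_weibull_binary()].
#'
#' @param shape Weibull shape parameter shared by both groups.
#' @param pooled_median Target median of the pooled population, days.
#' @param ratio Ratio of the good-prognosis to poor-prognosis median.
#' @return Named numeric vector `c(scale0, scale1)` in days.
#' @export
weibull_binary_scales <- function(shape = 1.2, pooled_median = 182,
                                  ratio = 2) {
  stopifnot(shape > 0, pooled_median > 0, ratio > 0)
  mix_surv <- function(s0) {
    0.5 * exp(-(pooled_median / s0)^shape) +
      0.5 * exp(-(pooled_median / (ratio * s0))^shape) - 0.5
  }
  s0 <- stats::uniroot(mix_surv, interval = pooled_median * c(0.05, 20),
                       tol = 1e-10)$root
  c(scale0 = s0, scale1 = ratio * s0)
}

#' Binary-covariate Weibull cohort
#'
#' Simulates a cohort whose survival times follow a Weibull distribution
#' with a common shape and a scale depending on a balanced binary covariate.
#' Default scales make the pooled median survival 182 days with group
#' medians in ratio 2:1. Follow-up is administratively censored at
#' `admin_censor` days.
#'
#' @param n Cohort size (default 5000).
#' @param shape Weibull shape (default 1.2; `shape = 1` is exponential).
#' @param scale0,scale1 Weibull scale (days) for covariate 0 / 1; defaults
#'   from [weibull_binary_scales()].
#' @param admin_censor Administrative censoring time in days (default 1825);
#'   `Inf` disables censoring.
#' @param seed Integer seed.
#' @return Data frame with columns `time`, `event`, `x`; `latent` and `seed`
#'   attributes as in [simulate_two_group()].
#' @export
simulate_weibull_binary <- function(n = 5000L, shape = 1.2,
                                    scale0 = NULL, scale1 = NULL,
                                    admin_censor = 1825, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(n >= 0, shape > 0)
  if (is.null(scale0) || is.null(scale1)) {
    sc <- weibull_binary_scales(shape)
    if (is.null(scale0)) scale0 <- sc[["scale0"]]
    if (is.null(scale1)) scale1 <- sc[["scale1"]]
  }
  stopifnot(scale0 > 0, scale1 > 0)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  n0 <- ceiling(n / 2)
  x <- rep(c(0, 1), c(n0, n - n0))
  t_true <- stats::rweibull(n, shape = shape,
                            scale = ifelse(x == 0, scale0, scale1))
  out <- data.frame(time = pmin(t_true, admin_censor),
                    event = as.integer(t_true <= admin_censor),
                    x = x)
  attr(out, "latent") <- data.frame(true_time = t_true)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' True median survival for a digit label
#'
#' In the digit-dependent exponential design the scale parameter is
#' `365 exp(-0.9 digit) / ln 2` days, so the median survival is
#' `365 exp(-0.9 digit)`: 365 days for digit 0 down to about 10 days for
#' digit 4.
#'
#' @param digit Integer label(s).
#' @param coef Per-digit log-hazard increment (default 0.9).
#' @param base_halflife Median survival of digit 0, days (default 365).
#' @return Median survival time(s) in days.
#' @export
digit_median <- function(digit, coef = 0.9, base_halflife = 365) {
  base_halflife * exp(-coef * digit)
}

#' Digit-dependent exponential cohort
#'
#' Simulates the image-surrogate validation cohort: each individual carries
#' a digit label drawn uniformly from `digits`, and an uncensored survival
#' time from an exponential distribution whose scale is
#' `base_halflife exp(-coef digit) / ln 2` days — higher digits behave like
#' larger, deadlier tumours with shorter median survival. Optionally, noisy
#' one-hot encodings of the digit stand in for image features so that a
#' network must recover the label from imperfect covariates.
#'
#' @param n Cohort size.
#' @param digits Integer label range (default `0:4`).
#' @param coef Per-digit log-hazard increment (default 0.9).
#' @param base_halflife Median survival of digit 0 in days (default 365).
#' @param noisy_features Number of noisy one-hot copies of the digit to
#'   append as covariates (default 0 = the digit column only); each copy is
#'   the one-hot indicator plus independent Gaussian noise with `noise_sd`.
#' @param noise_sd Standard deviation of the feature noise (default 0.5).
#' @param seed Integer seed.
#' @return Data frame with columns `time`, `event` (all 1: no censoring in
#'   this design), `digit`, and optional feature columns `f*`; `latent` and
#'   `seed` attributes.
#' @export
simulate_digit_cohort <- function(n, digits = 0:4, coef = 0.9,
                                  base_halflife = 365, noisy_features = 0L,
                                  noise_sd = 0.5, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(n >= 0, base_halflife > 0, noisy_features >= 0)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  digit <- sample(digits, n, replace = TRUE)
  beta <- base_halflife * exp(-coef * digit) / log(2)
  time <- stats::rexp(n, rate = 1 / beta)
  out <- data.frame(time = time, event = rep(1L, n), digit = digit)
  if (noisy_features > 0) {
    K <- length(digits)
    onehot <- outer(digit, digits, "==") + 0
    feats <- do.call(cbind, lapply(seq_len(noisy_features), function(r) {
      onehot + matrix(stats::rnorm(n * K, sd = noise_sd), n, K)
    }))
    colnames(feats) <- paste0("f", seq_len(ncol(feats)))
    out <- cbind(out, as.data.frame(feats))
  }
  attr(out, "latent") <- data.frame(digit = digit, scale = beta)
  attr(out, "seed") <- as.integer(seed)
  out
}
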