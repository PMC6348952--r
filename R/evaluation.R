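#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function from right-censored data,
#' computed with [survival::survfit()].
#'
#' @param time,event Follow-up times (days) and 0/1 event indicators.
#' @return Object of class `km_curve`: data at each observed time (`time`,
#'   `n_risk`, `n_event`, `surv`).
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) stop("empty input")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 surv = sf$surv, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "individuals,", sum(x$n_event), "events\n")
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation; `left = TRUE` gives the left limit `S(t-)`,
#' i.e., the value just before `t` (used for the weights of the censored
#' Brier score).
#'
#' @param km A `km_curve`.
#' @param t Times in days.
#' @param left Evaluate the left limit instead of the right-continuous value.
#' @return Numeric vector of survival probabilities.
#' @export
km_at <- function(km, t, left = FALSE) {
  idx <- if (left) findInterval(t, km$time, left.open = TRUE)
         else findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Harrell's concordance index
#'
#' The fraction of comparable pairs in which the individual predicted to
#' survive longer actually does. A pair is comparable when one member is an
#' observed event with a strictly earlier time than the other's follow-up
#' time; tied predicted scores receive credit 0.5; pairs with tied survival
#' times (including two events at the same time) are not compared. The index
#' depends on scores only through their ranks, so any strictly monotone
#' transform leaves it unchanged.
#'
#' @param score Per-individual ranking value, higher = longer predicted
#'   survival (e.g., predicted 1-year survival probability).
#' @param time,event Follow-up times and 0/1 event indicators.
#' @return Concordance in `[0, 1]`; 0.5 is chance.
#' @export
c_index <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  if (anyNA(score) || any(!is.finite(score))) stop("scores must be finite")
  tall <- cindex_tally(as.numeric(time), as.integer(event), as.numeric(score))
  if (tall[3] == 0)
    stop("no comparable pairs: concordance is undefined")
  (tall[1] + 0.5 * tall[2]) / tall[3]
}

#' Brier score for censored data
#'
#' Mean squared error between predicted survival probability at time `t` and
#' observed status, reweighted by the inverse probability of remaining
#' uncensored (the Graf adaptation). Individuals who failed by `t`
#' contribute `S_hat(t)^2 / G(T_i-)`; individuals still under observation
#' past `t` contribute `(1 - S_hat(t))^2 / G(t)`; individuals censored by
#' `t` contribute nothing. `G` is the Kaplan-Meier estimate of the censoring
#' distribution (event indicator reversed). With no censoring the score
#' reduces exactly to the mean squared error against the 0/1 outcome.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param pred Predicted probability of surviving beyond `t`, one per
#'   individual, in `[0, 1]`.
#' @param t Evaluation time in days.
#' @return Non-negative score (lower is better calibration).
#' @export
brier_censored <- function(time, event, pred, t) {
  stopifnot(length(time) == length(event), length(pred) == length(time))
  if (any(pred < 0 | pred > 1)) stop("'pred' must lie in [0, 1]")
  G <- kaplan_meier(time, 1 - event)
  failed <- time <= t & event == 1
  surviving <- time > t
  G_t <- km_at(G, t)
  if (any(surviving) && G_t == 0)
    stop("censoring survival G(t) is zero at t = ", t,
         ": the weighted Brier score is undefined")
  w_fail <- km_at(G, time[failed], left = TRUE)
  if (any(w_fail == 0))
    stop("censoring survival G(T-) is zero for some failure times")
  contrib <- numeric(length(time))
  contrib[failed] <- pred[failed]^2 / w_fail
  contrib[surviving] <- (1 - pred[surviving])^2 / G_t
  mean(contrib)
}

#' Calibration table by predicted-risk groups
#'
#' Groups individuals by quantiles of their predicted survival probability
#' at time `t` (deciles by default) and compares, per group, the mean
#' predicted probability with the Kaplan-Meier estimate of actual survival
#' at `t`. Grouping cuts act on ranks, so heavily tied predictions are split
#' as evenly as possible.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param pred Predicted survival probabilities at `t`.
#' @param t Evaluation time in days.
#' @param n_groups Number of quantile groups (default 10).
#' @return A data frame of class `calibration_table` with columns `group`,
#'   `n`, `mean_predicted`, `km_actual`.
#' @export
calibration_deciles <- function(time, event, pred, t, n_groups = 10L) {
  stopifnot(length(time) == length(event), length(pred) == length(time))
  N <- length(time)
  n_groups <- as.integer(n_groups)
  if (N < n_groups)
    stop("need at least ", n_groups, " individuals for ", n_groups, " groups")
  grp <- ceiling(rank(pred, ties.method = "first") * n_groups / N)
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    in_g <- grp == g
    km <- kaplan_meier(time[in_g], event[in_g])
    data.frame(group = g, n = sum(in_g),
               mean_predicted = mean(pred[in_g]),
               km_actual = km_at(km, t))
  }))
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Observed and average predicted survival curves per group
#'
#' For each group label, averages the model-predicted survival over the
#' group's individuals on a mesh of follow-up times and pairs it with the
#' group's Kaplan-Meier curve — the standard construction for overlaying
#' predicted and actual survival.
#'
#' @param labels Group label per individual.
#' @param curves A [survival_curve()] object with one row per individual.
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param mesh Times (days) at which to average predictions; defaults to the
#'   grid origin and boundaries.
#' @return Named list (one element per group level) of lists with `predicted`
#'   (data frame `time`, `mean_surv`) and `km` (the group's `km_curve`).
#' @export
calibration_by_group <- function(labels, curves, time, event, mesh = NULL) {
  stopifnot(inherits(curves, "surv_curve"),
            length(labels) == nrow(curves$S),
            length(time) == length(labels))
  if (is.null(mesh)) mesh <- c(0, curves$grid$boundaries)
  levs <- unique(labels)
  out <- lapply(levs, function(g) {
    in_g <- labels == g
    if (!any(in_g)) stop("empty group: ", g)
    sub <- structure(list(grid = curves$grid,
                          S = curves$S[in_g, , drop = FALSE]),
                     class = "surv_curve")
    pm <- survival_at(sub, mesh)
    if (is.matrix(pm)) pm <- colMeans(pm)
    list(predicted = data.frame(time = mesh, mean_surv = pm),
         km = kaplan_meier(time[in_g], event[in_g]))
  })
  names(out) <- as.character(levs)
  out
}

#' Time at which a survival curve crosses a probability
#'
#' Inverts the piecewise-linear reading of a survival curve: the first time
#' at which survival reaches `prob`. Used, e.g., to read off the median
#' survival time (`prob = 0.5`) of an averaged predicted curve.
#'
#' @param times Mesh times (days), increasing, starting at 0.
#' @param surv Survival probabilities at `times`, starting at 1.
#' @param prob Target probability.
#' @return Crossing time in days, or `NA` if the curve never reaches `prob`.
#' @export
crossing_time <- function(times, surv, prob = 0.5) {
  stopifnot(length(times) == length(surv))
  below <- which(surv <= prob)
  if (length(below) == 0L) return(NA_real_)
  j <- below[1]
  if (j == 1L) return(times[1])
  s1 <- surv[j - 1L]; s2 <- surv[j]
  if (s1 == s2) return(times[j])
  times[j - 1L] + (times[j] - times[j - 1L]) * (s1 - prob) / (s1 - s2)
}
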