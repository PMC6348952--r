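#' Follow-up time grids
#'
#' A `time_grid` partitions follow-up time into `n` left-closed, right-open
#' intervals `[t_{j-1}, t_j)`, `j = 1..n`, with implicit origin `t_0 = 0`.
#' The `boundaries` are the upper limits `t_1 < t_2 < ... < t_n`, in days.
#'
#' @param boundaries Strictly increasing positive numeric vector of interval
#'   upper limits, in days.
#' @return An object of class `time_grid` with elements `boundaries` and `n`.
#' @examples
#' time_grid(c(10, 20, 30))
#' @export
time_grid <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || anyNA(boundaries))
    stop("'boundaries' must be a non-empty numeric vector without NA")
  if (any(boundaries <= 0))
    stop("all grid boundaries must be positive")
  if (any(diff(boundaries) <= 0))
    stop("grid boundaries must be strictly increasing")
  structure(list(boundaries = boundaries, n = length(boundaries)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("Time grid:", x$n, "intervals over [0,", max(x$boundaries), ") days\n")
  cat("Boundaries:", paste(signif(x$boundaries, 6), collapse = " "), "\n")
  invisible(x)
}

#' @export
format.time_grid <- function(x, ...) {
  paste0("time_grid<", x$n, ">")
}

# interval midpoints (t_{j-1} + t_j)/2 with t_0 = 0
grid_midpoints <- function(grid) {
  b <- grid$boundaries
  (c(0, b[-grid$n]) + b) / 2
}

#' Uniform-width time grid
#'
#' Boundaries at `width, 2 width, ...` up to the smallest multiple of `width`
#' that is at least `max_time` (the last interval is extended past `max_time`
#' when it is not an exact multiple).
#'
#' @param width Interval width in days; must be positive.
#' @param max_time Largest follow-up time to cover, in days; must be at least
#'   `width`.
#' @return A [time_grid].
#' @examples
#' make_uniform_grid(365, 1780)  # five 1-year intervals, last ends at 1825
#' @export
make_uniform_grid <- function(width, max_time) {
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width <= 0)
    stop("'width' must be a single positive number")
  if (!is.numeric(max_time) || length(max_time) != 1L || is.na(max_time) ||
      max_time <= 0)
    stop("'max_time' must be a single positive number")
  if (max_time < width)
    stop("'max_time' must be at least 'width'")
  n <- ceiling(max_time / width)
  time_grid(width * seq_len(n))
}

#' Geometric (half-life) time grid
#'
#' Boundaries placed so that a reference exponential distribution with the
#' given half-life has the supplied cumulative event fractions at the
#' borders: the border for fraction `x` is `-ln(1 - x) * half_life / ln 2`.
#' Interval widths grow with follow-up time, so that roughly equal numbers of
#' events from that reference distribution fall in each interval.
#'
#' @param half_life Half-life of the reference exponential, in days.
#' @param coverage_fractions Strictly increasing fractions in `[0, 1)`; the
#'   first must be 0 (it maps to the origin). A fraction of 1 would place a
#'   border at infinity and is rejected.
#' @return A [time_grid] with `length(coverage_fractions) - 1` intervals.
#' @examples
#' make_halflife_grid(365, seq(0, 0.95, by = 0.05))  # 19 widening intervals
#' @export
make_halflife_grid <- function(half_life, coverage_fractions) {
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0)
    stop("'half_life' must be a single positive number")
  x <- as.numeric(coverage_fractions)
  if (length(x) < 2L || x[1] != 0)
    stop("'coverage_fractions' must start at 0 and contain at least one more value")
  if (any(x >= 1))
    stop("coverage fractions must be < 1 (a fraction of 1 gives an infinite border)")
  if (any(diff(x) <= 0))
    stop("'coverage_fractions' must be strictly increasing")
  time_grid(-log(1 - x[-1]) * half_life / log(2))
}

#' Event-quantile time grid
#'
#' Places boundaries at empirical quantiles of the observed event times, so
#' that around the same number of events falls into each interval. The last
#' boundary is extended to cover the maximum follow-up time (events or
#' censorings) when needed, since the model makes no predictions past the end
#' of the last interval.
#'
#' @param time,event Numeric follow-up times (days) and 0/1 event indicators.
#' @param n_intervals Number of intervals requested. Requires at least this
#'   many distinct event times. Duplicate quantile values are collapsed, with
#'   a warning, reducing the number of intervals.
#' @return A [time_grid].
#' @examples
#' make_event_quantile_grid(1:100, rep(1, 100), 4)
#' @export
make_event_quantile_grid <- function(time, event, n_intervals) {
  stopifnot(length(time) == length(event))
  if (!is.numeric(n_intervals) || length(n_intervals) != 1L || n_intervals < 1)
    stop("'n_intervals' must be a single positive integer")
  n_intervals <- as.integer(n_intervals)
  ev_times <- time[event == 1]
  if (length(unique(ev_times)) < n_intervals)
    stop("need at least ", n_intervals, " distinct event times, have ",
         length(unique(ev_times)))
  probs <- seq_len(n_intervals) / n_intervals
  b <- unname(stats::quantile(ev_times, probs = probs, type = 7))
  b[n_intervals] <- max(b[n_intervals], max(time))
  if (anyDuplicated(b)) {
    b <- unique(b)
    warning("duplicate quantile boundaries collapsed; grid reduced to ",
            length(b), " intervals")
  }
  time_grid(b)
}
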