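#' Encode censored follow-up as target vectors
#'
#' Transforms each individual's `(time, event)` pair into the paired binary
#' target vectors used by the discrete-time likelihood: `surv_s` marks the
#' intervals survived and `surv_f` the interval of failure (if any), on a
#' shared [time_grid].
#'
#' For an individual with an observed failure at time `t`,
#' `surv_s[j] = 1` iff `t >= t_j` and `surv_f[j] = 1` iff
#' `t_{j-1} <= t < t_j`. For a censored individual, `surv_s[j] = 1` iff the
#' censoring time reaches the midpoint of interval `j` — so censoring in the
#' second half of an interval earns "credit" for surviving it, which removes
#' the downward bias of dropping such individuals at the interval start — and
#' `surv_f` is identically zero.
#'
#' Failure times at or beyond the last boundary are clamped into the final
#' interval with a warning; extend the grid past the last follow-up time of
#' interest to avoid this. A censored time before the midpoint of the first
#' interval yields all-zero vectors: the individual contributes nothing to
#' the likelihood but is retained (a warning is emitted).
#'
#' @param time Numeric vector of follow-up times in days (failure time for
#'   events, censoring time otherwise); non-negative.
#' @param event 0/1 event indicators (1 = failure observed).
#' @param grid A [time_grid].
#' @return An object of class `surv_encoding`: a list with binary matrices
#'   `surv_s` and `surv_f` (individuals x intervals) and the `grid`.
#' @examples
#' g <- time_grid(c(10, 20, 30))
#' encode_survival(c(15, 25), c(1, 0), g)
#' @export
encode_survival <- function(time, event, grid) {
  stopifnot(inherits(grid, "time_grid"))
  time <- as.numeric(time)
  if (anyNA(time) || any(time < 0))
    stop("'time' must be non-negative and free of NA")
  event <- as.integer(event)
  if (length(event) != length(time) || anyNA(event) || !all(event %in% c(0L, 1L)))
    stop("'event' must be a 0/1 vector matching 'time'")

  b <- grid$boundaries
  n <- grid$n
  N <- length(time)
  mids <- grid_midpoints(grid)

  surv_s <- matrix(0, N, n)
  surv_f <- matrix(0, N, n)
  if (N == 0L)
    return(structure(list(surv_s = surv_s, surv_f = surv_f, grid = grid),
                     class = "surv_encoding"))

  ev <- event == 1L
  if (any(ev)) {
    t_ev <- time[ev]
    over <- t_ev >= b[n]
    if (any(over)) {
      warning(sum(over), " event time(s) at or beyond the last boundary ",
              b[n], " clamped into the final interval")
    }
    # failure interval: first j with t < t_j, clamped to n
    fint <- findInterval(t_ev, b, left.open = FALSE) + 1L
    fint[fint > n] <- n
    surv_s[ev, ] <- outer(t_ev, b, ">=")
    # clamped times must not also claim survival of the final interval
    surv_s[ev, n][over] <- 0
    surv_f[cbind(which(ev), fint)] <- 1
  }
  if (any(!ev)) {
    t_c <- time[!ev]
    surv_s[!ev, ] <- outer(t_c, mids, ">=")
    if (any(t_c < mids[1]))
      warning(sum(t_c < mids[1]), " censoring time(s) before the first ",
              "interval midpoint contribute nothing to the likelihood")
  }
  structure(list(surv_s = surv_s, surv_f = surv_f, grid = grid),
            class = "surv_encoding")
}

#' @export
print.surv_encoding <- function(x, ...) {
  cat("Survival encoding:", nrow(x$surv_s), "individuals x",
      ncol(x$surv_s), "intervals\n")
  cat("Events encoded:", sum(x$surv_f), "\n")
  invisible(x)
}

#' Encode a single record
#'
#' Convenience wrapper around [encode_survival()] for one individual;
#' returns plain vectors.
#'
#' @inheritParams encode_survival
#' @param time Follow-up time in days.
#' @param event 0 or 1.
#' @return List with binary vectors `surv_s` and `surv_f` of length `grid$n`.
#' @export
encode_record <- function(time, event, grid) {
  enc <- encode_survival(time, event, grid)
  list(surv_s = as.vector(enc$surv_s[1, ]), surv_f = as.vector(enc$surv_f[1, ]))
}
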