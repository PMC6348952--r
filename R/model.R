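#' @useDynLib dtsurv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# numerical floor/ceiling applied to probabilities before logs/powers
.dtsurv_eps <- 1e-7

clip01 <- function(p, eps = .dtsurv_eps) pmin(pmax(p, eps), 1 - eps)

sigmoid <- function(x) 1 / (1 + exp(-x))

as_pred_matrix <- function(surv_pred) {
  if (is.matrix(surv_pred)) surv_pred else matrix(surv_pred, nrow = 1)
}

#' Flexible output head
#'
#' Maps a batch of feature vectors to per-interval conditional survival
#' probabilities through a dense layer with one output per interval: the log
#' odds of surviving interval `j` is `hidden . kernel_j + bias_j`, passed
#' through a sigmoid. Both the baseline hazard and the effect of the input
#' can vary freely across intervals, so proportional hazards is not assumed.
#'
#' @param hidden Numeric matrix (batch x d) of incoming feature values, or a
#'   single feature vector.
#' @param kernel Weight matrix (d x n), `n` the number of intervals.
#' @param bias Numeric vector of `n` bias weights.
#' @return Matrix (batch x n) of conditional survival probabilities
#'   `surv_pred = 1 - h`, clipped away from 0 and 1.
#' @export
flexible_head <- function(hidden, kernel, bias) {
  if (!is.matrix(hidden)) hidden <- matrix(hidden, nrow = 1)
  kernel <- as.matrix(kernel)
  if (ncol(hidden) != nrow(kernel))
    stop("feature dimension ", ncol(hidden),
         " does not match kernel rows ", nrow(kernel))
  if (length(bias) != ncol(kernel))
    stop("bias length must equal the number of output intervals")
  logits <- sweep(hidden %*% kernel, 2, bias, "+")
  clip01(sigmoid(logits))
}

#' Proportional-hazards output head
#'
#' The conditional survival of interval `j` is
#' `(1 - h_base_j)^exp(xbeta)`, where the baseline conditional survival
#' `1 - h_base_j = sigmoid(base_logits_j)` is a free weight per interval and
#' `xbeta` is the scalar linear predictor (no bias). Covariates scale the
#' cumulative hazard by the time-constant factor `exp(xbeta)` — the
#' discrete-time analogue of a complementary log-log proportional-hazards
#' model.
#'
#' @param xbeta Numeric vector of linear predictors, one per individual.
#' @param base_logits Numeric vector of `n` baseline log-odds weights.
#' @return Matrix (batch x n) of conditional survival probabilities.
#' @export
ph_head <- function(xbeta, base_logits) {
  q <- clip01(sigmoid(base_logits))
  e <- exp(as.numeric(xbeta))
  clip01(outer(e, q, function(ei, qj) qj^ei))
}

#' Discrete-time survival loss (negative log likelihood)
#'
#' The loss of the model: minus the log likelihood of the encoded outcomes
#' under the predicted conditional survival probabilities,
#' \deqn{-\sum_i \sum_j \log(1 + s_{ij}(p_{ij} - 1)) + \log(1 - f_{ij} p_{ij}),}
#' where `s`/`f` are the `surv_s`/`surv_f` target matrices and `p` the
#' predictions. Each individual contributes `log h_j + sum_{i<j} log(1-h_i)`
#' if failing in interval `j`, and `sum log(1-h_i)` over intervals survived
#' if censored; the loss of a mini-batch depends only on its members, which
#' is what makes mini-batch gradient descent applicable.
#'
#' @param encoding A `surv_encoding` from [encode_survival()], or a list with
#'   binary matrices `surv_s` and `surv_f`.
#' @param surv_pred Matrix (individuals x intervals) of predicted conditional
#'   survival probabilities; clipped to `[1e-7, 1 - 1e-7]` before logs.
#' @param reduction `"sum"` (default) or `"mean"` over individuals; the
#'   choice only rescales gradients (and hence the effective learning rate).
#' @return Scalar loss.
#' @examples
#' g <- time_grid(c(10, 20))
#' enc <- encode_survival(25, 0, g)
#' nll_loss(enc, matrix(c(0.8, 0.9), 1))  # -(log 0.8 + log 0.9)
#' @export
nll_loss <- function(encoding, surv_pred, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  p <- clip01(as_pred_matrix(surv_pred))
  s <- encoding$surv_s
  f <- encoding$surv_f
  if (!all(dim(s) == dim(p)))
    stop("prediction matrix (", nrow(p), " x ", ncol(p),
         ") does not match encoding (", nrow(s), " x ", ncol(s), ")")
  ll <- log(1 + s * (p - 1)) + log(1 - f * p)
  tot <- -sum(ll)
  if (reduction == "mean") tot / nrow(p) else tot
}

# gradient of nll_loss (sum reduction) w.r.t. the predictions
nll_loss_grad <- function(encoding, surv_pred) {
  p <- clip01(as_pred_matrix(surv_pred))
  s <- encoding$surv_s
  f <- encoding$surv_f
  -(s / (1 + s * (p - 1)) - f / (1 - f * p))
}

#' Squared-error discrete-time loss
#'
#' The earlier heuristic loss for discrete-time network survival models: each
#' interval an individual survives contributes `h^2 / 2` and the failure
#' interval contributes `(1 - h)^2 / 2`, with `h = 1 - surv_pred`. For a null
#' model its minimiser coincides with the life-table hazard `d_j / r_j`, but
#' with covariates it minimises a different objective than the likelihood and
#' yields different parameters. Provided for comparison; [nll_loss()] is the
#' model's loss.
#'
#' @inheritParams nll_loss
#' @return Scalar loss.
#' @export
brown_loss <- function(encoding, surv_pred, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  p <- as_pred_matrix(surv_pred)
  s <- encoding$surv_s
  f <- encoding$surv_f
  if (!all(dim(s) == dim(p)))
    stop("prediction matrix does not match encoding dimensions")
  tot <- sum(0.5 * s * (1 - p)^2 + 0.5 * f * p^2)
  if (reduction == "mean") tot / nrow(p) else tot
}

#' Cumulative survival curve from conditional survival
#'
#' Converts per-interval conditional survival probabilities into cumulative
#' survival at interval ends, `S_j = prod_{i <= j} surv_pred_i`.
#'
#' @param surv_pred Matrix (individuals x intervals) or a single vector of
#'   conditional survival probabilities.
#' @param grid The [time_grid] the predictions refer to.
#' @return An object of class `surv_curve`: list with the `grid` and matrix
#'   `S` (individuals x intervals) of cumulative survival probabilities.
#' @examples
#' survival_curve(c(0.9, 0.8), time_grid(c(10, 20)))  # S = 0.9, 0.72
#' @export
survival_curve <- function(surv_pred, grid) {
  stopifnot(inherits(grid, "time_grid"))
  p <- as_pred_matrix(surv_pred)
  if (ncol(p) != grid$n)
    stop("predictions have ", ncol(p), " intervals but grid has ", grid$n)
  S <- p
  if (ncol(p) > 1L && nrow(p) > 0L) {
    for (j in 2:ncol(p)) S[, j] <- S[, j - 1L] * p[, j]
  }
  structure(list(grid = grid, S = S), class = "surv_curve")
}

#' @export
print.surv_curve <- function(x, ...) {
  cat("Step survival curve(s):", nrow(x$S), "individual(s),",
      x$grid$n, "intervals to day", max(x$grid$boundaries), "\n")
  invisible(x)
}

#' Survival probability at arbitrary times
#'
#' Evaluates cumulative survival at times `t` by piecewise-linear
#' interpolation through `(0, 1), (t_1, S_1), ..., (t_n, S_n)`. The model
#' carries no information past the end of the last interval, so `t > t_n` is
#' an error rather than an extrapolation; `mode = "step"` gives the
#' right-continuous step-function reading instead of interpolating.
#'
#' @param curve A `surv_curve` from [survival_curve()].
#' @param t Numeric vector of times in days, each in `[0, t_n]`.
#' @param mode `"linear"` (default) or `"step"`.
#' @return Matrix (individuals x length(t)) of survival probabilities; a
#'   vector if the curve holds one individual.
#' @export
survival_at <- function(curve, t, mode = c("linear", "step")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "surv_curve"))
  t <- as.numeric(t)
  b <- curve$grid$boundaries
  if (any(t < 0) || any(t > max(b)))
    stop("'t' must lie within [0, ", max(b), "]; the model makes no ",
         "survival predictions past the end of the last time interval")
  knots_x <- c(0, b)
  out <- apply(curve$S, 1, function(Si) {
    knots_y <- c(1, Si)
    if (mode == "linear") {
      stats::approx(knots_x, knots_y, xout = t, method = "linear")$y
    } else {
      knots_y[findInterval(t, knots_x, left.open = FALSE)]
    }
  })
  out <- matrix(out, nrow = nrow(curve$S), ncol = length(t), byrow = TRUE)
  if (nrow(out) == 1L) as.vector(out) else out
}
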