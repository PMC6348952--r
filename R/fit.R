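#' Fit a discrete-time survival network
#'
#' Trains a small feed-forward network (any number of ReLU hidden layers,
#' possibly none) ending in either the flexible per-interval head
#' ([flexible_head()]) or the proportional-hazards head ([ph_head()]), by
#' minimising the discrete-time negative log likelihood ([nll_loss()]) plus
#' an optional L2 penalty on the weight matrices, using mini-batch gradient
#' descent with analytically backpropagated gradients. The loss of each step
#' depends only on the individuals in the current mini-batch, so training
#' scales to datasets processed in chunks.
#'
#' With no hidden layers and the flexible head the model is a per-interval
#' logistic regression of conditional survival on the covariates; with no
#' covariates at all it is a life-table model whose fitted hazards converge
#' to `d_j / r_j`.
#'
#' @param x Covariate matrix (individuals x features); may have zero columns
#'   for an intercept-only model. A data frame of numeric columns is
#'   accepted.
#' @param time,event Follow-up times (days) and 0/1 event indicators.
#' @param grid A [time_grid] partitioning follow-up.
#' @param head `"flexible"` or `"prop_hazards"`.
#' @param hidden Integer vector of hidden-layer sizes; `integer(0)` (default)
#'   for no hidden layer.
#' @param l2 Non-negative L2 penalty coefficient applied to weight matrices
#'   (not biases or baseline logits); see [cv_l2()] for choosing it by
#'   cross-validation.
#' @param optimizer `"rmsprop"` (default) or `"sgd"`.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size; capped at the number of individuals.
#' @param epochs Number of passes over the training data.
#' @param seed Integer seed controlling weight initialisation and batch
#'   shuffling; mandatory, so a fit is reproducible from its configuration.
#' @param verbose Print the training loss every `verbose` epochs (0 = quiet).
#' @return An object of class `dtsurv`: fitted parameters, the grid, the
#'   architecture and training configuration, the per-epoch mean training
#'   loss (`loss_history`) and the final training loss (`final_loss`, mean
#'   per individual, penalty excluded).
#' @examples
#' cohort <- simulate_two_group(400, seed = 7)
#' g <- make_uniform_grid(100, 1500)
#' fit <- dtsurv_fit(cohort[, "x", drop = FALSE], cohort$time, cohort$event,
#'                   g, epochs = 50, seed = 1)
#' predict(fit, data.frame(x = c(0, 1)), type = "survival", times = 365)
#' @export
dtsurv_fit <- function(x, time, event, grid,
                       head = c("flexible", "prop_hazards"),
                       hidden = integer(0), l2 = 0,
                       optimizer = c("rmsprop", "sgd"),
                       lr = 0.001, batch_size = 256L, epochs = 1000L,
                       seed, verbose = 0L) {
  head <- match.arg(head)
  optimizer <- match.arg(optimizer)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory: supply a single integer so the fit is reproducible")
  stopifnot(inherits(grid, "time_grid"), l2 >= 0, lr > 0, epochs >= 0)
  if (is.null(x)) x <- matrix(numeric(0), length(time), 0L)
  x <- as_feature_matrix(x)
  N <- nrow(x)
  if (N == 0L) stop("empty training set")
  if (length(time) != N)
    stop("'time'/'event' must have one entry per row of 'x'")
  if (head == "prop_hazards" && ncol(x) == 0L && length(hidden) == 0L)
    stop("the proportional-hazards head needs at least one input feature")

  enc <- encode_survival(time, event, grid)
  batch_size <- min(as.integer(batch_size), N)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  params <- init_params(ncol(x), hidden, grid$n, head)
  cache <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  n_batches <- ceiling(N / batch_size)
  loss_history <- numeric(epochs)

  for (epoch in seq_len(epochs)) {
    ord <- sample.int(N)
    for (bi in seq_len(n_batches)) {
      idx <- ord[(((bi - 1L) * batch_size + 1L):min(bi * batch_size, N))]
      batch_enc <- list(surv_s = enc$surv_s[idx, , drop = FALSE],
                        surv_f = enc$surv_f[idx, , drop = FALSE])
      gr <- network_grad(params, x[idx, , drop = FALSE], batch_enc,
                         hidden, head, l2)
      for (nm in names(params)) {
        g <- gr[[nm]]
        if (optimizer == "rmsprop") {
          cache[[nm]] <- 0.9 * cache[[nm]] + 0.1 * g^2
          params[[nm]] <- params[[nm]] - lr * g / (sqrt(cache[[nm]]) + 1e-7)
        } else {
          params[[nm]] <- params[[nm]] - lr * g
        }
      }
    }
    p_all <- network_forward(params, x, hidden, head)$pred
    loss_history[epoch] <- nll_loss(enc, p_all, reduction = "mean")
    if (!is.finite(loss_history[epoch]))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    if (verbose > 0 && epoch %% verbose == 0)
      message(sprintf("epoch %d  loss %.6f", epoch, loss_history[epoch]))
  }

  final_loss <- if (epochs > 0) loss_history[epochs] else
    nll_loss(enc, network_forward(params, x, hidden, head)$pred,
             reduction = "mean")
  structure(list(params = params, head = head, hidden = hidden, grid = grid,
                 features = colnames(x),
                 config = list(l2 = l2, optimizer = optimizer, lr = lr,
                               batch_size = batch_size, epochs = epochs,
                               seed = as.integer(seed)),
                 loss_history = loss_history, final_loss = final_loss),
            class = "dtsurv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_feature_matrix <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("covariate matrix contains NA; impute before fitting")
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# Glorot-uniform weight matrices, zero biases/baseline logits
init_params <- function(p, hidden, n_out, head) {
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / max(fan_in + fan_out, 1))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  params <- list()
  dims <- c(p, hidden)
  for (l in seq_along(hidden)) {
    params[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- numeric(hidden[l])
  }
  d_last <- dims[length(dims)]
  if (head == "flexible") {
    params$kernel <- glorot(d_last, n_out)
    params$bias <- numeric(n_out)
  } else {
    params$beta <- glorot(d_last, 1L)
    params$base_logits <- numeric(n_out)
  }
  params
}

network_forward <- function(params, x, hidden, head) {
  A <- x
  acts <- list(A)
  pre <- list()
  for (l in seq_along(hidden)) {
    Z <- sweep(A %*% params[[paste0("W", l)]], 2, params[[paste0("b", l)]], "+")
    A <- pmax(Z, 0)
    pre[[l]] <- Z
    acts[[l + 1]] <- A
  }
  if (head == "flexible") {
    pred <- flexible_head(A, params$kernel, params$bias)
    list(pred = pred, acts = acts, pre = pre)
  } else {
    xbeta <- as.numeric(A %*% params$beta)
    pred <- ph_head(xbeta, params$base_logits)
    list(pred = pred, acts = acts, pre = pre, xbeta = xbeta)
  }
}

# analytic gradient of mean-per-individual nll + l2 * sum(weights^2)
network_grad <- function(params, x, enc, hidden, head, l2) {
  m <- nrow(x)
  fw <- network_forward(params, x, hidden, head)
  p <- fw$pred
  dP <- nll_loss_grad(enc, p) / m
  gr <- list()
  A_last <- fw$acts[[length(fw$acts)]]
  if (head == "flexible") {
    dlogit <- dP * p * (1 - p)
    gr$kernel <- crossprod(A_last, dlogit) + 2 * l2 * params$kernel
    gr$bias <- colSums(dlogit)
    dA <- dlogit %*% t(params$kernel)
  } else {
    q <- clip01(sigmoid(params$base_logits))
    e <- exp(fw$xbeta)
    # p[i, j] = q[j] ^ e[i]
    dq <- colSums(dP * (e * p / rep(q, each = m)))
    gr$base_logits <- dq * q * (1 - q)
    dxbeta <- rowSums(dP * p * rep(log(q), each = m)) * e
    gr$beta <- crossprod(A_last, dxbeta) + 2 * l2 * params$beta
    dA <- matrix(dxbeta, ncol = 1) %*% t(params$beta)
  }
  for (l in rev(seq_along(hidden))) {
    dZ <- dA * (fw$pre[[l]] > 0)
    gr[[paste0("W", l)]] <- crossprod(fw$acts[[l]], dZ) +
      2 * l2 * params[[paste0("W", l)]]
    gr[[paste0("b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(params[[paste0("W", l)]])
  }
  gr[names(params)]
}

#' @export
print.dtsurv <- function(x, ...) {
  cat("Discrete-time survival network (", x$head, " head)\n", sep = "")
  cat("  features:", length(x$features), " hidden:",
      if (length(x$hidden)) paste(x$hidden, collapse = "-") else "none",
      " intervals:", x$grid$n, "\n")
  cat("  final training loss (mean/indiv):", format(x$final_loss, digits = 6),
      "\n")
  invisible(x)
}

#' Predictions from a fitted discrete-time survival network
#'
#' @param object A `dtsurv` fit.
#' @param newx Covariate matrix or data frame with the same columns used to
#'   fit.
#' @param type `"conditional"` for the per-interval conditional survival
#'   matrix, `"curve"` for a [survival_curve()] object, `"survival"` for
#'   survival probabilities at the supplied `times`.
#' @param times Times (days) for `type = "survival"`.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.dtsurv <- function(object, newx,
                           type = c("conditional", "curve", "survival"),
                           times = NULL, ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newx)
  if (ncol(x) != length(object$features))
    stop("'newx' has ", ncol(x), " columns; model expects ",
         length(object$features))
  pred <- network_forward(object$params, x, object$hidden, object$head)$pred
  if (type == "conditional") return(pred)
  curve <- survival_curve(pred, object$grid)
  if (type == "curve") return(curve)
  if (is.null(times)) stop("'times' must be supplied for type = 'survival'")
  survival_at(curve, times)
}

#' Choose the L2 penalty by k-fold cross-validation
#'
#' Fits the model on `k - 1` folds for each candidate penalty and scores the
#' held-out fold by its mean log likelihood; returns the candidate with the
#' highest cross-validated log likelihood.
#'
#' @inheritParams dtsurv_fit
#' @param lambdas Numeric vector of candidate L2 coefficients.
#' @param k Number of folds (default 10).
#' @param ... Further arguments passed to [dtsurv_fit()] (epochs, lr, ...).
#' @return List with `best` (the selected penalty) and `table` (a data frame
#'   of candidate penalties and their mean held-out log likelihood per
#'   individual).
#' @export
cv_l2 <- function(x, time, event, grid, lambdas, k = 10L, seed, ...) {
  if (missing(seed)) stop("'seed' is mandatory")
  x <- as_feature_matrix(x)
  N <- nrow(x)
  k <- min(as.integer(k), N)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  folds <- sample(rep_len(seq_len(k), N))
  cv_ll <- sapply(lambdas, function(lam) {
    mean(sapply(seq_len(k), function(fold) {
      tr <- folds != fold
      fit <- dtsurv_fit(x[tr, , drop = FALSE], time[tr], event[tr], grid,
                        l2 = lam, seed = seed, ...)
      enc <- encode_survival(time[!tr], event[!tr], grid)
      pred <- network_forward(fit$params, x[!tr, , drop = FALSE],
                              fit$hidden, fit$head)$pred
      -nll_loss(enc, pred, reduction = "mean")
    }))
  })
  list(best = lambdas[which.max(cv_ll)],
       table = data.frame(lambda = lambdas, cv_loglik = cv_ll))
}
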