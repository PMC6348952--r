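test_that("an intercept-only model recovers the life-table hazards", {
  co <- random_cohort(400, seed = 4, censor_rate = 0)  # no censoring
  g <- make_event_quantile_grid(co$time, co$event, 5)
  fit <- suppressWarnings(
    dtsurv_fit(NULL, co$time, co$event, g,
               batch_size = 400, epochs = 2500, lr = 0.01, seed = 2))
  pred <- predict(fit, matrix(numeric(0), 1, 0), type = "conditional")
  enc <- suppressWarnings(encode_survival(co$time, co$event, g))
  h_ref <- life_table_hazards(enc)
  expect_equal(as.vector(1 - pred), h_ref, tolerance = 1e-3)
  # with no censoring the fitted curve matches Kaplan-Meier at interval ends
  S_fit <- as.vector(predict(fit, matrix(numeric(0), 1, 0), type = "curve")$S)
  km <- kaplan_meier(co$time, co$event)
  expect_equal(S_fit, km_at(km, g$boundaries), tolerance = 5e-3)
})

test_that("training is reproducible from the seed and leaves the RNG alone", {
  co <- random_cohort(150, seed = 6)
  x <- matrix(rnorm(150), 150, 1)
  g <- make_uniform_grid(100, 600)
  set.seed(123); before <- runif(3)
  set.seed(123)
  invisible(suppressWarnings(
    dtsurv_fit(x, co$time, co$event, g, epochs = 5, seed = 9)))
  after <- runif(3)
  expect_equal(after, before)  # global RNG stream untouched by the fit
  expect_error(dtsurv_fit(x, co$time, co$event, g, epochs = 1), "seed")
})

test_that("identical seeds give identical fits, different seeds differ", {
  co <- random_cohort(200, seed = 10)
  x <- matrix(rnorm(200), 200, 1)
  g <- make_uniform_grid(100, 600)
  f1 <- suppressWarnings(dtsurv_fit(x, co$time, co$event, g, epochs = 20, seed = 5))
  f2 <- suppressWarnings(dtsurv_fit(x, co$time, co$event, g, epochs = 20, seed = 5))
  f3 <- suppressWarnings(dtsurv_fit(x, co$time, co$event, g, epochs = 20, seed = 6))
  expect_identical(f1$params, f2$params)
  expect_false(isTRUE(all.equal(f1$params, f3$params)))
})

test_that("a descent step decreases the training loss", {
  co <- random_cohort(300, seed = 12)
  x <- matrix(co$time * 0 + rnorm(300), 300, 1)
  g <- make_uniform_grid(100, 800)
  f0 <- suppressWarnings(dtsurv_fit(x, co$time, co$event, g, epochs = 0, seed = 3))
  f1 <- suppressWarnings(dtsurv_fit(x, co$time, co$event, g, epochs = 1, seed = 3))
  f5 <- suppressWarnings(dtsurv_fit(x, co$time, co$event, g, epochs = 5, seed = 3))
  expect_lt(f1$final_loss, f0$final_loss)
  expect_lt(f5$final_loss, f1$final_loss)
})

test_that("analytic parameter gradients match central finite differences", {
  set.seed(5)
  n <- 25
  g <- time_grid(c(50, 100, 200))
  x <- matrix(rnorm(n * 3), n, 3)
  time <- rexp(n, 1 / 120); event <- rbinom(n, 1, 0.6)
  enc <- suppressWarnings(encode_survival(time, event, g))
  for (head in c("flexible", "prop_hazards")) {
    hidden <- 4L
    params <- dtsurv:::init_params(3L, hidden, g$n, head)
    loss_fn <- function(pv) {
      p2 <- utils::relist(pv, params)
      for (nm in names(p2)) dim(p2[[nm]]) <- dim(params[[nm]])
      fw <- dtsurv:::network_forward(p2, x, hidden, head)
      pen <- sum(unlist(p2[grep("^(W|kernel|beta)", names(p2))])^2)
      nll_loss(enc, fw$pred, reduction = "mean") + 0.01 * pen
    }
    an <- unlist(dtsurv:::network_grad(params, x, enc, hidden, head,
                                       l2 = 0.01))
    pv <- unlist(params)
    num <- vapply(seq_along(pv), function(i) {
      up <- pv; up[i] <- up[i] + 1e-5
      dn <- pv; dn[i] <- dn[i] - 1e-5
      (loss_fn(up) - loss_fn(dn)) / 2e-5
    }, numeric(1))
    expect_equal(unname(an), unname(num), tolerance = 1e-5)
  }
})

test_that("the fitted ph head keeps the proportional-hazards structure", {
  co <- simulate_two_group(600, seed = 21)
  g <- make_uniform_grid(200, 1400)
  fit <- suppressWarnings(
    dtsurv_fit(co[, "x", drop = FALSE], co$time, co$event, g,
               head = "prop_hazards", epochs = 300, batch_size = 600,
               lr = 0.02, seed = 2))
  p <- predict(fit, data.frame(x = c(0, 1)), type = "conditional")
  ratio <- log(p[2, ]) / log(p[1, ])
  expect_equal(ratio, rep(ratio[1], g$n), tolerance = 1e-6)
  # the good-prognosis group must get the lower cumulative hazard
  expect_lt(ratio[1], 1)
})

test_that("likelihood and squared-error losses have different minimisers", {
  g <- time_grid(c(1, 2))
  x <- rep(c(0, 1), each = 30)
  time <- c(rep(0.5, 12), rep(1.5, 10), rep(2.5, 8),
            rep(0.5, 4), rep(1.5, 10), rep(2.5, 16))
  event <- as.integer(time < 2.5)
  enc <- encode_survival(time, event, g)
  mkpred <- function(par) ph_head(x * par[1], par[2:3])
  o_nll <- optim(c(0, 0, 0), function(par) nll_loss(enc, mkpred(par)),
                 method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  o_brown <- optim(c(0, 0, 0), function(par) brown_loss(enc, mkpred(par)),
                   method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  expect_equal(o_nll$convergence, 0)
  expect_equal(o_brown$convergence, 0)
  expect_gt(max(abs(o_nll$par - o_brown$par)), 0.01)
})

test_that("cross-validation selects a sensible L2 strength", {
  co <- simulate_digit_cohort(600, seed = 31)
  g <- make_event_quantile_grid(co$time, co$event, 5)
  cv <- suppressWarnings(
    cv_l2(co[, "digit", drop = FALSE], co$time, co$event, g,
          lambdas = c(0, 100), k = 3, seed = 8,
          epochs = 500, batch_size = 600, lr = 0.02))
  expect_equal(nrow(cv$table), 2)
  expect_true(all(is.finite(cv$table$cv_loglik)))
  # a crushing penalty erases a strong predictor: held-out likelihood drops
  expect_equal(cv$best, 0)
})

test_that("checkpoints round-trip fits exactly", {
  co <- simulate_two_group(120, seed = 41)
  g <- make_uniform_grid(300, 1200)
  fit <- suppressWarnings(
    dtsurv_fit(co[, "x", drop = FALSE], co$time, co$event, g,
               hidden = 3L, epochs = 10, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  newx <- data.frame(x = c(0, 1))
  expect_equal(predict(back, newx, type = "conditional"),
               predict(fit, newx, type = "conditional"))
  expect_equal(back$grid$boundaries, g$boundaries)
  expect_equal(back$config$seed, 4L)
})
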