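test_that("flexible head computes sigmoid(hidden . kernel + bias)", {
  p <- flexible_head(matrix(0, 1, 2), matrix(1, 2, 3), rep(0, 3))
  expect_equal(as.vector(p), rep(0.5, 3))
  # saturation is clipped just inside (0, 1)
  p_hi <- flexible_head(matrix(0, 1, 1), matrix(0, 1, 2), c(100, -100))
  expect_equal(as.vector(p_hi), c(1 - 1e-7, 1e-7))
  expect_equal(as.vector(flexible_head(1, matrix(log(3)), 0)), 0.75)
  expect_error(flexible_head(matrix(0, 1, 3), matrix(1, 2, 2), c(0, 0)),
               "does not match")
  expect_error(flexible_head(matrix(0, 1, 2), matrix(1, 2, 2), 0), "bias")
})

test_that("proportional-hazards head powers baseline survival by exp(xbeta)", {
  bl <- c(-0.3, 0.2, 1)
  expect_equal(as.vector(ph_head(0, bl)), as.vector(1 / (1 + exp(-bl))))
  # baseline conditional survival 0.5, xbeta = ln 2: 0.5^2 = 0.25
  expect_equal(as.vector(ph_head(log(2), 0)), 0.25)
  # xbeta -> -inf: exponent -> 0, survival -> 1 (up to clipping)
  expect_equal(as.vector(ph_head(-50, bl)), rep(1 - 1e-7, 3))
})

test_that("ph head satisfies the proportional-hazards log-survival ratio", {
  set.seed(9)
  bl <- rnorm(6)
  for (rep in 1:10) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    ratio <- log(ph_head(a, bl)) / log(ph_head(b, bl))
    expect_equal(as.vector(ratio), rep(exp(a - b), 6), tolerance = 1e-6)
  }
})

test_that("likelihood loss reproduces hand-computed cases", {
  g1 <- time_grid(10)
  enc_f <- encode_survival(5, 1, g1)
  expect_equal(nll_loss(enc_f, matrix(0.5)), -log(0.5))
  g2 <- time_grid(c(10, 20))
  enc_c <- encode_survival(25, 0, g2)
  expect_equal(nll_loss(enc_c, matrix(c(0.8, 0.9), 1)), -(log(0.8) + log(0.9)))
  # all-zero encoding (early censoring) contributes nothing
  enc_0 <- suppressWarnings(encode_survival(1, 0, g2))
  expect_equal(nll_loss(enc_0, matrix(c(0.3, 0.3), 1)), 0)
  expect_error(nll_loss(enc_c, matrix(0.5)), "does not match")
  # mean reduction divides by the batch size only
  enc2 <- encode_survival(c(25, 25), c(0, 0), g2)
  p2 <- matrix(c(0.8, 0.9), 2, 2, byrow = TRUE)
  expect_equal(nll_loss(enc2, p2, reduction = "mean"),
               nll_loss(enc2, p2) / 2)
})

test_that("vectorised loss equals the per-individual log likelihood", {
  set.seed(77)
  for (rep in 1:20) {
    n_int <- sample(2:7, 1)
    b <- sort(runif(n_int, 5, 400))
    g <- time_grid(b)
    n <- 30
    time <- runif(n, 0, max(b) * 0.99)
    event <- rbinom(n, 1, 0.6)
    pred <- matrix(runif(n * n_int, 0.05, 0.95), n, n_int)
    enc <- suppressWarnings(encode_survival(time, event, g))
    expect_equal(nll_loss(enc, pred), -oracle_loglik(time, event, b, pred),
                 tolerance = 1e-10)
  }
})

test_that("loss gradient w.r.t. predictions matches central differences", {
  set.seed(31)
  g <- time_grid(c(30, 90, 180))
  time <- runif(12, 0, 175); event <- rbinom(12, 1, 0.5)
  enc <- suppressWarnings(encode_survival(time, event, g))
  pred <- matrix(runif(12 * 3, 0.1, 0.9), 12, 3)
  an <- dtsurv:::nll_loss_grad(enc, pred)
  h <- 1e-6
  num <- matrix(0, 12, 3)
  for (k in seq_along(pred)) {
    up <- pred; up[k] <- up[k] + h
    dn <- pred; dn[k] <- dn[k] - h
    num[k] <- (nll_loss(enc, up) - nll_loss(enc, dn)) / (2 * h)
  }
  expect_equal(an, num, tolerance = 1e-5)
})

test_that("squared-error loss matches its definition and null minimiser", {
  g <- time_grid(10)
  # failure interval with hazard 1 (surv_pred 0) costs nothing
  expect_equal(brown_loss(encode_survival(5, 1, g), matrix(1e-12)), 0,
               tolerance = 1e-12)
  # failure interval with hazard 0.5 costs (1 - 0.5)^2 / 2
  expect_equal(brown_loss(encode_survival(5, 1, g), matrix(0.5)), 0.125)
  # null model: minimiser over a common hazard is the life-table d/r
  d <- 7; r <- 25
  enc <- encode_survival(c(rep(5, d), rep(15, r - d)),
                         c(rep(1, d), rep(0, r - d)), g)
  opt <- optimize(function(h) brown_loss(enc, matrix(1 - h, r, 1)), c(0, 1))
  expect_equal(opt$minimum, d / r, tolerance = 1e-5)
})

test_that("survival curves are cumulative products, monotone non-increasing", {
  g <- time_grid(c(10, 20))
  expect_equal(as.vector(survival_curve(c(0.9, 0.8), g)$S), c(0.9, 0.72))
  expect_equal(as.vector(survival_curve(c(1, 1), g)$S), c(1, 1))
  expect_equal(as.vector(survival_curve(0.5, time_grid(10))$S), 0.5)
  set.seed(8)
  for (rep in 1:10) {
    p <- matrix(runif(5 * 6, 0.01, 0.999), 5, 6)
    S <- survival_curve(p, time_grid(1:6))$S
    expect_true(all(diff(t(S)) <= 0))
    expect_true(all(S > 0 & S <= 1))
  }
})

test_that("survival_at interpolates linearly and refuses extrapolation", {
  cv <- survival_curve(c(0.8, 0.625), time_grid(c(10, 30)))  # S = 0.8, 0.5
  expect_equal(survival_at(cv, 0), 1)
  expect_equal(survival_at(cv, c(10, 30)), c(0.8, 0.5))  # knots exact
  expect_equal(survival_at(survival_curve(0.8, time_grid(10)), 5), 0.9)
  expect_equal(survival_at(cv, 20), 0.65)
  expect_error(survival_at(cv, 31), "past the end")
  # step mode reads the right-continuous step function
  expect_equal(survival_at(cv, c(5, 10, 20), mode = "step"), c(1, 0.8, 0.8))
})
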