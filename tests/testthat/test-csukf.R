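test_that("sigma points match the hand-evaluated unscented transform", {
  # n = 1, alpha = 1, beta = 0, kappa = 2: lambda = 2, gamma = sqrt(3)
  sp <- make_sigma_points(0, matrix(1), alpha = 1, beta = 0, kappa = 2)
  expect_equal(as.numeric(sp$points), c(0, sqrt(3), -sqrt(3)))
  expect_equal(sp$wm, c(2 / 3, 1 / 6, 1 / 6))
  expect_equal(sum(sp$wm), 1)

  # box constraint pulls the infeasible point back to the boundary
  spc <- make_sigma_points(0.5, matrix(1), lower = 0, upper = Inf,
                           alpha = 1, beta = 0, kappa = 2)
  expect_equal(min(spc$points), 0)
  expect_equal(sum(spc$wm), 1)

  # weights sum to one with active constraints in higher dimension
  sp3 <- make_sigma_points(c(0.1, 0.2, 5), diag(c(1, 1, 1)),
                           lower = rep(0, 3), upper = rep(10, 3))
  expect_equal(sum(sp3$wm), 1)
  expect_true(all(sp3$points >= -1e-12))

  expect_error(make_sigma_points(-1, matrix(1), lower = 0, upper = 1),
               "violates")
})

test_that("rank-one Cholesky update agrees with direct factorization", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    L <- t(chol(crossprod(matrix(rnorm(n * n), n)) + diag(n)))
    x <- rnorm(n)
    up <- chol_update(L, x, 0.7)
    expect_equal(tcrossprod(up), tcrossprod(L) + 0.7 * tcrossprod(x),
                 tolerance = 1e-10)
    dn <- chol_update(L, 0.2 * x, -1)
    expect_equal(tcrossprod(dn),
                 tcrossprod(L) - 0.04 * tcrossprod(x),
                 tolerance = 1e-10)
  }
  L <- diag(2)
  expect_error(chol_update(L, c(2, 0), -1), "positive definiteness")
})

test_that("prediction and update reproduce the analytic Kalman filter", {
  ls <- linear_system()
  dt <- 0.5
  Ad <- ls$expm(dt)
  Q <- diag(c(0.01, 0.02))
  R <- diag(c(0.04, 0.09))
  lay <- augmented_layout(ls$model)
  set.seed(7)
  x <- c(1, 0.5)
  ys <- matrix(NA, 50, 2)
  for (k in 1:50) {
    x <- as.numeric(Ad %*% x) + as.numeric(t(chol(Q)) %*% rnorm(2))
    ys[k, ] <- x + as.numeric(t(chol(R)) %*% rnorm(2))
  }
  st <- filter_state(c(1, 0.5), diag(0.1, 2), t(chol(Q)),
                     lower = rep(-Inf, 2), upper = rep(Inf, 2))
  m <- c(1, 0.5); P <- diag(0.01, 2)
  ctl <- list(integrator = "lsoda", rtol = 1e-11, atol = 1e-12)
  worst <- 0
  tprev <- 0
  for (k in 1:50) {
    tk <- k * dt
    st <- csukf_predict(st, ls$model, lay, tprev, tk, ctl)
    oracle_pred <- list(m = as.numeric(Ad %*% m),
                        P = Ad %*% P %*% t(Ad) + Q)
    up <- csukf_update(st, ys[k, ], R, ls$model, lay, tk)
    st <- up$state
    o <- kf_oracle_step(m, P, Ad, Q, R, ys[k, ])
    m <- o$m; P <- o$P
    worst <- max(worst, abs(st$mean - m), abs(tcrossprod(st$S) - P))
    tprev <- tk
  }
  expect_lt(worst, 1e-6)
})

test_that("degenerate prediction and update limits behave", {
  const <- build_fixture_model("constant")
  lay <- augmented_layout(const)
  st <- filter_state(c(1, 2), diag(0.3, 2), matrix(0, 2, 2),
                     lower = rep(-Inf, 2), upper = rep(Inf, 2))
  pr <- csukf_predict(st, const, lay, 0, 1)
  expect_equal(pr$mean, st$mean)
  expect_equal(tcrossprod(pr$S), tcrossprod(st$S), tolerance = 1e-10)

  # huge R: posterior ~ prior (zero-gain limit)
  up <- csukf_update(pr, c(50, -10), diag(1e12, 2), const, lay, 1)
  expect_equal(up$state$mean, pr$mean, tolerance = 1e-6)

  # parameter block of the predicted mean is untouched by dynamics
  dec <- decay_model()
  lay2 <- augmented_layout(dec)
  st2 <- filter_state(c(1, 0.5), diag(c(0.1, 0), 2) + diag(1e-9, 2),
                      diag(0, 2), lower = rep(-Inf, 2),
                      upper = rep(Inf, 2))
  pr2 <- csukf_predict(st2, dec, lay2, 0, 0.3)
  expect_equal(pr2$mean[2], 0.5, tolerance = 1e-9)
})

test_that("posterior means respect tight random box constraints", {
  const <- build_fixture_model("constant")
  lay <- augmented_layout(const)
  set.seed(21)
  for (i in 1:15) {
    lo <- runif(2, 0, 0.5)
    hi <- lo + runif(2, 0.2, 1)
    m0 <- runif(2, lo, hi)
    st <- filter_state(m0, diag(0.4, 2), diag(1e-3, 2), lo, hi)
    st <- csukf_predict(st, const, lay, 0, 1)
    up <- csukf_update(st, runif(2, -2, 2), diag(0.01, 2), const, lay, 1)
    expect_true(all(up$state$mean >= lo - 1e-12 &
                      up$state$mean <= hi + 1e-12))
    sp <- make_sigma_points(up$state$mean, up$state$S, lo, hi)
    expect_true(all(sp$points >= lo - 1e-9 & sp$points <= hi + 1e-9))
  }
})

test_that("chi-square merit matches hand and brute-force evaluation", {
  expect_equal(merit_chi2(matrix(0, 5, 2), diag(2)), 0)
  expect_equal(merit_chi2(matrix(2, 1, 1), matrix(4)), 1)
  set.seed(5)
  E <- matrix(rnorm(30), 10, 3)
  R <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  brute <- 0
  Ri <- solve(R)
  for (k in 1:10) for (i in 1:3) for (j in 1:3)
    brute <- brute + E[k, i] * Ri[i, j] * E[k, j]
  expect_equal(merit_chi2(E, R), brute, tolerance = 1e-10)
  expect_error(merit_chi2(matrix(1, 2, 1), matrix(0)), "singular")
})

test_that("estimation is a fixed point at the truth and merit is consistent", {
  dec <- decay_model()
  clean <- simulate(dec, times = seq(0.5, 6, 0.5), theta = c(k = 0.5))
  fit <- csukf(dec, clean, theta0 = c(k = 0.5), R = 1e-4, passes = 3,
               control = list(param_sd = 1e-4, q_param = 1e-6))
  expect_equal(coef(fit)[["k"]], 0.5, tolerance = 0.01)
  expect_equal(fit$merit, merit_chi2(fit$residuals, fit$R_list),
               tolerance = 1e-8)
})

test_that("only the product is recovered for the structurally deficient model", {
  seeds <- 1:12
  prods <- th1s <- numeric(0)
  for (s in seeds) {
    fx <- make_fixture(fixture_spec("product_ni", seed = s))
    fit <- csukf(fx$model, fx$noisy, seed = s, passes = 14)
    prods <- c(prods, prod(coef(fit)))
    th1s <- c(th1s, coef(fit)[["th1"]])
  }
  expect_lt(abs(median(prods) - 0.3) / 0.3, 0.05)
  # individual parameters scatter along the ridge (the Uniform(0,1)
  # starts project onto the hyperbola, keeping a wide spread)
  expect_gt(sd(th1s) / mean(th1s), 0.3)
})

test_that("square-root factor stays positive definite along a fit", {
  fx <- make_fixture(fixture_spec("mm_chain",
                                  grid = seq(2, 40, 2), seed = 4))
  fit <- csukf(fx$model, fx$noisy, seed = 4, passes = 3)
  expect_true(all(diag(fit$S) > 0))
  P <- tcrossprod(fit$S)
  expect_true(all(eigen(P, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_equal(P, t(P), tolerance = 1e-12)
})

test_that("fit object methods are coherent", {
  fx <- make_fixture(fixture_spec("product_ni", seed = 2))
  fit <- csukf(fx$model, fx$noisy, seed = 2, passes = 4)
  expect_named(coef(fit), c("th1", "th2"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_equal(nrow(residuals(fit)), nrow(fx$noisy))
  pred <- predict(fit)
  expect_s3_class(pred, "kf_series")
  expect_output(print(fit), "CSUKF fit")
  expect_output(print(summary(fit)), "chi-square merit")
  sim <- simulate(fit, seed = 1)
  expect_equal(nrow(sim), nrow(fx$noisy))
})
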