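test_that("chi-square thresholds reproduce the reference quantiles", {
  expect_equal(chi2_threshold(0.95, 1), 3.84, tolerance = 5e-3)
  expect_equal(chi2_threshold(0.95, 12), 21.03, tolerance = 5e-3)
  # independent quantile route: chi-square(df) = Gamma(df/2, scale 2)
  for (df in c(1, 3, 12)) {
    expect_equal(chi2_threshold(0.95, df),
                 stats::qgamma(0.95, df / 2, scale = 2),
                 tolerance = 1e-9)
  }
  expect_lt(chi2_threshold(1e-12, 4), 1e-5)   # degenerate quantile
  expect_error(chi2_threshold(1.2, 1), "alpha")
  expect_error(chi2_threshold(0.95, 0), "df")
})

test_that("the Gaussian-mean profile is the analytic parabola", {
  toy <- gaussian_mean_toy()
  fit <- csukf(toy$model, toy$series, R = toy$sigma^2, seed = 3,
               passes = 10)
  tr <- profile_parameter(fit, "mu")
  expect_equal(tr$class, "identifiable")
  n <- length(toy$ys)
  ci_expect <- mean(toy$ys) +
    c(-1, 1) * sqrt(3.841459) * toy$sigma / sqrt(n)
  width <- diff(ci_expect)
  expect_lt(abs(tr$ci[["lower"]] - ci_expect[1]) / width, 0.02)
  expect_lt(abs(tr$ci[["upper"]] - ci_expect[2]) / width, 0.02)

  # at psi = theta-hat the recorded point equals the fit objective
  centre <- tr$points[tr$points$direction == 0, ]
  expect_equal(centre$chi2_raw, chi2_objective(fit), tolerance = 1e-9)

  # delta chi2 at the first step in each direction is non-negative
  expect_true(all(tr$points$chi2 >= tr$chi2_min - 1e-6))
})

test_that("classification rules follow the crossing pattern", {
  mk <- function(psi, chi2, side) {
    structure(list(points = data.frame(psi = psi, chi2 = chi2,
                                       direction = side, side = side),
                   chi2_min = 0, threshold_pointwise = 3.84,
                   flat_eps = 0.5, flat_decades = 2),
              class = "profile_traj")
  }
  both <- mk(c(0.5, 1, 2), c(5, 0, 5), c(-1, 0, 1))
  expect_equal(classify_profile(both), "identifiable")
  onesided <- mk(c(0.5, 1, 2), c(0.1, 0, 5), c(-1, 0, 1))
  expect_equal(classify_profile(onesided), "practical")
  flat <- mk(c(0.01, 1, 100), c(0.05, 0, 0.08), c(-1, 0, 1))
  expect_equal(classify_profile(flat), "structural")
  slow <- mk(c(0.01, 1, 100), c(2, 0, 2.5), c(-1, 0, 1))
  expect_equal(classify_profile(slow), "practical")
  expect_error(classify_profile(mk(numeric(0), numeric(0), numeric(0))),
               "empty")
})

test_that("the product model profiles flat over two decades", {
  fx <- make_fixture(fixture_spec("product_ni", seed = 1))
  fit <- csukf(fx$model, fx$noisy, seed = 1)
  tr <- profile_parameter(fit, "th1")
  expect_equal(tr$class, "structural")
  ok <- !tr$points$nuisance_at_bound
  span <- log10(max(tr$points$psi[ok]) / min(tr$points$psi[ok]))
  expect_gt(span, 2)
  expect_lt(max(tr$points$chi2[ok]) - tr$chi2_min, 0.5)
  expect_true(all(is.infinite(tr$ci)))
})

test_that("simultaneous-threshold intervals contain pointwise intervals", {
  toy <- gaussian_mean_toy(seed = 8)
  fit <- csukf(toy$model, toy$series, R = toy$sigma^2, seed = 8,
               passes = 8)
  tr <- profile_parameter(fit, "mu")
  wide <- tr
  wide$threshold_pointwise <- tr$threshold_simultaneous
  ci_wide <- kfident:::profile_ci(wide)
  expect_lte(ci_wide[["lower"]], tr$ci[["lower"]])
  expect_gte(ci_wide[["upper"]], tr$ci[["upper"]])
})

test_that("classification is recomputable from the stored trajectory", {
  fx <- make_fixture(fixture_spec("product_ni", seed = 2))
  fit <- csukf(fx$model, fx$noisy, seed = 2)
  ident <- run_identifiability(fit)
  for (p in names(ident$trajectories)) {
    expect_equal(classify_profile(ident$trajectories[[p]]),
                 ident$summary$class[ident$summary$parameter == p])
  }
  expect_output(print(ident), "identifiability")
})

test_that("trajectory variability locates informative measurements", {
  fx <- make_fixture(fixture_spec("product_ni", seed = 1))
  fit <- csukf(fx$model, fx$noisy, seed = 1)
  tr <- profile_parameter(fit, "th1")
  tv <- trajectory_variability(fit, tr)
  # the full profile keeps the product constant, so the envelope is
  # within the optimizer tolerance, far below the parameter spread
  expect_lt(max(tv$width), 0.2)
  expect_equal(tv$suggestion$state, "x")

  # zero-length profile (single point) has zero envelope
  tr1 <- tr
  tr1$eta <- tr$eta[1]
  tv1 <- trajectory_variability(fit, tr1)
  expect_equal(max(tv1$width), 0)
})
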