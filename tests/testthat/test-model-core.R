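test_that("simulate handles trivial and closed-form systems", {
  const <- build_fixture_model("constant")
  s <- simulate(const, times = 1:5,
                theta = stats::setNames(numeric(0), character(0)))
  expect_equal(unname(as.matrix(s[, c("A", "B")])),
               matrix(rep(c(1, 2), each = 5), 5))

  dec <- decay_model()
  s2 <- simulate(dec, times = c(1, 2), theta = c(k = 0.5))
  expect_equal(s2$A, exp(-0.5 * c(1, 2)), tolerance = 1e-7)

  # deterministic for fixed inputs
  s3 <- simulate(dec, times = c(1, 2), theta = c(k = 0.5))
  expect_identical(s2$A, s3$A)

  expect_error(simulate(dec, times = c(2, 1), theta = c(k = 0.5)),
               "strictly increasing")
})

test_that("the reference long grid yields 234 measurement samples", {
  grid <- seq(10, 2340, by = 10)
  expect_length(grid, 234)
  dec <- decay_model()
  s <- simulate(dec, times = grid, theta = c(k = 1e-3))
  expect_equal(nrow(s), 234)
})

test_that("integrator tolerances are converged on the fixtures", {
  m <- build_fixture_model("mm_chain")
  t <- seq(1, 40, 2)
  a <- simulate(m, times = t, control = list(rtol = 1e-8, atol = 1e-10))
  b <- simulate(m, times = t, control = list(rtol = 5e-9, atol = 5e-11))
  expect_lt(max(abs(series_values(a) - series_values(b))), 1e-7)
})

test_that("noise models match their defining formulas and clamp at zero", {
  ser <- kf_series(1:4, matrix(1, 4, 1), "y")
  expect_identical(series_values(apply_noise(ser, noise_model("none"))),
                   series_values(ser))

  zero <- kf_series(1:4, matrix(0, 4, 1), "y")
  out0 <- apply_noise(zero, noise_model("multiplicative"), seed = 9)
  expect_true(all(series_values(out0) == 0))

  # seeded draws reproduce max(0, 1 + 0.2 r_k) for the same stream
  set.seed(42)
  r <- stats::rnorm(4)
  expect_equal(as.numeric(series_values(
    apply_noise(ser, noise_model("multiplicative"), seed = 42))),
    pmax(0, 1 + 0.2 * r))

  # mixed model: y + 0.1 r1 + 0.2 r2 y with independent streams
  set.seed(7)
  r1 <- stats::rnorm(4); r2 <- stats::rnorm(4)
  expect_equal(as.numeric(series_values(
    apply_noise(ser, noise_model("mixed"), seed = 7))),
    pmax(0, 1 + 0.1 * r1 + 0.2 * r2 * 1))

  # clamp property over seeds, including signals near zero
  small <- kf_series(1:20, matrix(0.01, 20, 2), c("a", "b"))
  for (s in 1:25) {
    expect_true(all(series_values(
      apply_noise(small, noise_model("mixed"), seed = s)) >= 0))
    expect_true(all(series_values(
      apply_noise(small, noise_model("multiplicative"), seed = s)) >= 0))
  }
})

test_that("discretize advances states and never touches parameters", {
  const <- build_fixture_model("constant")
  lay <- augmented_layout(const)
  x <- c(1, 2)
  expect_equal(discretize(const, lay, x, 0, 5), x)

  dec <- decay_model()
  lay2 <- augmented_layout(dec)
  out <- discretize(dec, lay2, c(1, 1), 0, 0.1,
                    control = list(integrator = "lsoda"))
  expect_equal(out[1], exp(-0.1), tolerance = 1e-8)
  expect_identical(out[2], 1)     # parameter block bit-identical

  # parameter invariance for a batch of sigma-point-like columns
  X <- rbind(x = c(1, 2, 0.5), k = c(0.3, 0.7, 1.2))
  out2 <- discretize(dec, lay2, X, 0, 0.5)
  expect_identical(out2[2, ], X[2, ])
  expect_error(discretize(dec, lay2, c(1, 1), 1, 1), "exceed")
})

test_that("time-series container validates and round-trips CSV", {
  expect_error(kf_series(c(1, 1, 2), matrix(0, 3, 1), "y"),
               "strictly increasing")
  expect_error(kf_series(1:2, matrix(c(1, NA), 2, 1), "y"), "finite")
  s <- kf_series(1:3, cbind(a = 1:3 / 7, b = 3:1 / 7), c("a", "b"))
  p <- tempfile(fileext = ".csv")
  write_series(s, p)
  s2 <- read_series(p)
  expect_equal(s2$a, s$a)
  expect_equal(s2$time, s$time)
  unlink(p)
})
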