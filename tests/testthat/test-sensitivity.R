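test_that("scaled sensitivities reproduce analytic cancellations", {
  # x(t) = theta t observed directly: (dx/dtheta)(theta/x) = 1
  lin <- kinetic_model("lin", function(x, theta, t) c(theta[["a"]]),
                       "x", "a", c(x = 0), theta_true = c(a = 2))
  Z <- sensitivity_matrix(lin, c(a = 2), times = 1:5)
  expect_equal(as.numeric(Z$Z), rep(1, 5), tolerance = 1e-5)

  # x = exp(-k t): scaled sensitivity is -k t
  dec <- decay_model()
  Z2 <- sensitivity_matrix(dec, c(k = 0.5), times = c(1, 2, 4))
  expect_equal(as.numeric(Z2$Z), -0.5 * c(1, 2, 4), tolerance = 1e-5)
})

test_that("finite differences match the forward sensitivity ODE", {
  # independent oracle: integrate the sensitivity equations
  # dS/dt = J_x S + J_theta for the Michaelis-Menten chain
  m <- build_fixture_model("mm_chain")
  th <- m$theta_true
  times <- seq(2, 30, 2)
  rhs_ext <- function(t, y, parms) {
    S <- y[1]
    sens <- matrix(y[3:6], 2)  # d(S,P)/d(Vmax,Km)
    den <- th[["Km"]] + S
    v <- th[["Vmax"]] * S / den
    dv_dS <- th[["Vmax"]] * th[["Km"]] / den^2
    dv_dVmax <- S / den
    dv_dKm <- -th[["Vmax"]] * S / den^2
    dsens <- rbind(-dv_dS * sens[1, ] - c(dv_dVmax, dv_dKm),
                   dv_dS * sens[1, ] + c(dv_dVmax, dv_dKm))
    list(c(-v, v, as.numeric(dsens)))
  }
  sol <- deSolve::ode(c(m$x0, rep(0, 4)), c(0, times), rhs_ext, NULL,
                      rtol = 1e-10, atol = 1e-12)
  oracle_raw <- sol[-1, 4:7]  # columns: dS/dV, dP/dV, dS/dK, dP/dK
  Z <- sensitivity_matrix(m, th, times)
  raw <- Z$Z_raw   # rows: (times x S, times x P)
  nt <- length(times)
  expect_equal(unname(raw[1:nt, "Vmax"]), unname(oracle_raw[, 1]),
               tolerance = 1e-4)
  expect_equal(unname(raw[nt + 1:nt, "Vmax"]), unname(oracle_raw[, 2]),
               tolerance = 1e-4)
  expect_equal(unname(raw[1:nt, "Km"]), unname(oracle_raw[, 3]),
               tolerance = 1e-4)
})

test_that("scaling makes columns invariant to parameter units", {
  dec <- decay_model()
  Z1 <- sensitivity_matrix(dec, c(k = 0.5), times = 1:5)
  dec10 <- kinetic_model("dec10",
                         rhs = function(x, theta, t)
                           c(-theta[["k"]] / 10 * x[["A"]]),
                         state_names = "A", param_names = "k",
                         x0 = c(A = 1))
  Z2 <- sensitivity_matrix(dec10, c(k = 5), times = 1:5)
  expect_equal(Z1$Z, Z2$Z, tolerance = 1e-4)
})

test_that("orthogonal ranking follows norms, collinearity and threshold", {
  # orthogonal columns rank by descending norm
  M <- cbind(a = c(3, 0, 0), b = c(0, 2, 0), c = c(0, 0, 1))
  r <- rank_parameters(M, threshold = 0)
  expect_equal(r$ranked, c("a", "b", "c"))

  # perfect collinearity: the twin column is unranked
  M2 <- cbind(a = c(10, 0), b = c(10, 0))
  r2 <- rank_parameters(M2, threshold = 0.004)
  expect_length(r2$ranked, 1)
  expect_length(r2$unranked, 1)

  # residual norms at accepted steps are >= threshold
  expect_true(all(r2$residual_norms >= 0.004))

  # greedy equals brute-force greedy with explicit projections (p <= 5)
  set.seed(9)
  M3 <- matrix(rnorm(40 * 4), 40)
  colnames(M3) <- letters[1:4]
  r3 <- rank_parameters(M3, threshold = 0)
  brute <- character(0)
  rem <- colnames(M3)
  while (length(rem)) {
    rn <- sapply(rem, function(p) {
      if (!length(brute)) return(sqrt(sum(M3[, p]^2)))
      q <- qr(M3[, brute, drop = FALSE])
      sqrt(sum(qr.resid(q, M3[, p])^2))
    })
    brute <- c(brute, rem[which.max(rn)])
    rem <- setdiff(rem, brute)
  }
  expect_equal(r3$ranked, brute)
})

test_that("a planted low-rank sensitivity matrix leaves the dependent columns unranked", {
  # 12 columns, 3 of which are near-linear combinations of the others
  set.seed(2)
  B <- matrix(rnorm(200 * 9), 200)
  C <- B %*% matrix(rnorm(27), 9) * 0.5
  M <- cbind(B, C + 1e-5 * rnorm(length(C)))
  colnames(M) <- sprintf("p%02d", 1:12)
  r <- rank_parameters(M, threshold = 0.004)
  # the matrix has numerical rank 9, so exactly three columns are left
  # unranked (which three depends on the greedy selection order)
  expect_length(r$ranked, 9)
  expect_length(r$unranked, 3)
})

test_that("rankings aggregate by average position with majority unranking", {
  r1 <- structure(list(ranked = c("a", "b"), residual_norms = c(2, 1),
                       unranked = "c", threshold = 0.004),
                  class = "ranking")
  expect_equal(aggregate_rankings(list(r1, r1))$ranked, c("a", "b"))

  r2 <- structure(list(ranked = c("b", "a"), residual_norms = c(2, 1),
                       unranked = "c", threshold = 0.004),
                  class = "ranking")
  agg <- aggregate_rankings(list(r1, r2))
  expect_equal(agg$ranked, c("a", "b"))   # tie broken lexicographically
  expect_equal(agg$unranked, "c")

  # unranked in 30 of 50 runs stays unranked; in 20 of 50 it is ranked
  rk_with <- structure(list(ranked = c("a", "c"), residual_norms = c(2, 1),
                            unranked = "b", threshold = 0.004),
                       class = "ranking")
  runs <- c(rep(list(r1), 30), rep(list(rk_with), 20))
  expect_true("c" %in% aggregate_rankings(runs)$unranked)
  runs2 <- c(rep(list(r1), 20), rep(list(rk_with), 30))
  expect_false("c" %in% aggregate_rankings(runs2)$unranked)

  expect_error(aggregate_rankings(list()), "empty")
})

test_that("ranking is deterministic", {
  set.seed(3)
  M <- matrix(rnorm(60), 20)
  colnames(M) <- c("x", "y", "z")
  expect_identical(rank_parameters(M), rank_parameters(M))
})
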