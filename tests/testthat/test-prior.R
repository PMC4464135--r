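test_that("rank-based priors follow the geometric schedule", {
  dec2 <- build_fixture_model("product_ni")
  rk <- structure(list(ranked = c("th1", "th2"),
                       residual_norms = c(2, 1), unranked = character(0),
                       threshold = 0.004), class = "ranking")
  pr <- prior_from_ranking(rk, dec2, nominal = c(th1 = 0.5, th2 = 0.5),
                           sigma = c(0.01, 1), perturb = 0)
  sds <- diag(pr$sqrt_V0)
  expect_equal(unname(sds[2:3]), c(0.01, 1))

  rk3 <- structure(list(ranked = c("a", "b", "c"),
                        residual_norms = 3:1, unranked = character(0),
                        threshold = 0.004), class = "ranking")
  m3 <- kinetic_model("m3", function(x, theta, t) c(0), "x",
                      c("a", "b", "c"), c(x = 1))
  pr3 <- prior_from_ranking(rk3, m3, nominal = c(a = 1, b = 1, c = 1),
                            sigma = c(0.01, 1), perturb = 0)
  expect_equal(diag(pr3$sqrt_V0)[3], sqrt(0.01 * 1))  # geometric middle

  # unranked parameters take sigma_max
  rk_u <- structure(list(ranked = "a", residual_norms = 2,
                         unranked = c("b", "c"), threshold = 0.004),
                    class = "ranking")
  pr_u <- prior_from_ranking(rk_u, m3, nominal = c(a = 1, b = 1, c = 1),
                             sigma = c(0.01, 1), perturb = 0)
  expect_equal(unname(diag(pr_u$sqrt_V0)[3:4]), c(1, 1))

  # prior std is non-decreasing in rank number
  expect_true(all(diff(diag(pr3$sqrt_V0)[-1]) >= 0))
  expect_error(prior_from_ranking(rk, dec2, c(th1 = 1, th2 = 1),
                                  sigma = c(1, 0.1)), "sigma_min")
})

test_that("phase carry-over preserves the previous posterior", {
  fx <- make_fixture(fixture_spec("product_ni", seed = 3))
  fit <- csukf(fx$model, fx$noisy, seed = 3, passes = 4)
  pr <- prior_from_phase(fit, perturb = 0)
  expect_equal(pr$mean0[fit$layout$param_idx],
               fit$mean[fit$layout$param_idx])
  expect_equal(tcrossprod(pr$sqrt_V0), tcrossprod(fit$S),
               tolerance = 1e-12)

  pr2 <- prior_from_phase(fit, perturb = 0.05, seed = 1)
  ratio <- pr2$mean0[fit$layout$param_idx] /
    fit$mean[fit$layout$param_idx]
  expect_true(all(ratio >= 0.95 & ratio <= 1.05))
})

test_that("uninformed priors draw within the documented ranges", {
  m <- build_fixture_model("mm_chain")
  pr <- uninformed_prior(m, seed = 10)
  v <- diag(pr$sqrt_V0)^2
  q <- diag(pr$sqrt_Q0)^2
  expect_true(all(v >= 0.001 & v <= 0.1))
  expect_true(all(q >= 0.001 & q <= 0.1))
  th <- pr$mean0[3:4]
  expect_true(all(th >= 0 & th <= 1))
  expect_equal(uninformed_prior(m, seed = 10)$mean0, pr$mean0)
  expect_false(identical(uninformed_prior(m, seed = 11)$mean0, pr$mean0))
})

test_that("prior YAML round trip preserves the specification", {
  m <- build_fixture_model("product_ni")
  pr <- uninformed_prior(m, seed = 2)
  p <- tempfile(fileext = ".yaml")
  write_prior(pr, p)
  pr2 <- read_prior(p)
  expect_equal(pr2$mean0, as.numeric(pr$mean0))
  expect_equal(pr2$sqrt_V0, pr$sqrt_V0, ignore_attr = TRUE)
  expect_equal(pr2$provenance, "uninformed")
  unlink(p)
})

test_that("two-phase informed estimation tightens the gene-network parameters", {
  # two-condition procedure: rank-informed phase on the mutant data,
  # then the wild type warm-started from that posterior, contrasted
  # with single-phase uninformed runs on the wild-type data alone
  bundles <- generate_experiment2(seed = 1)
  seeds <- 1:6
  est <- c("pro1", "pro2", "rbs1", "rbs2", "p_deg")
  Rf <- function(y) noise_variance(bundles$noise, y)
  wt <- bundles$wild_type
  mu <- bundles$mutant
  single <- lapply(seeds, function(s)
    csukf(wt$model, wt$noisy, estimate = est, R = Rf,
          prior = uninformed_prior(wt$model, est, seed = s),
          seed = s, passes = 6))
  # stage 0 on the mutant data: ranking and nominal values
  stage0 <- lapply(seeds[1:3], function(s)
    csukf(mu$model, mu$noisy, estimate = est, R = Rf,
          prior = uninformed_prior(mu$model, est, seed = s),
          seed = s, passes = 6))
  ranking <- aggregate_rankings(lapply(stage0, function(f)
    suppressWarnings(rank_parameters(
      sensitivity_matrix(mu$model, coef(f), mu$noisy$time,
                         params = est)))))
  nominal <- apply(do.call(rbind, lapply(stage0, coef)), 2, median)
  two <- lapply(seeds, function(s) {
    ph1 <- csukf(mu$model, mu$noisy, estimate = est, R = Rf,
                 prior = prior_from_ranking(ranking, mu$model, nominal,
                                            seed = s, estimate = est),
                 seed = s, passes = 6)
    csukf(wt$model, wt$noisy, estimate = est, R = Rf,
          prior = prior_from_phase(ph1, seed = s), seed = s, passes = 6)
  })
  sd_single <- apply(do.call(rbind, lapply(single, coef)), 2, sd)
  sd_two <- apply(do.call(rbind, lapply(two, coef)), 2, sd)
  expect_gte(mean(sd_two < sd_single), 0.8)
})
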