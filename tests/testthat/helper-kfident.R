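# Shared helpers: small models and closed-form oracles used across the
# test files. Everything is generated in code; no fixture files.

# scalar exponential-decay model (closed form x = x0 * exp(-k t))
decay_model <- function() {
  kinetic_model("decay",
                rhs = function(x, theta, t) c(-theta[["k"]] * x[["A"]]),
                state_names = "A", param_names = "k", x0 = c(A = 1),
                theta_true = c(k = 0.5))
}

# 2-state linear system dx = A x with exact discrete transition by
# eigendecomposition (independent of the package's integrators)
linear_system <- function() {
  A <- matrix(c(-0.3, 0.1, 0.05, -0.2), 2, 2)
  model <- kinetic_model("lin2",
                         rhs = function(x, theta, t) as.numeric(A %*% x),
                         state_names = c("x1", "x2"),
                         param_names = character(0),
                         x0 = c(x1 = 1, x2 = 0.5))
  expm <- function(dt) {
    ev <- eigen(A)
    Re(ev$vectors %*% diag(exp(ev$values * dt)) %*% solve(ev$vectors))
  }
  list(model = model, A = A, expm = expm)
}

# textbook Kalman filter for x(k+1) = Ad x(k) + w, y = x + v
kf_oracle_step <- function(m, P, Ad, Q, R, y) {
  m <- as.numeric(Ad %*% m)
  P <- Ad %*% P %*% t(Ad) + Q
  K <- P %*% solve(P + R)
  m <- m + as.numeric(K %*% (y - m))
  P <- (diag(nrow(P)) - K) %*% P
  list(m = m, P = P)
}

# Gaussian-mean toy: y_k = mu + noise, observation map reads the
# parameter directly (profile likelihood has a closed-form parabola)
gaussian_mean_toy <- function(n = 50, mu = 2, sigma = 0.5, seed = 3) {
  model <- kinetic_model("toy", function(x, theta, t) 0, "x", "mu",
                         c(x = 0),
                         observe = function(x, theta, t) theta[["mu"]],
                         obs_names = "y", theta_true = c(mu = mu))
  set.seed(seed)
  ys <- mu + sigma * stats::rnorm(n)
  list(model = model,
       series = kf_series(seq_len(n), matrix(ys, ncol = 1), "y"),
       sigma = sigma, ys = ys)
}
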