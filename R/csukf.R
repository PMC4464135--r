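# Constrained square-root unscented Kalman filter.
#
# The covariance is carried as a lower-triangular Cholesky factor S with
# P = S S'. Prediction propagates sigma points through the discretized
# dynamics and rebuilds the factor by QR of the weighted deviations
# (augmented with sqrt(Q)) plus a rank-one update for the centre weight;
# the measurement update uses QR with sqrt(R) and column-wise downdates.
# Box constraints L <= x <= U are enforced by pulling violating sigma
# points back along their ray from the mean to the nearest feasible
# point, re-weighting in proportion to the applied scaling, and by
# clipping the predicted/posterior means.

#' Rank-one Cholesky update / downdate
#'
#' Returns the lower-triangular factor of `L %*% t(L) + w * x %*% t(x)`.
#' Negative `w` performs a downdate; loss of positive definiteness is an
#' error (never silently patched).
#'
#' @param L lower-triangular matrix with positive diagonal.
#' @param x numeric vector.
#' @param w scalar weight (sign selects update vs downdate).
#' @return updated lower-triangular factor.
#' @export
chol_update <- function(L, x, w) {
  sgn <- if (w < 0) -1 else 1
  x <- sqrt(abs(w)) * as.numeric(x)
  n <- length(x)
  for (k in seq_len(n)) {
    r2 <- L[k, k]^2 + sgn * x[k]^2
    if (r2 <= 0)
      stop("Cholesky downdate lost positive definiteness", call. = FALSE)
    r <- sqrt(r2)
    c_ <- r / L[k, k]
    s_ <- x[k] / L[k, k]
    L[k, k] <- r
    if (k < n) {
      i <- (k + 1):n
      L[i, k] <- (L[i, k] + sgn * s_ * x[i]) / c_
      x[i] <- c_ * x[i] - s_ * L[i, k]
    }
  }
  L
}

# lower-triangular factor from the transposed-QR compound matrix A (rows
# are weighted deviations); returns t(R) with positive diagonal. When
# constraint scaling collapses sigma points (mean on a boundary) the
# factor can lose rank; the diagonal is floored at a tiny fraction of
# its largest entry so positive definiteness is maintained.
sqrt_from_qr <- function(A) {
  R <- qr.R(qr(A))
  d <- sign(diag(R))
  d[d == 0] <- 1
  L <- t(R * d)
  dg <- diag(L)
  floor_ <- max(dg, 0) * 1e-8 + 1e-12
  diag(L) <- pmax(dg, floor_)
  L
}

#' Unscented-transform sigma points with box constraints
#'
#' Builds the `2n+1` sigma points `{x, x +/- sqrt(n+lambda) S e_i}` with
#' the standard scaled-UT weights, then enforces box constraints by
#' scaling each violating point along its ray from the mean to the
#' boundary; the scaled points' mean and covariance weights are
#' multiplied by the scale factor and all weights renormalized so the
#' mean weights again sum to one.
#'
#' @param mean augmented mean vector (must itself satisfy the
#'   constraints).
#' @param S lower-triangular covariance factor with positive diagonal.
#' @param lower,upper box constraints (vectors, `-Inf`/`Inf` allowed).
#' @param alpha,beta,kappa unscented-transform scalars; defaults
#'   `alpha = 1`, `beta = 2`, `kappa = max(0, 3 - n)` (fourth-order
#'   moment matching for Gaussians at small n; kappa floors at 0 for
#'   n > 3 so the centre covariance weight stays non-negative and the
#'   square-root updates remain well defined).
#' @return list with `points` (n x (2n+1) matrix), `wm`, `wc`.
#' @export
make_sigma_points <- function(mean, S, lower = NULL, upper = NULL,
                              alpha = 1, beta = 2, kappa = NULL) {
  n <- length(mean)
  if (any(diag(S) <= 0))
    stop("covariance factor must have positive diagonal", call. = FALSE)
  if (is.null(kappa)) kappa <- max(0, 3 - n)
  if (is.null(lower)) lower <- rep(-Inf, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  if (any(mean < lower - 1e-12) || any(mean > upper + 1e-12))
    stop("mean violates box constraints", call. = FALSE)
  lambda <- alpha^2 * (n + kappa) - n
  if (n + lambda <= 0) stop("invalid UT scaling (n + lambda <= 0)",
                            call. = FALSE)
  gam <- sqrt(n + lambda)
  pts <- cbind(mean, mean + gam * S, mean - gam * S, deparse.level = 0)
  wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + (1 - alpha^2 + beta)
  # ray-scale violating points back into the box
  scl <- rep(1, 2 * n + 1)
  for (j in 2:(2 * n + 1)) {
    d <- pts[, j] - mean
    s <- 1
    bad_lo <- which(pts[, j] < lower)
    if (length(bad_lo))
      s <- min(s, min((lower[bad_lo] - mean[bad_lo]) / d[bad_lo]))
    bad_hi <- which(pts[, j] > upper)
    if (length(bad_hi))
      s <- min(s, min((upper[bad_hi] - mean[bad_hi]) / d[bad_hi]))
    if (s < 1) {
      pts[, j] <- mean + s * d
      scl[j] <- s
    }
  }
  if (any(scl < 1)) {
    # scale the affected weights and renormalize the non-centre block
    # back to its original mass (the centre weight can be negative for
    # n > 3, so it is left untouched and total mass stays 1)
    mass <- sum(wm[-1])
    wm[-1] <- wm[-1] * scl[-1]
    wc[-1] <- wc[-1] * scl[-1]
    norm <- mass / sum(wm[-1])
    wm[-1] <- wm[-1] * norm
    wc[-1] <- wc[-1] * norm
  }
  list(points = pts, wm = wm, wc = wc)
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Initial filter state for the CSUKF
#'
#' @param mean initial augmented mean `[states | estimated parameters]`.
#' @param sqrt_V lower-triangular factor of the initial state-estimation
#'   covariance.
#' @param sqrt_Q lower-triangular factor of the per-step process-noise
#'   covariance.
#' @param lower,upper box constraints over the augmented entries.
#' @param alpha,beta,kappa unscented-transform scalars (see
#'   [make_sigma_points()]).
#' @return object of class `filter_state`.
#' @export
filter_state <- function(mean, sqrt_V, sqrt_Q, lower = NULL, upper = NULL,
                         alpha = 1, beta = 2, kappa = NULL) {
  n <- length(mean)
  if (is.null(lower)) lower <- rep(-Inf, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  if (any(lower > upper)) stop("lower bound exceeds upper", call. = FALSE)
  if (is.null(dim(sqrt_V))) sqrt_V <- diag(sqrt_V, n)
  if (is.null(dim(sqrt_Q))) sqrt_Q <- diag(sqrt_Q, n)
  mean <- clip_box(mean, lower, upper)
  structure(list(mean = mean, S = sqrt_V, sqrt_Q = sqrt_Q,
                 lower = lower, upper = upper,
                 alpha = alpha, beta = beta, kappa = kappa, k = 0L),
            class = "filter_state")
}

#' CSUKF time-update (prediction)
#'
#' Propagates the sigma points through [discretize()] over
#' `[t_k, t_k1]`, forms the predicted mean and rebuilds the square-root
#' factor from the QR of the weighted deviations augmented with
#' `sqrt_Q`, plus a rank-one update/downdate for the centre weight.
#'
#' @param state a [filter_state()].
#' @param model a [kinetic_model()].
#' @param layout an [augmented_layout()].
#' @param t_k,t_k1 interval endpoints; if `t_k1 == t_k` the dynamics are
#'   skipped and only process noise is added.
#' @param control integrator settings, see [discretize()].
#' @return the predicted `filter_state`.
#' @export
csukf_predict <- function(state, model, layout, t_k, t_k1,
                          control = list()) {
  sp <- make_sigma_points(state$mean, state$S, state$lower, state$upper,
                          state$alpha, state$beta, state$kappa)
  Xp <- if (t_k1 > t_k)
    discretize(model, layout, sp$points, t_k, t_k1, control)
  else sp$points
  m <- as.numeric(Xp %*% sp$wm)
  D <- Xp - m
  A <- t(cbind(D[, -1, drop = FALSE] %*% diag(sqrt(sp$wc[-1]),
                                              length(sp$wc) - 1),
               state$sqrt_Q))
  S <- sqrt_from_qr(A)
  S <- chol_update(S, D[, 1], sp$wc[1])
  state$mean <- clip_box(m, state$lower, state$upper)
  state$S <- S
  state$k <- state$k + 1L
  state
}

#' CSUKF measurement update
#'
#' Redraws constrained sigma points around the predicted mean, maps them
#' through the observation function, builds the innovation-covariance
#' factor by QR with `sqrt(R)`, computes the gain by triangular solves
#' and applies column-wise Cholesky downdates to the state factor. The
#' posterior mean is clipped into the box constraints.
#'
#' @inheritParams csukf_predict
#' @param y_k observation vector at time `t_k`.
#' @param R_k measurement-noise covariance at this step (matrix, or
#'   vector of variances).
#' @param t_k observation time (passed to the observation map).
#' @return list with the posterior `state`, the innovation `residual`
#'   (`y_k - y_pred`), and `y_pred`.
#' @export
csukf_update <- function(state, y_k, R_k, model, layout, t_k = 0) {
  o <- length(y_k)
  if (is.null(dim(R_k))) R_k <- diag(R_k, o)
  sqrt_R <- tryCatch(t(chol(R_k)),
                     error = function(e) stop("R is not positive definite; ",
                       "inflate the measurement-noise floor", call. = FALSE))
  sp <- make_sigma_points(state$mean, state$S, state$lower, state$upper,
                          state$alpha, state$beta, state$kappa)
  Y <- vapply(seq_len(ncol(sp$points)), function(j) {
    parts <- split_augmented(model, layout, sp$points[, j])
    as.numeric(model$observe(parts$x, parts$theta, t_k))
  }, numeric(o))
  Y <- matrix(Y, nrow = o)
  y_hat <- as.numeric(Y %*% sp$wm)
  Dy <- Y - y_hat
  Ay <- t(cbind(Dy[, -1, drop = FALSE] %*% diag(sqrt(sp$wc[-1]),
                                                length(sp$wc) - 1),
                sqrt_R))
  Sy <- sqrt_from_qr(Ay)
  Sy <- tryCatch(chol_update(Sy, Dy[, 1], sp$wc[1]),
                 error = function(e) stop("singular innovation factor; ",
                   "consider inflating R", call. = FALSE))
  Dx <- sp$points - state$mean
  Pxy <- Dx %*% (sp$wc * t(Dy))
  # K = Pxy (Sy Sy')^{-1} via two triangular solves
  K <- t(forwardsolve(Sy, t(Pxy)))
  K <- t(backsolve(t(Sy), t(K)))
  resid <- y_k - y_hat
  state$mean <- clip_box(state$mean + as.numeric(K %*% resid),
                         state$lower, state$upper)
  # Joseph-form square-root update: the posterior covariance
  # sum_i wc_i (Dx_i - K Dy_i)(.)' + K R K' is a sum of outer products,
  # so the factor can be rebuilt by QR without fragile downdates.
  Dj <- Dx - K %*% Dy
  Aj <- t(cbind(Dj[, -1, drop = FALSE] %*% diag(sqrt(sp$wc[-1]),
                                                length(sp$wc) - 1),
                K %*% sqrt_R))
  S <- sqrt_from_qr(Aj)
  S <- chol_update(S, Dj[, 1], sp$wc[1])
  state$S <- S
  list(state = state, residual = resid, y_pred = y_hat)
}

#' Chi-square merit of a residual sequence
#'
#' The weighted sum of squared innovations
#' \eqn{\chi^2 = \sum_k (y_k - \hat y^-_k) R_k^{-1} (y_k - \hat y^-_k)'},
#' the filter's likelihood surrogate.
#'
#' @param residuals matrix of innovations (one row per time point) or a
#'   list of vectors.
#' @param R a single covariance matrix, a variance vector recycled over
#'   steps, or a list of per-step covariance matrices/variance vectors.
#' @return scalar merit value.
#' @export
merit_chi2 <- function(residuals, R) {
  if (is.list(residuals)) residuals <- do.call(rbind, residuals)
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  get_Rinv <- function(Rk) {
    if (is.null(dim(Rk))) {
      if (any(Rk <= 0)) stop("singular R", call. = FALSE)
      diag(1 / Rk, length(Rk))
    } else {
      if (abs(det(Rk)) < .Machine$double.xmin)
        stop("singular R", call. = FALSE)
      solve(Rk)
    }
  }
  total <- 0
  for (k in seq_len(n)) {
    Rk <- if (is.list(R)) R[[k]] else R
    e <- residuals[k, ]
    total <- total + as.numeric(e %*% get_Rinv(Rk) %*% e)
  }
  total
}
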