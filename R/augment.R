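#' Augmented state layout for joint state/parameter estimation
#'
#' Parameter estimation is recast as state estimation by appending the
#' estimated parameters to the state vector with zero dynamics
#' (\eqn{\dot\theta = 0}). The augmented ordering is fixed as
#' `[states | estimated parameters]`; every covariance factor in the
#' package uses this order.
#'
#' @param model a [kinetic_model()].
#' @param estimate character vector of parameters to estimate; defaults
#'   to all non-fixed parameters.
#' @return list with `names`, `d` (number of states), `p` (number of
#'   estimated parameters), `state_idx`, `param_idx`.
#' @export
augmented_layout <- function(model, estimate = estimated_params(model)) {
  if (!all(estimate %in% model$param_names))
    stop("unknown parameters: ",
         paste(setdiff(estimate, model$param_names), collapse = ", "),
         call. = FALSE)
  if (any(estimate %in% names(model$fixed_params)))
    stop("cannot estimate a fixed parameter", call. = FALSE)
  d <- length(model$state_names)
  p <- length(estimate)
  list(names = c(model$state_names, estimate), d = d, p = p,
       state_idx = seq_len(d), param_idx = if (p) d + seq_len(p) else integer(0),
       estimate = estimate)
}

# Split an augmented vector into (x, full theta) given layout.
split_augmented <- function(model, layout, x_aug) {
  x <- stats::setNames(x_aug[layout$state_idx], model$state_names)
  th_est <- stats::setNames(x_aug[layout$param_idx], layout$estimate)
  list(x = x, theta = full_theta(model, th_est))
}

#' Propagate augmented states over one observation interval
#'
#' Advances the state block of one or more augmented vectors from `t_k`
#' to `t_k1` by numerically integrating the model's vector field with the
#' parameters taken from each vector's own parameter block; the parameter
#' block is returned unchanged. This is the discrete transition map used
#' by the filter's sigma points, so several augmented vectors (columns)
#' are propagated jointly.
#'
#' @param model a [kinetic_model()].
#' @param layout an [augmented_layout()].
#' @param X numeric matrix of augmented column vectors (or a single
#'   vector).
#' @param t_k,t_k1 interval endpoints, `t_k1 > t_k`.
#' @param control integrator settings: `integrator` one of `"rk4"`
#'   (fixed-step classical Runge-Kutta, `substeps` per interval, default
#'   4) or `"lsoda"` (adaptive, `rtol`/`atol`); defaults suit smooth
#'   kinetics sampled densely relative to their time scales.
#' @return matrix (or vector) of the same shape with the state block
#'   advanced.
#' @export
discretize <- function(model, layout, X, t_k, t_k1, control = list()) {
  if (t_k1 <= t_k) stop("t_k1 must exceed t_k", call. = FALSE)
  vec <- is.null(dim(X))
  X <- as.matrix(X)
  ctl <- modifyList(list(integrator = "rk4", substeps = 4L,
                         rtol = 1e-8, atol = 1e-10), control)
  thetas <- apply(X, 2, function(col)
    split_augmented(model, layout, col)$theta)
  thetas <- matrix(thetas, ncol = ncol(X))
  deriv <- function(S, t) {
    # S: d x m state block; returns rate matrix of same shape
    vapply(seq_len(ncol(S)), function(j) {
      x <- stats::setNames(S[, j], model$state_names)
      th <- stats::setNames(thetas[, j], model$param_names)
      r <- as.numeric(model$rhs(x, th, t))
      if (any(!is.finite(r))) r <- rep(NaN, layout$d)  # caught by caller
      r
    }, numeric(layout$d))
  }
  S <- X[layout$state_idx, , drop = FALSE]
  if (ctl$integrator == "rk4") {
    # fixed-step RK4; on overflow (stiff transient for the current
    # sigma-point parameters) retry with doubled substeps before
    # giving up
    m <- ctl$substeps
    S0 <- S
    repeat {
      S <- S0
      h <- (t_k1 - t_k) / m
      t <- t_k
      ok <- TRUE
      for (s in seq_len(m)) {
        k1 <- deriv(S, t)
        k2 <- deriv(S + h / 2 * k1, t + h / 2)
        k3 <- deriv(S + h / 2 * k2, t + h / 2)
        k4 <- deriv(S + h * k3, t + h)
        S <- S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        t <- t + h
        if (any(!is.finite(S)) || max(abs(S)) > 1e12) { ok <- FALSE; break }
      }
      if (ok) break
      m <- m * 8L
      if (m > 16384L)
        stop("state propagation diverged on [", signif(t_k, 6), ", ",
             signif(t_k1, 6), "]", call. = FALSE)
    }
  } else if (ctl$integrator == "lsoda") {
    d <- layout$d
    m <- ncol(S)
    func <- function(t, y, parms)
      list(as.numeric(deriv(matrix(y, nrow = d), t)))
    sol <- deSolve::ode(y = as.numeric(S), times = c(t_k, t_k1), func = func,
                        parms = NULL, method = "lsoda",
                        rtol = ctl$rtol, atol = ctl$atol)
    if (nrow(sol) < 2 || attr(sol, "istate")[1] < 0)
      stop("ODE integration failed on [", signif(t_k, 6), ", ",
           signif(t_k1, 6), "]", call. = FALSE)
    S <- matrix(sol[2, -1], nrow = d)
  } else stop("unknown integrator '", ctl$integrator, "'", call. = FALSE)
  if (any(!is.finite(S)))
    stop("state propagation diverged on [", signif(t_k, 6), ", ",
         signif(t_k1, 6), "]", call. = FALSE)
  X[layout$state_idx, ] <- S
  if (vec) drop(X) else X
}
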