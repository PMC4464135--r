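#' Define a kinetic model as a continuous state-space system
#'
#' A kinetic model couples an ODE right-hand side \eqn{\dot x = F(x,\theta,t)}
#' for the species concentrations with an observation map
#' \eqn{y = H(x,\theta,t)} selecting (or transforming) the measurable
#' outputs. Parameters can be partitioned into an estimated set and a set
#' held fixed during estimation.
#'
#' @param name identifier for the model.
#' @param rhs function `(x, theta, t)` returning the d-dimensional rate
#'   vector (mM/s by convention). `x` and `theta` are named numeric
#'   vectors.
#' @param state_names character vector of state identifiers (length d).
#' @param param_names character vector of parameter identifiers.
#' @param x0 named numeric initial state, length d (mM).
#' @param observe optional function `(x, theta, t)` returning the
#'   observation vector; defaults to observing the states named in
#'   `obs_names` directly.
#' @param obs_names identifiers of the observed outputs; defaults to all
#'   states.
#' @param theta_true optional reference parameter vector (used by fixtures
#'   and benchmarks to generate synthetic data).
#' @param fixed_params named numeric vector of parameters held constant
#'   during estimation; must be disjoint from the estimated set.
#' @return an object of class `kinetic_model`.
#' @examples
#' decay <- kinetic_model("decay",
#'   rhs = function(x, theta, t) c(-theta[["k"]] * x[["A"]]),
#'   state_names = "A", param_names = "k", x0 = c(A = 1),
#'   theta_true = c(k = 0.5))
#' simulate(decay, times = 0:5)
#' @export
kinetic_model <- function(name, rhs, state_names, param_names, x0,
                          observe = NULL, obs_names = state_names,
                          theta_true = NULL, fixed_params = NULL) {
  stopifnot(is.function(rhs), length(state_names) >= 1,
            length(x0) == length(state_names))
  if (anyDuplicated(state_names) || anyDuplicated(param_names))
    stop("state and parameter names must be unique", call. = FALSE)
  if (length(obs_names) < 1) stop("at least one observed output is required",
                                  call. = FALSE)
  x0 <- stats::setNames(as.numeric(x0), state_names)
  if (!is.null(theta_true)) {
    theta_true <- check_theta(theta_true, param_names)
  }
  fixed_params <- if (is.null(fixed_params)) numeric(0) else fixed_params
  if (length(fixed_params) && !all(names(fixed_params) %in% param_names))
    stop("fixed_params must name a subset of param_names", call. = FALSE)
  if (is.null(observe)) {
    if (!all(obs_names %in% state_names))
      stop("default observation map requires obs_names to be states",
           call. = FALSE)
    idx <- match(obs_names, state_names)
    observe <- function(x, theta, t) x[idx]
  }
  structure(list(name = name, rhs = rhs, observe = observe,
                 state_names = state_names, param_names = param_names,
                 obs_names = obs_names, x0 = x0, theta_true = theta_true,
                 fixed_params = fixed_params),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model:", x$name, "\n")
  cat("  states   (", length(x$state_names), "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  params   (", length(x$param_names), "): ",
      paste(x$param_names, collapse = ", "), "\n", sep = "")
  cat("  observed (", length(x$obs_names), "): ",
      paste(x$obs_names, collapse = ", "), "\n", sep = "")
  if (length(x$fixed_params))
    cat("  fixed:", paste(names(x$fixed_params), collapse = ", "), "\n")
  invisible(x)
}

# normalise a theta vector against the model's parameter names
check_theta <- function(theta, param_names) {
  if (is.null(names(theta))) {
    if (length(theta) != length(param_names))
      stop("unnamed theta must have length ", length(param_names),
           call. = FALSE)
    names(theta) <- param_names
  }
  if (!all(param_names %in% names(theta)))
    stop("theta is missing parameters: ",
         paste(setdiff(param_names, names(theta)), collapse = ", "),
         call. = FALSE)
  as.numeric(theta[param_names]) |> stats::setNames(param_names)
}

#' Names of the estimated (non-fixed) parameters of a model
#' @param model a [kinetic_model()].
#' @return character vector.
#' @export
estimated_params <- function(model) {
  setdiff(model$param_names, names(model$fixed_params))
}

# complete a partial parameter vector: reference values (when present)
# underlie everything, fixed parameters override them, and the supplied
# estimates override both
full_theta <- function(model, theta_est) {
  th <- stats::setNames(numeric(length(model$param_names)),
                        model$param_names)
  if (!is.null(model$theta_true)) th[] <- model$theta_true[model$param_names]
  th[names(model$fixed_params)] <- model$fixed_params
  known <- intersect(names(theta_est), model$param_names)
  th[known] <- theta_est[known]
  th
}

#' Simulate a kinetic model deterministically (and optionally add noise)
#'
#' Integrates the ODE system from `x0` and applies the observation map at
#' each requested time. Integration uses an adaptive stiff-capable solver
#' (`deSolve::lsoda`) with tight default tolerances.
#'
#' @param object a [kinetic_model()].
#' @param nsim number of noisy replicates when `noise` is given.
#' @param seed optional seed for the noise stream.
#' @param times numeric measurement grid; need not include 0 (integration
#'   always starts at `t = 0` from `x0`). Strictly increasing.
#' @param theta parameter vector; defaults to `object$theta_true`.
#' @param x0 initial state override.
#' @param noise optional [noise_model()] applied to the clean series.
#' @param control list of integrator settings: `rtol` (default `1e-8`),
#'   `atol` (default `1e-10`), `method` (`"lsoda"`).
#' @param ... unused.
#' @return a time-series data frame (class `kf_series`): column `time`
#'   plus one column per observed output. With `nsim > 1` a list of them.
#' @export
simulate.kinetic_model <- function(object, nsim = 1, seed = NULL,
                                   times, theta = object$theta_true,
                                   x0 = object$x0, noise = NULL,
                                   control = list(), ...) {
  if (is.null(theta)) stop("no parameter vector available", call. = FALSE)
  theta <- check_theta(theta, object$param_names)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  ctl <- modifyList(list(rtol = 1e-8, atol = 1e-10, method = "lsoda"),
                    control)
  t_solve <- if (times[1] > 0) c(0, times) else times
  func <- function(t, y, parms) {
    names(y) <- object$state_names
    list(as.numeric(object$rhs(y, theta, t)))
  }
  sol <- deSolve::ode(y = as.numeric(x0), times = t_solve, func = func,
                      parms = NULL, method = ctl$method,
                      rtol = ctl$rtol, atol = ctl$atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(t_solve))
    stop("ODE integration failed near t = ",
         signif(sol[nrow(sol), 1], 6), call. = FALSE)
  keep <- match(times, sol[, 1])
  obs <- vapply(seq_along(keep), function(i) {
    x <- sol[keep[i], -1]
    names(x) <- object$state_names
    as.numeric(object$observe(x, theta, times[i]))
  }, numeric(length(object$obs_names)))
  obs <- if (length(object$obs_names) == 1) matrix(obs, ncol = 1) else t(obs)
  clean <- kf_series(times, obs, object$obs_names,
                     meta = list(model = object$name))
  if (is.null(noise)) return(clean)
  if (!is.null(seed)) set.seed(seed)
  reps <- replicate(nsim, apply_noise(clean, noise), simplify = FALSE)
  if (nsim == 1) reps[[1]] else reps
}

#' Construct a measurement time series
#'
#' The standard container for measurement data: a data frame with a
#' strictly increasing `time` column (seconds) and one column per observed
#' output (mM). Provenance is carried in the `meta` attribute.
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric matrix, `length(times)` rows.
#' @param names character identifiers for the value columns.
#' @param meta free-form provenance list.
#' @return data frame of class `kf_series`.
#' @export
kf_series <- function(times, values, names, meta = list()) {
  values <- as.matrix(values)
  if (length(times) < 2) stop("a time series needs at least 2 rows",
                              call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("time-series values must be finite", call. = FALSE)
  df <- data.frame(time = times, values)
  colnames(df) <- c("time", names)
  attr(df, "meta") <- meta
  class(df) <- c("kf_series", "data.frame")
  df
}

#' Extract the value matrix of a time series
#' @param series a [kf_series()].
#' @return numeric matrix (rows = time points, columns = outputs).
#' @export
series_values <- function(series) {
  as.matrix(series[, setdiff(colnames(series), "time"), drop = FALSE])
}

#' Read / write time-series CSV files
#'
#' CSV convention: first column `time`, remaining columns named by the
#' observed species.
#' @param path file path.
#' @return `read_series` returns a `kf_series`.
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (colnames(df)[1] != "time")
    stop("first CSV column must be 'time'", call. = FALSE)
  kf_series(df$time, as.matrix(df[, -1, drop = FALSE]),
            colnames(df)[-1], meta = list(source = path))
}

#' @param series a `kf_series`.
#' @rdname read_series
#' @export
write_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
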