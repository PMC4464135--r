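# Scaled sensitivity matrix and orthogonal parameter ranking.

#' Scaled sensitivity matrix of a kinetic model
#'
#' Builds the matrix of scaled sensitivity coefficients
#' \eqn{z_{ij} = (\partial x_i/\partial \theta_j)\,(\hat\theta_j/\hat x_i)}
#' over all (time, output) pairs, where the raw derivatives are computed
#' by central finite differences of the deterministic simulation. The
#' scaling makes columns dimensionless and invariant under unit changes
#' of individual parameters.
#'
#' @param model a [kinetic_model()].
#' @param theta_hat parameter vector at which sensitivities are taken
#'   (full or estimated part; fixed parameters are filled in).
#' @param times measurement grid.
#' @param params columns to compute (default: the estimated parameters).
#' @param rel_step relative finite-difference step (default `1e-6`).
#' @param eps_scale floor used for the output value in the scaling when
#'   \eqn{\hat x_i = 0} (default `1e-12`; applied with a warning).
#' @param control integrator settings forwarded to [simulate()]
#'   (defaults tighten `rtol`/`atol` to `1e-10`/`1e-12` so the
#'   difference quotient stays above integration error).
#' @return object of class `sensitivity_matrix`: the scaled matrix `Z`
#'   ((n_times * n_outputs) x n_params, labeled rows/columns), plus the
#'   raw matrix `Z_raw`, `theta_hat`, `x_hat` and `times`.
#' @export
sensitivity_matrix <- function(model, theta_hat, times,
                               params = estimated_params(model),
                               rel_step = 1e-6, eps_scale = 1e-12,
                               control = list()) {
  th <- full_theta(model, check_part(theta_hat, params))
  ctl <- modifyList(list(rtol = 1e-10, atol = 1e-12), control)
  # fall back to standard tolerances where the solver cannot honour the
  # tight defaults (large-state systems); the difference quotient then
  # simply carries a larger, still acceptable, truncation floor
  sim <- function(theta) {
    tryCatch(simulate(model, times = times, theta = theta, control = ctl),
             error = function(e)
               simulate(model, times = times, theta = theta,
                        control = list(rtol = 1e-8, atol = 1e-10)))
  }
  base <- sim(th)
  x_hat <- as.numeric(series_values(base))
  o <- length(model$obs_names)
  rows <- paste(rep(times, o), rep(model$obs_names, each = length(times)),
                sep = ":")
  Z_raw <- matrix(NA_real_, length(x_hat), length(params),
                  dimnames = list(rows, params))
  for (p in params) {
    h <- rel_step * max(abs(th[[p]]), 1e-2)  # floor guards tiny values
    up <- th; up[[p]] <- th[[p]] + h
    dn <- th; dn[[p]] <- th[[p]] - h
    yu <- as.numeric(series_values(sim(up)))
    yd <- as.numeric(series_values(sim(dn)))
    Z_raw[, p] <- (yu - yd) / (2 * h)
  }
  scale_x <- abs(x_hat)
  if (any(scale_x < eps_scale)) {
    warning("output value(s) of 0 at scaling points; using eps_scale floor")
    scale_x <- pmax(scale_x, eps_scale)
  }
  Z <- Z_raw * (rep(1, length(x_hat)) %o% th[params]) / scale_x
  structure(list(Z = Z, Z_raw = Z_raw, theta_hat = th[params],
                 x_hat = x_hat, times = times,
                 outputs = model$obs_names),
            class = "sensitivity_matrix")
}

check_part <- function(theta, params) {
  if (is.null(names(theta)) && length(theta) == length(params))
    names(theta) <- params
  theta
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("Scaled sensitivity matrix:", nrow(x$Z), "x", ncol(x$Z), "\n")
  cat("  column norms:\n")
  print(signif(sqrt(colSums(x$Z^2)), 4))
  invisible(x)
}

#' Orthogonal parameter ranking
#'
#' Greedy orthogonalization of the scaled sensitivity columns: the first
#' rank goes to the column of largest Euclidean norm; at each later step
#' all columns are regressed onto the span of the selected columns and
#' the parameter with the largest residual norm is selected next. The
#' procedure stops when the largest residual norm falls below
#' `threshold`; parameters left over are reported as unranked
#' (ranking-non-identifiable).
#'
#' @param Z a [sensitivity_matrix()] or a plain labeled matrix.
#' @param threshold residual-norm stop criterion (default 0.004).
#' @return object of class `ranking`: `ranked` (ordered names),
#'   `residual_norms` (per accepted step), `unranked`, `threshold`.
#' @export
rank_parameters <- function(Z, threshold = 0.004) {
  M <- if (inherits(Z, "sensitivity_matrix")) Z$Z else as.matrix(Z)
  if (!ncol(M)) stop("empty sensitivity matrix", call. = FALSE)
  if (is.null(colnames(M))) colnames(M) <- paste0("p", seq_len(ncol(M)))
  remaining <- colnames(M)
  ranked <- character(0)
  norms <- numeric(0)
  repeat {
    if (!length(remaining)) break
    res_norm <- if (!length(ranked)) {
      sqrt(colSums(M[, remaining, drop = FALSE]^2))
    } else {
      X <- M[, ranked, drop = FALSE]
      # residual after projection onto span(X); pseudo-inverse guards
      # rank-deficient selections
      P <- X %*% MASS_ginv(crossprod(X)) %*% t(X)
      R <- M[, remaining, drop = FALSE] -
        P %*% M[, remaining, drop = FALSE]
      sqrt(colSums(R^2))
    }
    best <- which.max(res_norm)
    if (res_norm[best] < threshold) break
    ranked <- c(ranked, remaining[best])
    norms <- c(norms, res_norm[best])
    remaining <- remaining[-best]
  }
  structure(list(ranked = ranked, residual_norms = norms,
                 unranked = remaining, threshold = threshold),
            class = "ranking")
}

# Moore-Penrose pseudo-inverse via SVD (symmetric input here)
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.ranking <- function(x, ...) {
  cat("Orthogonal parameter ranking (threshold ", x$threshold, ")\n",
      sep = "")
  if (length(x$ranked))
    for (i in seq_along(x$ranked))
      cat(sprintf("  %2d. %-12s residual norm %.4g\n", i, x$ranked[i],
                  x$residual_norms[i]))
  if (length(x$unranked))
    cat("  unranked (N.I.):", paste(x$unranked, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate rankings across repeated estimation runs
#'
#' Averages the rank position of each parameter over runs (an unranked
#' parameter counts as worst rank + 1) and orders parameters by average
#' position, breaking ties lexicographically. A parameter unranked in
#' more than half the runs stays unranked in the aggregate.
#'
#' @param runs list of [rank_parameters()] results over the same
#'   parameter set.
#' @return a `ranking` object; `residual_norms` holds the average rank
#'   positions of the ranked parameters.
#' @export
aggregate_rankings <- function(runs) {
  if (!length(runs)) stop("empty runs list", call. = FALSE)
  all_params <- sort(unique(unlist(lapply(runs, function(r)
    c(r$ranked, r$unranked)))))
  worst <- length(all_params) + 1L
  pos <- sapply(runs, function(r) {
    p <- stats::setNames(rep(worst, length(all_params)), all_params)
    if (length(r$ranked)) p[r$ranked] <- seq_along(r$ranked)
    p
  })
  pos <- matrix(pos, nrow = length(all_params),
                dimnames = list(all_params, NULL))
  avg <- rowMeans(pos)
  n_unranked <- rowSums(pos == worst)
  stay_unranked <- n_unranked > length(runs) / 2
  ranked <- all_params[!stay_unranked]
  ord <- order(avg[ranked], ranked)   # lexicographic tie-break
  ranked <- ranked[ord]
  structure(list(ranked = ranked, residual_norms = avg[ranked],
                 unranked = sort(all_params[stay_unranked]),
                 threshold = runs[[1]]$threshold),
            class = "ranking")
}
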