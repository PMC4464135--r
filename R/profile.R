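# Profile-likelihood identifiability analysis: per-parameter chi-square
# trajectories with CSUKF re-optimization of the nuisance parameters,
# likelihood-ratio confidence intervals and classification into
# identifiable / structurally / practically non-identifiable.

#' Chi-square likelihood-ratio threshold
#'
#' The quantile of the chi-square distribution with `df` degrees of
#' freedom used as the likelihood-ratio confidence threshold
#' \eqn{\Delta(\alpha, m)}: the pointwise threshold takes `df = 1`, the
#' simultaneous threshold `df = `number of parameters. At the 95% level
#' these are 3.84 and (for 12 parameters) 21.03.
#'
#' @param alpha confidence level in (0, 1), e.g. 0.95.
#' @param df degrees of freedom, >= 1.
#' @return scalar threshold.
#' @export
chi2_threshold <- function(alpha, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qchisq(alpha, df)
}

#' Profile the likelihood of one parameter
#'
#' Steps the parameter of interest away from its estimate in both
#' directions, at each step re-optimizing the nuisance parameters with
#' the CSUKF (warm-started from the neighbouring profile point) and
#' recording the deterministic chi-square objective. Stepping is
#' multiplicative (log-scale exploration); the step is halved when the
#' objective jumps by more than 1 between points and doubled after 5
#' smooth points. Each direction stops on threshold crossing, on
#' flatness (small rise over at least `flat_decades` decades), when the
#' parameter's box bound is reached, or at `max_steps`.
#'
#' @param fit a [csukf()] result.
#' @param param name of the parameter of interest.
#' @param alpha confidence level (default 0.95); the pointwise
#'   threshold `chi2_threshold(alpha, 1)` defines the CI endpoints.
#' @param step initial multiplicative step (default 1.1).
#' @param max_steps per direction (default 200).
#' @param flat_eps chi-square rise regarded as flat (default 0.5,
#'   an order of magnitude below the pointwise threshold; absorbs the
#'   re-optimization tolerance of the filter-based nuisance refits).
#' @param flat_decades log10 span that must be explored before a flat
#'   trajectory is called flat (default 2).
#' @param passes CSUKF sweeps per re-optimization (default 4).
#' @param refit_seeds unused reserved.
#' @return object of class `profile_traj`: `points` data frame
#'   (psi, chi2, direction), `eta` list of nuisance vectors, `chi2_min`,
#'   thresholds, crossing info, `ci`, and `class` (see
#'   [classify_profile()]).
#' @export
profile_parameter <- function(fit, param, alpha = 0.95, step = 1.1,
                              max_steps = 200, flat_eps = 0.5,
                              flat_decades = 2, passes = 4,
                              refit_seeds = NULL) {
  stopifnot(inherits(fit, "csukf"))
  est <- names(fit$theta)
  if (!param %in% est) stop("'", param, "' is not an estimated parameter",
                            call. = FALSE)
  nuisance <- setdiff(est, param)
  pi_idx <- match(param, est)
  lo <- fit$lower[fit$layout$d + pi_idx]
  hi <- fit$upper[fit$layout$d + pi_idx]
  lo_n <- fit$lower[fit$layout$d + match(nuisance, est)]
  hi_n <- fit$upper[fit$layout$d + match(nuisance, est)]
  at_bound <- function(eta) {
    if (!length(nuisance)) return(FALSE)
    e <- eta[nuisance]
    any(e <= lo_n * 1.1 + 1e-12 | e >= hi_n * 0.9)
  }
  thr1 <- chi2_threshold(alpha, 1)
  thrm <- chi2_threshold(alpha, length(est))
  chi2_hat <- chi2_objective(fit, fit$theta)
  theta_hat <- fit$theta

  refit_chi2 <- function(psi, eta_start, psi_prev = NULL) {
    # re-optimize nuisance parameters with the parameter of interest
    # fixed at psi; evaluate the deterministic objective at the result
    model_f <- fit$model
    model_f$fixed_params <- c(model_f$fixed_params,
                              stats::setNames(psi, param))
    if (!length(nuisance)) {
      th <- stats::setNames(psi, param)
      return(list(chi2 = chi2_objective(fit, th), eta = numeric(0)))
    }
    nlo <- fit$lower[fit$layout$d + match(nuisance, est)]
    nhi <- fit$upper[fit$layout$d + match(nuisance, est)]
    score <- function(eta) {
      chi2_objective(fit, c(stats::setNames(psi, param), eta[nuisance]))
    }
    # candidate warm starts: the neighbouring profile point, a
    # ratio-scaled compensation of it, and the original fit
    starts <- list(eta_start[nuisance])
    if (!is.null(psi_prev) && psi_prev > 0)
      starts$ratio <- clip_box(eta_start[nuisance] * psi_prev / psi,
                               nlo, nhi)
    starts$hat <- theta_hat[nuisance]
    cs <- vapply(starts, function(e) tryCatch(score(e),
                                              error = function(err) Inf), 0)
    best_i <- which.min(cs)
    eta_best <- starts[[best_i]]
    chi2_best <- cs[best_i]
    # scale-aware filter re-optimization from the best candidate:
    # prior and process-noise stds follow the warm start's magnitude so
    # tiny nuisance values stay resolvable
    eta0 <- abs(eta_best)
    f2 <- csukf(model_f, fit$data, estimate = nuisance,
                theta0 = eta_best, R = fit$R_list,
                lower = nlo, upper = nhi,
                passes = passes, tol = 1e-3,
                control = modifyList(fit$control, list(
                  param_sd = pmax(0.3 * eta0, 1e-8),
                  q_param = pmax(0.02 * eta0, 1e-9),
                  q_decay = 0.6)))
    cand <- tryCatch(score(coef(f2)), error = function(err) Inf)
    if (cand < chi2_best) {
      chi2_best <- cand
      eta_best <- coef(f2)
    }
    list(chi2 = chi2_best, eta = eta_best)
  }

  explore <- function(dir) {
    pts <- list()
    psi <- theta_hat[[param]]
    eta <- theta_hat
    stp <- step
    smooth_run <- 0
    last_chi2 <- chi2_hat
    crossed <- FALSE
    hit_bound <- FALSE
    failed <- 0L
    for (i in seq_len(max_steps)) {
      # propose a multiplicative step; reject and shrink while the
      # objective jumps by more than 1 chi-square unit, so the
      # trajectory is resolved finely where it rises steeply
      res <- NULL
      for (try in 1:8) {
        psi_next <- if (dir > 0) psi * stp else psi / stp
        if (psi_next > hi || psi_next < lo) { hit_bound <- TRUE; break }
        res <- tryCatch(refit_chi2(psi_next, eta, psi_prev = psi),
                        error = function(e) NULL)
        if (is.null(res)) { failed <- failed + 1L; break }
        if (abs(res$chi2 - last_chi2) <= 1 || stp <= 1.005) break
        stp <- max(1.005, sqrt(stp))
        smooth_run <- 0
        res <- NULL
      }
      if (hit_bound) break
      if (is.null(res)) {
        if (failed >= 3) break   # repeated refit failure: stop this side
        psi <- psi_next
        next
      }
      smooth_run <- smooth_run + 1
      if (smooth_run >= 5) { stp <- min(stp^2, 2); smooth_run <- 0 }
      pts[[length(pts) + 1L]] <-
        list(psi = psi_next, chi2 = res$chi2,
             bound = at_bound(c(stats::setNames(psi_next, param),
                                res$eta)),
             eta = c(stats::setNames(psi_next, param), res$eta))
      eta[nuisance] <- res$eta[nuisance]
      psi <- psi_next
      last_chi2 <- res$chi2
      # a single high point can be an under-optimized refit; require
      # two consecutive points above the threshold before stopping
      npts <- length(pts)
      if (res$chi2 - chi2_hat > thr1 * 1.2 && npts >= 2 &&
          pts[[npts - 1L]]$chi2 - chi2_hat > thr1 * 1.05) {
        crossed <- TRUE
        break
      }
    }
    list(points = pts, crossed = crossed, hit_bound = hit_bound,
         failed = failed)
  }

  up <- explore(+1)
  down <- explore(-1)
  pts <- data.frame(
    psi = c(rev(vapply(down$points, `[[`, 0, "psi")), theta_hat[[param]],
            vapply(up$points, `[[`, 0, "psi")),
    chi2_raw = c(rev(vapply(down$points, `[[`, 0, "chi2")), chi2_hat,
                 vapply(up$points, `[[`, 0, "chi2")))
  pts$direction <- c(rep(-1, length(down$points)), 0,
                     rep(1, length(up$points)))
  pts$nuisance_at_bound <- c(
    rev(vapply(down$points, function(p) isTRUE(p$bound), NA)), FALSE,
    vapply(up$points, function(p) isTRUE(p$bound), NA))
  # every recorded value upper-bounds the true profile, and the true
  # profile is quasi-convex: a point cannot exceed one farther from the
  # minimum on its own side, so spikes above the outward running
  # minimum are failed re-optimizations and take that minimum instead
  im <- which.min(pts$chi2_raw)
  v <- pts$chi2_raw
  if (im > 1) v[seq_len(im - 1)] <- cummin(v[seq_len(im - 1)])
  if (im < length(v)) {
    idx <- (im + 1):length(v)
    v[idx] <- rev(cummin(rev(v[idx])))
  }
  pts$chi2 <- v
  pts$side <- sign(pts$psi - pts$psi[im])
  eta_list <- c(rev(lapply(down$points, `[[`, "eta")),
                list(fit$theta),
                lapply(up$points, `[[`, "eta"))
  # the profile scan may find a better optimum than the original fit
  chi2_min <- min(pts$chi2)
  traj <- structure(list(param = param, points = pts, eta = eta_list,
                         chi2_min = chi2_min, chi2_fit = chi2_hat,
                         theta_hat = theta_hat[[param]],
                         threshold_pointwise = thr1,
                         threshold_simultaneous = thrm,
                         alpha = alpha,
                         flat_eps = flat_eps, flat_decades = flat_decades,
                         hit_bound_up = up$hit_bound,
                         hit_bound_down = down$hit_bound,
                         n_failed = up$failed + down$failed,
                         unreliable = (up$failed + down$failed) >
                           0.3 * nrow(pts)),
                    class = "profile_traj")
  traj$class <- classify_profile(traj)
  traj$ci <- profile_ci(traj)
  traj
}

# linear interpolation of the threshold crossing in each direction
profile_ci <- function(traj) {
  pts <- traj$points
  if (!is.null(pts$nuisance_at_bound)) pts <- pts[!pts$nuisance_at_bound, ]
  thr <- traj$chi2_min + traj$threshold_pointwise
  solve_side <- function(s) {
    sd_col <- if (is.null(pts$side)) pts$direction else pts$side
    p <- pts[sd_col == s | sd_col == 0, ]
    p <- p[order(p$psi), ]
    if (s < 0) p <- p[rev(seq_len(nrow(p))), ]   # walk away from center
    above <- which(p$chi2 > thr)
    if (!length(above)) return(if (s > 0) Inf else -Inf)
    i <- above[1]
    if (i == 1) return(p$psi[1])
    f <- (thr - p$chi2[i - 1]) / (p$chi2[i] - p$chi2[i - 1])
    p$psi[i - 1] + f * (p$psi[i] - p$psi[i - 1])
  }
  c(lower = solve_side(-1), upper = solve_side(+1))
}

#' Classify a profile-likelihood trajectory
#'
#' Applies the classification rules: threshold crossings on both sides
#' give an identifiable parameter with a finite confidence interval;
#' a crossing on exactly one side gives practical non-identifiability
#' (the open side's bound is infinite); no crossing with a flat profile
#' (rise below `flat_eps` over at least `flat_decades` decades) gives
#' structural non-identifiability; no crossing with a non-flat profile
#' is reported as practical (rising too slowly). Points whose
#' re-optimized nuisance vector sits on a box bound are excluded: their
#' rise is induced by the constraints, not by data information.
#'
#' @param traj a `profile_traj` from [profile_parameter()].
#' @return one of `"identifiable"`, `"structural"`, `"practical"`.
#' @export
classify_profile <- function(traj) {
  pts <- traj$points
  if (!nrow(pts)) stop("empty profile trajectory", call. = FALSE)
  # a chi-square rise while a re-optimized nuisance parameter is pinned
  # on its box bound reflects the constraints, not the likelihood
  # geometry; such points do not count as crossings
  if (!is.null(pts$nuisance_at_bound)) pts <- pts[!pts$nuisance_at_bound, ]
  thr <- traj$chi2_min + traj$threshold_pointwise
  side <- if (is.null(pts$side)) pts$direction else pts$side
  cross_up <- any(pts$chi2[side > 0] > thr)
  cross_down <- any(pts$chi2[side < 0] > thr)
  if (cross_up && cross_down) return("identifiable")
  if (cross_up || cross_down) return("practical")
  span <- log10(max(pts$psi) / min(pts$psi))
  flat <- (max(pts$chi2) - traj$chi2_min) < traj$flat_eps &&
    span >= traj$flat_decades
  if (flat) "structural" else "practical"
}

#' @export
print.profile_traj <- function(x, ...) {
  cat("Profile likelihood:", x$param, "->", x$class, "\n")
  cat(sprintf("  psi range [%.4g, %.4g], chi2 min %.4g, pointwise thr %.3g\n",
              min(x$points$psi), max(x$points$psi), x$chi2_min,
              x$threshold_pointwise))
  ci <- x$ci
  cat(sprintf("  95%% CI: [%.4g, %.4g]\n", ci[1], ci[2]))
  if (x$unreliable) cat("  WARNING: >30% of refits failed\n")
  invisible(x)
}

#' @export
plot.profile_traj <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$psi, pts$chi2 - x$chi2_min, log = "x", type = "b",
                 pch = 16, cex = 0.6, xlab = x$param,
                 ylab = expression(Delta ~ chi^2),
                 main = paste0(x$param, " (", x$class, ")"), ...)
  graphics::abline(h = x$threshold_pointwise, lty = 2)
  graphics::abline(h = x$threshold_simultaneous, lty = 3)
  invisible(x)
}

#' Run the profile-likelihood analysis over several parameters
#'
#' Maps [profile_parameter()] and [classify_profile()] over the
#' requested parameters.
#'
#' @param fit a [csukf()] result.
#' @param params parameters to profile (default: all estimated).
#' @param ... forwarded to [profile_parameter()].
#' @return object of class `identifiability`: named list of
#'   trajectories plus a `summary` data frame (class, CI bounds).
#' @export
run_identifiability <- function(fit, params = names(fit$theta), ...) {
  trajs <- lapply(params, function(p) profile_parameter(fit, p, ...))
  names(trajs) <- params
  summary <- data.frame(
    parameter = params,
    class = vapply(trajs, `[[`, "", "class"),
    ci_lower = vapply(trajs, function(t) t$ci[[1]], 0),
    ci_upper = vapply(trajs, function(t) t$ci[[2]], 0),
    estimate = vapply(trajs, `[[`, 0, "theta_hat"),
    row.names = NULL)
  structure(list(trajectories = trajs, summary = summary,
                 chi2_min = min(vapply(trajs, `[[`, 0, "chi2_min")),
                 alpha = trajs[[1]]$alpha),
            class = "identifiability")
}

#' @export
print.identifiability <- function(x, ...) {
  cat("Profile-likelihood identifiability analysis (",
      x$alpha * 100, "% level)\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' State-trajectory variability along a profile
#'
#' Simulates the model at every profile point's full parameter vector
#' and measures, per state and time, the envelope width (max - min)
#' across the profile. Regions of large width mark where additional
#' measurements would most efficiently pin down the profiled parameter.
#'
#' @param fit the [csukf()] fit the profile came from.
#' @param traj a `profile_traj` whose points carry re-optimized
#'   nuisance vectors.
#' @param times simulation grid (default: the data's).
#' @return list with `width` (time x state matrix of envelope widths)
#'   and `suggestion` (state and time of the maximum).
#' @export
trajectory_variability <- function(fit, traj, times = fit$data$time) {
  model <- fit$model
  sims <- list()
  for (i in seq_along(traj$eta)) {
    th <- fit$theta_full
    th[names(traj$eta[[i]])] <- traj$eta[[i]]
    s <- tryCatch(simulate(model, times = times, theta = th),
                  error = function(e) NULL)
    if (!is.null(s)) sims[[length(sims) + 1L]] <- series_values(s)
  }
  if (!length(sims)) stop("no profile point could be simulated",
                          call. = FALSE)
  arr <- simplify2array(sims)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  width <- apply(arr, c(1, 2), max) - apply(arr, c(1, 2), min)
  dimnames(width) <- list(NULL, model$obs_names)
  idx <- which(width == max(width), arr.ind = TRUE)[1, ]
  list(width = width,
       suggestion = list(state = model$obs_names[idx[2]],
                         time = times[idx[1]],
                         width = max(width)))
}
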