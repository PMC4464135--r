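# Detection of inter-parameter relationships: linear correlation from
# the filter's square-root covariance, and non-linear functional
# relations by alternating conditional expectations with bootstrap.

#' Parameter correlation matrix from a square-root covariance factor
#'
#' Reconstructs `P = S S'` and normalizes the parameter block to a
#' correlation matrix. Pairs with `|corr| >= tau` are flagged.
#'
#' @param S lower-triangular square-root factor (a full augmented factor
#'   or already restricted to the parameter block), or a [csukf()] fit.
#' @param param_idx indices of the parameter block (default: all rows;
#'   taken from the fit's layout when `S` is a fit).
#' @param tau flag threshold for strong correlation (default 0.8).
#' @return object of class `correlation_report`: `corr` matrix and
#'   `flagged_pairs` data frame.
#' @export
correlation_from_sqrt <- function(S, param_idx = NULL, tau = 0.8) {
  nms <- NULL
  if (inherits(S, "csukf")) {
    param_idx <- S$layout$param_idx
    nms <- S$layout$estimate
    S <- S$S
  }
  P <- tcrossprod(S)
  if (!is.null(param_idx)) P <- P[param_idx, param_idx, drop = FALSE]
  v <- diag(P)
  if (any(v <= 0)) stop("degenerate filter state: zero variance entry",
                        call. = FALSE)
  corr <- P / sqrt(v %o% v)
  diag(corr) <- 1
  if (!is.null(nms)) dimnames(corr) <- list(nms, nms)
  if (is.null(rownames(corr)))
    dimnames(corr) <- rep(list(paste0("p", seq_len(nrow(corr)))), 2)
  pairs <- which(upper.tri(corr) & abs(corr) >= tau, arr.ind = TRUE)
  flagged <- data.frame(param1 = rownames(corr)[pairs[, 1]],
                        param2 = colnames(corr)[pairs[, 2]],
                        corr = corr[pairs])
  structure(list(corr = corr, flagged_pairs = flagged, tau = tau),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Parameter correlations (|corr| >=", x$tau, "flagged)\n")
  print(round(x$corr, 3))
  if (nrow(x$flagged_pairs)) {
    cat("flagged pairs:\n")
    print(x$flagged_pairs, digits = 3)
  } else cat("no strongly correlated pairs\n")
  invisible(x)
}

# Nadaraya-Watson conditional expectation of v given x, evaluated at x.
# Smoothing happens on the rank scale of x (an adaptive bandwidth),
# which keeps the estimate invariant under monotone transforms of x and
# robust to heavily skewed parameter samples; the bandwidth follows
# Silverman's rule on that scale.
nw_smooth <- function(v, x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(rep(mean(v), n))
  r <- rank(x, ties.method = "average") / n
  bw <- 1.06 * stats::sd(r) * n^(-1 / 5)
  W <- exp(-0.5 * (outer(r, r, "-") / bw)^2)
  as.numeric(W %*% v) / rowSums(W)
}

#' Maximal correlation by alternating conditional expectations
#'
#' Estimates the maximal correlation between a response `y` and one or
#' more predictors `X` by alternating conditional expectations: the
#' response transform is the (normalized) conditional expectation of the
#' summed predictor transforms given `y`, and each predictor transform
#' is updated by backfitting the current residual on that predictor.
#' Conditional expectations use Nadaraya-Watson local averaging with
#' Silverman's bandwidth.
#'
#' @param y numeric response sample (length >= 30).
#' @param X numeric predictor vector or matrix (columns non-constant).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the r-squared change (default
#'   `1e-4`).
#' @return list with `r2` (squared maximal correlation), `theta`
#'   (response transform values), `phi` (matrix of predictor transform
#'   values), `iterations`, `converged`.
#' @export
ace_maximal_correlation <- function(y, X, max_iter = 100, tol = 1e-4) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 30) stop("ACE needs at least 30 samples", call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0) || stats::sd(y) == 0)
    stop("constant column passed to ACE", call. = FALSE)
  p <- ncol(X)
  theta <- as.numeric(scale(y))
  phi <- matrix(0, n, p)
  r2 <- 0
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    for (j in seq_len(p)) {
      resid <- theta - rowSums(phi[, -j, drop = FALSE])
      phi[, j] <- nw_smooth(resid, X[, j])
      phi[, j] <- phi[, j] - mean(phi[, j])
    }
    s <- rowSums(phi)
    theta <- nw_smooth(s, y)
    theta <- theta - mean(theta)
    if (stats::sd(theta) == 0) break
    theta <- theta / stats::sd(theta)
    r2_new <- stats::cor(theta, s)^2
    if (is.na(r2_new)) break
    if (abs(r2_new - r2) < tol) { r2 <- r2_new; converged <- TRUE; break }
    r2 <- r2_new
  }
  list(r2 = r2, theta = theta, phi = phi, iterations = it,
       converged = converged)
}

#' Detect non-linear functional relations among parameters (MOTA-style)
#'
#' For each response parameter, greedily grows a predictor subset (up to
#' `max_set`) scored by the bootstrap mean of the ACE maximal
#' correlation. A relation is reported when the bootstrap mean r-squared
#' reaches `tau` with standard deviation at most `r2_sd_max`; minimal
#' subsets are preferred (a superset is not grown once a subset
#' passes).
#'
#' @param samples matrix of co-optimized parameter vectors (rows =
#'   samples, e.g. profile points and/or repeated-fit estimates),
#'   labeled columns.
#' @param max_set maximal predictor-set size (default 3).
#' @param B bootstrap resamples (default 50).
#' @param tau r-squared detection threshold (default 0.9).
#' @param r2_sd_max maximal bootstrap r-squared std (default 0.1).
#' @param seed optional seed for the bootstrap.
#' @return data frame of class `mota_relations`: response, predictors
#'   (comma-joined), r2_mean, r2_sd, significant.
#' @export
mota_detect <- function(samples, max_set = 3, B = 50, tau = 0.9,
                        r2_sd_max = 0.1, seed = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 30)
    stop("too few samples for MOTA; extend profiling or add fits",
         call. = FALSE)
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("p", seq_len(ncol(samples)))
  keep <- apply(samples, 2, stats::sd) > 0
  samples <- samples[, keep, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  params <- colnames(samples)
  n <- nrow(samples)
  boot_idx <- replicate(B, sample.int(n, n, replace = TRUE),
                        simplify = FALSE)
  boot_score <- function(resp, preds) {
    r2s <- vapply(boot_idx, function(idx) {
      s <- samples[idx, , drop = FALSE]
      ok <- stats::sd(s[, resp]) > 0 &&
        all(apply(s[, preds, drop = FALSE], 2, stats::sd) > 0)
      if (!ok) return(NA_real_)
      ace_maximal_correlation(s[, resp], s[, preds, drop = FALSE],
                              max_iter = 30)$r2
    }, 0)
    r2s <- r2s[is.finite(r2s)]
    c(mean = mean(r2s), sd = stats::sd(r2s))
  }
  out <- NULL
  for (resp in params) {
    cand <- setdiff(params, resp)
    chosen <- character(0)
    best <- c(mean = -Inf, sd = NA)
    while (length(chosen) < max_set && length(cand)) {
      scores <- lapply(cand, function(p)
        boot_score(resp, c(chosen, p)))
      means <- vapply(scores, `[[`, 0, "mean")
      j <- which.max(means)
      if (means[j] <= best[["mean"]] + 1e-3) break
      chosen <- c(chosen, cand[j])
      best <- scores[[j]]
      cand <- cand[-j]
      if (best[["mean"]] >= tau && best[["sd"]] <= r2_sd_max) break
    }
    sig <- length(chosen) > 0 && best[["mean"]] >= tau &&
      best[["sd"]] <= r2_sd_max
    if (length(chosen))
      out <- rbind(out, data.frame(
        response = resp, predictors = paste(chosen, collapse = ","),
        r2_mean = best[["mean"]], r2_sd = best[["sd"]],
        significant = sig))
  }
  if (is.null(out))
    out <- data.frame(response = character(0), predictors = character(0),
                      r2_mean = numeric(0), r2_sd = numeric(0),
                      significant = logical(0))
  class(out) <- c("mota_relations", "data.frame")
  out
}

#' Suggest remedies for non-identifiable parameters
#'
#' Combines the identifiability classes, detected relations, the
#' orthogonal ranking and (optionally) trajectory-variability hotspots
#' into an ordered remedy list: measure the highest-ranked member of
#' each relation touching a non-identifiable parameter; fix unranked
#' parameters to nominal values; add data at the variability hotspot of
#' practically non-identifiable parameters.
#'
#' @param classes named character vector of per-parameter classes
#'   (`"identifiable"` / `"structural"` / `"practical"`).
#' @param relations a [mota_detect()] result (may be empty).
#' @param ranking a [rank_parameters()] / [aggregate_rankings()] result.
#' @param hotspots optional named list of [trajectory_variability()]
#'   suggestions per practically non-identifiable parameter.
#' @return data frame with columns `action`, `target`, `reason`,
#'   ordered by ranking priority; zero rows when all parameters are
#'   identifiable.
#' @export
suggest_remedies <- function(classes, relations, ranking,
                             hotspots = NULL) {
  ni <- names(classes)[classes != "identifiable"]
  out <- NULL
  rank_of <- function(p) {
    i <- match(p, ranking$ranked)
    if (is.na(i)) length(ranking$ranked) + 1L else i
  }
  if (!is.null(relations) && nrow(relations)) {
    for (i in seq_len(nrow(relations))) {
      if (!isTRUE(relations$significant[i])) next
      members <- c(relations$response[i],
                   strsplit(relations$predictors[i], ",")[[1]])
      if (!any(members %in% ni)) next
      target <- members[which.min(vapply(members, rank_of, 0))]
      out <- rbind(out, data.frame(
        action = "measure", target = target,
        reason = paste0("highest-ranked member of relation {",
                        paste(members, collapse = ", "), "}"),
        priority = rank_of(target)))
    }
  }
  for (p in intersect(ranking$unranked, ni)) {
    out <- rbind(out, data.frame(
      action = "fix_nominal", target = p,
      reason = "unranked (insensitive); fix to a nominal value",
      priority = length(ranking$ranked) + 1L))
  }
  if (!is.null(hotspots)) {
    for (p in intersect(names(hotspots), ni)) {
      h <- hotspots[[p]]
      out <- rbind(out, data.frame(
        action = "add_data", target = p,
        reason = sprintf("measure %s near t = %g (envelope width %.3g)",
                         h$state, h$time, h$width),
        priority = rank_of(p)))
    }
  }
  if (is.null(out))
    out <- data.frame(action = character(0), target = character(0),
                      reason = character(0), priority = numeric(0))
  out <- out[!duplicated(out[, c("action", "target")]), ]
  out <- out[order(out$priority), ]
  rownames(out) <- NULL
  out
}
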