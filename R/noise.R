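#' Measurement-noise models for synthetic data
#'
#' Two standard noise generators for kinetic time-series data, both
#' clamped at zero so concentrations stay non-negative:
#' \describe{
#'   \item{multiplicative}{\eqn{y' = \max[0,\; y (1 + c\, r)]} with
#'     \eqn{r \sim N(0,1)} and relative scale `c_mult` (default 0.2).}
#'   \item{mixed}{\eqn{y' = \max[0,\; y + a\, r_1 + C\, r_2\, y]} with
#'     independent standard-normal \eqn{r_1, r_2}, additive floor `a_add`
#'     (default 0.1) and relative part `C` (default 0.2).}
#'   \item{none}{the identity map.}
#' }
#'
#' @param kind one of `"multiplicative"`, `"mixed"`, `"none"`.
#' @param c_mult relative noise scale of the multiplicative model.
#' @param a_add additive noise scale of the mixed model.
#' @param C relative noise scale of the mixed model.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative", "mixed", "none"),
                        c_mult = 0.2, a_add = 0.1, C = 0.2) {
  kind <- match.arg(kind)
  structure(list(kind = kind, c_mult = c_mult, a_add = a_add, C = C),
            class = "noise_model")
}

#' Apply a noise model to a time series
#'
#' Elementwise independent draws from the current RNG stream; pass `seed`
#' (or call `set.seed()`) for reproducibility.
#'
#' @param series a [kf_series()].
#' @param noise a [noise_model()].
#' @param seed optional integer seed.
#' @return a noisy `kf_series` of the same shape; values are never
#'   negative.
#' @export
apply_noise <- function(series, noise, seed = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  y <- series_values(series)
  out <- switch(noise$kind,
    none = y,
    multiplicative = y * (1 + noise$c_mult *
                            matrix(stats::rnorm(length(y)), nrow(y))),
    mixed = y + noise$a_add * matrix(stats::rnorm(length(y)), nrow(y)) +
      noise$C * matrix(stats::rnorm(length(y)), nrow(y)) * y,
    stop("unknown noise kind", call. = FALSE))
  out <- matrix(pmax(out, 0), nrow(y))
  kf_series(series$time, out, setdiff(colnames(series), "time"),
            meta = c(attr(series, "meta"), list(noise = noise$kind)))
}

#' Measurement-noise variance implied by a noise model
#'
#' Returns the per-observation variance used to build the filter's
#' measurement-noise covariance R: `(c_mult*y)^2` for the multiplicative
#' model and `a_add^2 + (C*y)^2` for the mixed model, floored at
#' `floor^2` to avoid singular R where the signal vanishes.
#'
#' @inheritParams apply_noise
#' @param y observation vector (one time point).
#' @param floor standard-deviation floor (default 0.02).
#' @return variance vector the length of `y`.
#' @export
noise_variance <- function(noise, y, floor = 0.02) {
  v <- switch(noise$kind,
    none = rep(floor^2, length(y)),
    multiplicative = (noise$c_mult * y)^2,
    mixed = noise$a_add^2 + (noise$C * y)^2,
    stop("unknown noise kind", call. = FALSE))
  pmax(v, floor^2)
}
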