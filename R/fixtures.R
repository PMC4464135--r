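# Synthetic kinetic fixtures: identifiable, structurally and practically
# non-identifiable models, plus the two experiment-style data bundles.
# Every fixture constructs programmatically (no data files) and carries
# theta_true so clean data can always be regenerated.

#' Specify a synthetic fixture
#'
#' @param model_id one of `"mm_chain"` (2-state Michaelis-Menten chain,
#'   both parameters identifiable under dense data), `"product_ni"`
#'   (\eqn{\dot x = -\theta_1\theta_2 x}; only the product is
#'   identifiable), `"practical_ni"` (Michaelis-Menten operated far below
#'   Km, so only Vmax/Km is well constrained), `"grn_small"` (3-gene
#'   cascade with Hill-type mRNA synthesis and linear degradation /
#'   translation), `"constant"` (zero vector field).
#' @param overrides named list/vector overriding `theta_true` entries or
#'   `x0`.
#' @param noise a [noise_model()]; default multiplicative, c = 0.2.
#' @param grid measurement time grid; each model has a sensible default.
#' @param seed integer seed for the noise stream.
#' @param mutant for `grn_small`: if `TRUE`, scale the translation rate
#'   `rbs2` by 2 (the increased-RBS-activity analog).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(model_id = c("mm_chain", "product_ni",
                                      "practical_ni", "grn_small",
                                      "constant"),
                         overrides = NULL, noise = noise_model("multiplicative"),
                         grid = NULL, seed = 1L, mutant = FALSE) {
  model_id <- match.arg(model_id)
  structure(list(model_id = model_id, overrides = overrides, noise = noise,
                 grid = grid, seed = seed, mutant = mutant),
            class = "fixture_spec")
}

fixture_defaults <- function(model_id) {
  switch(model_id,
    mm_chain = list(grid = seq(0.5, 45, by = 0.5)),
    product_ni = list(grid = seq(0.5, 10, by = 0.5)),
    practical_ni = list(grid = seq(2, 40, by = 2)),
    grn_small = list(grid = 0:20),
    constant = list(grid = seq(1, 10, by = 1)))
}

build_fixture_model <- function(model_id, overrides = NULL,
                                mutant = FALSE) {
  m <- switch(model_id,
    mm_chain = kinetic_model(
      "mm_chain",
      rhs = function(x, theta, t) {
        v <- theta[["Vmax"]] * x[["S"]] / (theta[["Km"]] + x[["S"]])
        c(-v, v)
      },
      state_names = c("S", "P"), param_names = c("Vmax", "Km"),
      x0 = c(S = 3, P = 0),
      theta_true = c(Vmax = 0.1, Km = 0.3)),
    product_ni = kinetic_model(
      "product_ni",
      rhs = function(x, theta, t)
        c(-theta[["th1"]] * theta[["th2"]] * x[["x"]]),
      state_names = "x", param_names = c("th1", "th2"),
      x0 = c(x = 1), theta_true = c(th1 = 0.6, th2 = 0.5)),
    practical_ni = kinetic_model(
      "practical_ni",
      rhs = function(x, theta, t) {
        v <- theta[["Vmax"]] * x[["S"]] / (theta[["Km"]] + x[["S"]])
        c(-v, v)
      },
      state_names = c("S", "P"), param_names = c("Vmax", "Km"),
      x0 = c(S = 0.1, P = 0),
      theta_true = c(Vmax = 1, Km = 5)),
    grn_small = {
      th <- c(pro1 = 3, pro2 = 5, pro3 = 6,
              rbs1 = 4, rbs2 = 5, rbs3 = 3,
              p_deg = 0.8, Kd1 = 1, h1 = 2, Kd2 = 1, h2 = 2,
              m_deg = 1)
      # the mutant doubles the rbs2 activity as a known perturbation of
      # the shared underlying parameter (the estimated value is the
      # same quantity in both conditions)
      rbs2_scale <- if (mutant) 2 else 1
      kinetic_model(
        if (mutant) "grn_small_mutant" else "grn_small",
        rhs = function(x, theta, t) {
          act <- x[["p1"]]^theta[["h1"]] /
            (theta[["Kd1"]]^theta[["h1"]] + x[["p1"]]^theta[["h1"]])
          rep_ <- theta[["Kd2"]]^theta[["h2"]] /
            (theta[["Kd2"]]^theta[["h2"]] + x[["p2"]]^theta[["h2"]])
          c(theta[["pro1"]] - theta[["m_deg"]] * x[["m1"]],
            theta[["rbs1"]] * x[["m1"]] - theta[["p_deg"]] * x[["p1"]],
            theta[["pro2"]] * act - theta[["m_deg"]] * x[["m2"]],
            rbs2_scale * theta[["rbs2"]] * x[["m2"]] -
              theta[["p_deg"]] * x[["p2"]],
            theta[["pro3"]] * rep_ - theta[["m_deg"]] * x[["m3"]],
            theta[["rbs3"]] * x[["m3"]] - theta[["p_deg"]] * x[["p3"]])
        },
        state_names = c("m1", "p1", "m2", "p2", "m3", "p3"),
        param_names = names(th),
        x0 = c(m1 = 0, p1 = 0, m2 = 0, p2 = 0, m3 = 0, p3 = 0),
        theta_true = th,
        fixed_params = c(m_deg = 1))
    },
    constant = kinetic_model(
      "constant",
      rhs = function(x, theta, t) c(0, 0),
      state_names = c("A", "B"), param_names = character(0),
      x0 = c(A = 1, B = 2), theta_true = NULL),
    stop("unknown model_id '", model_id, "'", call. = FALSE))
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    th_ov <- intersect(names(ov), m$param_names)
    x_ov <- intersect(names(ov), m$state_names)
    if (length(th_ov)) m$theta_true[th_ov] <- ov[th_ov]
    if (length(x_ov)) m$x0[x_ov] <- ov[x_ov]
    bad <- setdiff(names(ov), c(th_ov, x_ov))
    if (length(bad)) stop("unknown override(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' Build a synthetic fixture: model plus clean and noisy data
#'
#' @param spec a [fixture_spec()].
#' @return list with `model`, `clean` and `noisy` (`kf_series`), and the
#'   spec itself.
#' @examples
#' fx <- make_fixture(fixture_spec("mm_chain", seed = 3))
#' head(fx$noisy)
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  grid <- if (is.null(spec$grid)) fixture_defaults(spec$model_id)$grid
          else spec$grid
  model <- build_fixture_model(spec$model_id, spec$overrides, spec$mutant)
  theta <- model$theta_true
  if (is.null(theta)) theta <- stats::setNames(numeric(0), character(0))
  clean <- simulate(model, times = grid, theta = theta)
  set.seed(spec$seed)
  noisy <- apply_noise(clean, spec$noise)
  list(model = model, clean = clean, noisy = noisy, spec = spec)
}

#' Generate a sucrose-experiment-style dataset bundle
#'
#' Measurement grid `[0, 2340]` s with step 10 s (the initial state is
#' not a measurement, giving 234 samples), initial concentrations of
#' 1 mM, multiplicative noise `y(1 + 0.2 r)` clamped at zero, and the
#' matching measurement-noise covariance convention
#' `R = diag((0.2 y)^2)` (floored).
#'
#' @param seed integer seed.
#' @param model optional [kinetic_model()]; defaults to the
#'   Michaelis-Menten chain with rates slowed to the 2340-second window
#'   (`Vmax = 1.5e-3` mM/s, `Km = 0.3` mM).
#' @return list with `model`, `clean`, `noisy`, `R` (per-step variance
#'   list) and `noise`.
#' @export
generate_experiment1 <- function(seed = 1L, model = NULL) {
  if (is.null(model)) {
    model <- build_fixture_model("mm_chain")
    model$theta_true <- c(Vmax = 1.5e-3, Km = 0.3)
    model$x0 <- c(S = 1, P = 1)
  }
  grid <- seq(10, 2340, by = 10)
  nm <- noise_model("multiplicative", c_mult = 0.2)
  clean <- simulate(model, times = grid, theta = model$theta_true)
  set.seed(seed)
  noisy <- apply_noise(clean, nm)
  Y <- series_values(noisy)
  R <- lapply(seq_len(nrow(Y)), function(k) noise_variance(nm, Y[k, ]))
  list(model = model, clean = clean, noisy = noisy, R = R, noise = nm)
}

#' Generate a two-condition gene-network-style dataset pair
#'
#' Wild-type and mutant (translation rate `rbs2` doubled) versions of
#' the 3-gene cascade on the grid 0..20 s with step 1 s (21 samples),
#' with mixed noise `y + 0.1 r1 + 0.2 r2 y` clamped at zero and the
#' matching R convention `0.1^2 + (0.2 y)^2`.
#'
#' @param seed integer seed.
#' @return list with `wild_type` and `mutant` bundles (each `model`,
#'   `clean`, `noisy`, `R`) and the shared `noise` model.
#' @export
generate_experiment2 <- function(seed = 1L) {
  nm <- noise_model("mixed", a_add = 0.1, C = 0.2)
  grid <- 0:20
  bundle <- function(mutant, s) {
    model <- build_fixture_model("grn_small", mutant = mutant)
    clean <- simulate(model, times = grid, theta = model$theta_true)
    set.seed(s)
    noisy <- apply_noise(clean, nm)
    Y <- series_values(noisy)
    R <- lapply(seq_len(nrow(Y)), function(k) noise_variance(nm, Y[k, ]))
    list(model = model, clean = clean, noisy = noisy, R = R)
  }
  list(mutant = bundle(TRUE, seed), wild_type = bundle(FALSE, seed + 1L),
       noise = nm)
}
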