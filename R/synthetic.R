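#' Orthonormal basis of the identified temporal subspace
#'
#' The RW2 prior is improper in level and slope, so the temporal effect is
#' identified by constraining it to sum to zero and carry no linear trend.
#' This returns an orthonormal T x (T-2) basis of that subspace; projecting a
#' vector onto it (`B %*% t(B) %*% x`) removes its best-fit line.
#'
#' @param n_quarters Number of time points T (>= 3).
#' @return A T x (T-2) matrix with orthonormal columns orthogonal to both the
#'   constant and the linear trend.
#' @keywords internal
rw2_constraint_basis <- function(n_quarters) {
  if (n_quarters < 3) stop("RW2 needs at least 3 time points", call. = FALSE)
  t <- seq_len(n_quarters)
  Q <- qr.Q(qr(cbind(1, t - mean(t))), complete = TRUE)
  Q[, 3:n_quarters, drop = FALSE]
}

#' Project a temporal effect onto the identified subspace
#' @param delta Numeric vector of temporal effects.
#' @return `delta` with its best-fit line removed (sum zero, zero trend).
#' @keywords internal
project_temporal <- function(delta) {
  B <- rw2_constraint_basis(length(delta))
  drop(B %*% crossprod(B, delta))
}

#' Scenario settings for the synthetic-panel generator
#'
#' Describes the shape of a simulated surveillance panel: how many areas and
#' quarters, the census population range per area, how the covariate evolves,
#' and an optional mid-window dip in the temporal effect (emulating the
#' pandemic-era decline in notifications).
#'
#' @param n_areas Number of areas (>= 2).
#' @param n_quarters Number of quarters (>= 3; RW2 needs three points).
#' @param age_group Age-group label carried on the panel.
#' @param population_range Length-2 positive integer range for per-area census
#'   population, sampled log-uniformly (municipality sizes are heavy-tailed).
#' @param covariate_trajectory One of `"constant"`, `"linear-growth"`,
#'   `"random-walk"` for the per-area covariate path.
#' @param dip Optional list `list(start_t=, end_t=, depth=)`: a smooth bump of
#'   the given log-scale depth subtracted from the temporal effect over
#'   `[start_t, end_t]`, then re-identified.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_areas = 60, n_quarters = 12,
                            age_group = "15-19",
                            population_range = c(5000, 200000),
                            covariate_trajectory = c("linear-growth",
                                                     "constant",
                                                     "random-walk"),
                            dip = NULL) {
  covariate_trajectory <- match.arg(covariate_trajectory)
  if (n_areas < 2) stop("need at least 2 areas", call. = FALSE)
  if (n_quarters < 3) stop("RW2 needs n_quarters >= 3", call. = FALSE)
  stopifnot(length(population_range) == 2, all(population_range > 0))
  if (!is.null(dip)) {
    stopifnot(all(c("start_t", "end_t", "depth") %in% names(dip)),
              dip$start_t >= 1, dip$end_t <= n_quarters,
              dip$start_t <= dip$end_t)
  }
  structure(list(n_areas = n_areas, n_quarters = n_quarters,
                 age_group = age_group,
                 population_range = population_range,
                 covariate_trajectory = covariate_trajectory,
                 dip = dip),
            class = "scenario_config")
}

#' Draw a generating truth for a synthetic panel
#'
#' Samples the parameters of the spatiotemporal model: intercept, IID spatial
#' effects `gamma_i ~ N(0, 1/tau_gamma)`, RW2 temporal effect (second
#' differences `~ N(0, 1/tau_delta)`, re-identified to sum-zero / zero-trend),
#' and IID covariate slopes `beta_i ~ N(0, 1/tau_beta)`. Deterministic given
#' `seed`.
#'
#' @param config A [scenario_config()].
#' @param alpha Log baseline incidence rate per person-quarter.
#' @param tau_gamma,tau_delta,tau_beta Positive precisions of the effects.
#' @param family One of `"poisson"`, `"zip"`, `"negbin"`.
#' @param pi Structural zero-inflation weight in `[0, 1)` (ZIP only).
#' @param phi Positive overdispersion scale (negative binomial only); the
#'   count variance is `lambda + lambda^2 / phi`.
#' @param seed Integer seed.
#' @param planted_gamma Optional named numeric vector: spatial effects to plant
#'   at fixed values (names are area indices as integers), e.g. to create
#'   known high-risk areas for calibration experiments.
#' @return A list of class `synthetic_truth`.
#' @export
simulate_truth <- function(config, alpha = -9, tau_gamma = 4, tau_delta = 25,
                           tau_beta = 4, family = c("poisson", "zip", "negbin"),
                           pi = 0.2, phi = 1, seed = 1,
                           planted_gamma = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(config, "scenario_config"),
            tau_gamma > 0, tau_delta > 0, tau_beta > 0,
            pi >= 0, pi < 1, phi > 0)
  n <- config$n_areas
  T <- config$n_quarters
  set.seed(seed)

  gamma <- stats::rnorm(n, 0, 1 / sqrt(tau_gamma))
  if (!is.null(planted_gamma)) {
    idx <- as.integer(names(planted_gamma))
    stopifnot(all(idx >= 1 & idx <= n))
    gamma[idx] <- as.numeric(planted_gamma)
  }
  beta <- stats::rnorm(n, 0, 1 / sqrt(tau_beta))

  # RW2 draw: double cumulative sum of innovations, then identification
  innov <- stats::rnorm(T - 2, 0, 1 / sqrt(tau_delta))
  delta <- c(0, 0, cumsum(cumsum(innov)))
  if (!is.null(config$dip)) {
    d <- config$dip
    span <- d$start_t:d$end_t
    bump <- numeric(T)
    bump[span] <- d$depth * sin(seq(0, base::pi, length.out = length(span)))^2
    delta <- delta - bump
  }
  delta <- project_temporal(delta)

  structure(list(alpha = alpha, gamma = gamma, delta = delta, beta = beta,
                 tau_gamma = tau_gamma, tau_delta = tau_delta,
                 tau_beta = tau_beta, pi = pi, phi = phi,
                 family = family, seed = seed),
            class = "synthetic_truth")
}

#' Simulate an observed panel from a generating truth
#'
#' Builds the exposure and covariate surfaces from the scenario, forms the
#' expected counts `lambda[i,t] = exp(alpha + gamma_i + delta_t +
#' beta_i * I[i,t]) * offset[i,t]` and draws counts from the configured family.
#' Deterministic given the truth's seed (offset/covariate) plus `seed`
#' (counts).
#'
#' @param truth A [simulate_truth()] result.
#' @param config The matching [scenario_config()].
#' @param seed Integer seed for the count draws (defaults to `truth$seed + 1`).
#' @return A `panel_data` with attribute `truth`.
#' @export
simulate_panel <- function(truth, config, seed = truth$seed + 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "scenario_config"))
  n <- config$n_areas
  T <- config$n_quarters
  if (length(truth$gamma) != n || length(truth$delta) != T) {
    stop("truth dimensions do not match config", call. = FALSE)
  }

  set.seed(truth$seed)
  lr <- log(config$population_range)
  popn <- round(exp(stats::runif(n, lr[1], lr[2])))
  offset <- matrix(popn, n, T)

  base_cov <- stats::runif(n, 0, 0.2)   # internet points per inhabitant
  covariate <- switch(config$covariate_trajectory,
    "constant" = matrix(base_cov, n, T),
    "linear-growth" = outer(base_cov, seq(1, 1.5, length.out = T)),
    "random-walk" = {
      steps <- matrix(stats::rnorm(n * T, 0, 0.01), n, T)
      pmax(base_cov + t(apply(steps, 1, cumsum)), 0)
    })

  nu <- truth$alpha + outer(truth$gamma, rep(1, T)) +
    outer(rep(1, n), truth$delta) + truth$beta * covariate
  lam <- exp(nu) * offset

  set.seed(seed)
  y <- switch(truth$family,
    poisson = stats::rpois(n * T, lam),
    zip = {
      # Poisson branch drawn first so pi = 0 reproduces the Poisson
      # stream bit-for-bit under a common seed
      yp <- stats::rpois(n * T, lam)
      z <- stats::rbinom(n * T, 1, truth$pi)
      ifelse(z == 1, 0L, yp)
    },
    negbin = stats::rnbinom(n * T, size = truth$phi, mu = lam))
  y <- matrix(as.integer(y), n, T)

  area_ids <- sprintf("%02d%03d", rep(seq_len(ceiling(n / 50)), each = 50,
                                      length.out = n),
                      seq_len(n))
  panel <- panel_data(y, offset, covariate, area_ids = area_ids,
                      age_group = config$age_group)
  attr(panel, "truth") <- truth
  panel
}
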