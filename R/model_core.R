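#' Model specification: likelihood family, priors, identification
#'
#' @param family `"poisson"`, `"zip"` (Poisson plus a structural mass at
#'   zero) or `"negbin"` (mean-scale negative binomial, variance
#'   `lambda + lambda^2/phi`).
#' @param prior_settings Named list of hyperprior parameters; missing entries
#'   take the defaults of [default_priors()].
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson", "zip", "negbin"),
                       prior_settings = list()) {
  family <- match.arg(family)
  pr <- utils::modifyList(default_priors(), prior_settings)
  structure(list(family = family, prior_settings = pr,
                 constraint = "sum-zero, zero-linear-trend"),
            class = "model_spec")
}

#' Default hyperprior settings
#'
#' Precisions of the three random effects get diffuse Gamma(1, 5e-5) priors;
#' the intercept a vague Normal(0, var 1000); the zero-inflation weight a
#' Normal(-1, var 1) prior on its logit; the overdispersion scale a standard
#' log-normal. These keep every posterior proper while contributing almost no
#' information at surveillance sample sizes.
#'
#' @return Named list of hyperprior parameters.
#' @export
default_priors <- function() {
  list(tau_shape = 1, tau_rate = 5e-5,
       alpha_mean = 0, alpha_var = 1000,
       pi_logit_mean = -1, pi_logit_var = 1,
       log_phi_mean = 0, log_phi_var = 1)
}

#' Parameter state of the spatiotemporal model
#'
#' One point in parameter space: intercept, spatial effects, identified
#' temporal effects, covariate slopes, effect precisions, and the
#' family-specific parameters.
#'
#' @param alpha Intercept (log incidence rate per person-quarter).
#' @param gamma Numeric vector of spatial effects (length = areas).
#' @param delta Numeric vector of temporal effects; must satisfy the sum-zero
#'   and zero-linear-trend identification within 1e-8.
#' @param beta Numeric vector of covariate slopes (length = areas).
#' @param tau_gamma,tau_delta,tau_beta Positive precisions.
#' @param pi Zero-inflation weight in `[0, 1)` (ZIP only).
#' @param phi Positive overdispersion scale (negative binomial only).
#' @return A list of class `parameter_state`.
#' @export
parameter_state <- function(alpha, gamma, delta, beta,
                            tau_gamma = 1, tau_delta = 1, tau_beta = 1,
                            pi = NULL, phi = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1,
            tau_gamma > 0, tau_delta > 0, tau_beta > 0)
  if (length(gamma) != length(beta)) {
    stop("gamma and beta must have one entry per area", call. = FALSE)
  }
  resid <- delta - project_temporal(delta)
  if (max(abs(resid)) > 1e-8) {
    stop("delta violates the identification constraints (sum zero, zero linear trend)",
         call. = FALSE)
  }
  if (!is.null(pi) && (pi < 0 || pi >= 1)) {
    stop("pi must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(phi) && phi <= 0) stop("phi must be positive", call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma, delta = delta, beta = beta,
                 tau_gamma = tau_gamma, tau_delta = tau_delta,
                 tau_beta = tau_beta, pi = pi, phi = phi),
            class = "parameter_state")
}

#' Evaluate the linear predictor and derived rates
#'
#' Computes `nu[i,t] = alpha + gamma_i + delta_t + beta_i * I[i,t]`, the
#' incidence rate `rho = exp(nu)` per person-quarter and the expected count
#' `lambda = rho * offset`.
#'
#' @param state A [parameter_state()].
#' @param panel A [panel_data()].
#' @return List of class `likelihood_terms` with matrices `nu`, `rho`, `lam`.
#' @export
linear_predictor <- function(state, panel) {
  n <- panel$n_areas; T <- panel$n_quarters
  if (length(state$gamma) != n || length(state$delta) != T) {
    stop("state dimensions do not match panel", call. = FALSE)
  }
  nu <- state$alpha +
    matrix(state$gamma, n, T) +
    matrix(state$delta, n, T, byrow = TRUE) +
    state$beta * panel$covariate
  rho <- exp(nu)
  lam <- rho * panel$offset
  if (any(!is.finite(lam))) {
    bad <- which(!is.finite(lam), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expected count at area %d, quarter %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  structure(list(nu = nu, rho = rho, lam = lam), class = "likelihood_terms")
}

#' Poisson log-likelihood of a count panel
#'
#' @param y Count matrix.
#' @param lam Positive matrix of expected counts, same shape.
#' @return Total log-likelihood including all constants (`log y!` terms), so
#'   values are comparable across likelihood families.
#' @export
poisson_loglik <- function(y, lam) {
  check_counts(y, lam)
  sum(stats::dpois(y, lam, log = TRUE))
}

#' Zero-inflated Poisson log-likelihood
#'
#' A structural point mass at zero with weight `pi` is mixed with a Poisson:
#' zeros contribute `log(pi + (1-pi) exp(-lambda))` (evaluated by log-sum-exp),
#' positive counts `log(1-pi)` plus the Poisson log-mass.
#'
#' @inheritParams poisson_loglik
#' @param pi Zero-inflation weight in `[0, 1)`.
#' @export
zip_loglik <- function(y, lam, pi) {
  check_counts(y, lam)
  if (length(pi) != 1 || pi < 0 || pi >= 1) {
    stop("pi must be a scalar in [0, 1)", call. = FALSE)
  }
  sum(zip_cell_logmass(y, lam, pi))
}

#' Negative binomial log-likelihood (mean-scale form)
#'
#' Parameterised by mean `lambda` and scale `phi` so the variance is
#' `lambda + lambda^2 / phi`; equivalently size `phi` and success probability
#' `phi / (phi + lambda)`. As `phi` grows the Poisson is recovered.
#'
#' @inheritParams poisson_loglik
#' @param phi Positive overdispersion scale.
#' @export
negbin_loglik <- function(y, lam, phi) {
  check_counts(y, lam)
  if (length(phi) != 1 || phi <= 0) stop("phi must be a positive scalar", call. = FALSE)
  sum(stats::dnbinom(y, size = phi, mu = lam, log = TRUE))
}

check_counts <- function(y, lam) {
  if (!identical(dim(as.matrix(y)), dim(as.matrix(lam)))) {
    stop("y and lam must share the same shape", call. = FALSE)
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("y must contain non-negative integers", call. = FALSE)
  }
  if (any(lam <= 0)) stop("lam must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

# per-cell ZIP log-mass, log-sum-exp stabilised for the zero branch
zip_cell_logmass <- function(y, lam, pi) {
  base_mass <- stats::dpois(y, lam, log = TRUE)
  if (pi == 0) return(base_mass)
  out <- log1p(-pi) + base_mass
  z <- y == 0
  if (any(z)) {
    a <- rep(log(pi), sum(z))
    b <- log1p(-pi) - lam[z]
    m <- pmax(a, b)
    out[z] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

# per-cell log-mass dispatcher used by the sampler, DIC and WAIC
cell_logmass <- function(y, lam, family, pi = NULL, phi = NULL) {
  switch(family,
    poisson = stats::dpois(y, lam, log = TRUE),
    zip = zip_cell_logmass(y, lam, pi),
    negbin = stats::dnbinom(y, size = phi, mu = lam, log = TRUE),
    stop("unknown family: ", family, call. = FALSE))
}

#' Improper RW2 log-prior for the temporal effect
#'
#' `(T-2)/2 log(tau) - tau/2 * sum of squared second differences`; the density
#' of the order-two random walk up to an additive constant. It is invariant to
#' adding any line `a + b t`, which is why the temporal effect needs the
#' sum-zero / zero-trend identification.
#'
#' @param delta Numeric vector of length >= 3.
#' @param tau_delta Positive precision of the second differences.
#' @export
rw2_logprior <- function(delta, tau_delta) {
  T <- length(delta)
  if (T < 3) stop("RW2 needs at least 3 time points", call. = FALSE)
  if (tau_delta <= 0) stop("tau_delta must be positive", call. = FALSE)
  q <- sum(diff(delta, differences = 2)^2)
  (T - 2) / 2 * log(tau_delta) - tau_delta / 2 * q
}

#' IID Gaussian log-prior for an effect vector
#'
#' @param v Numeric vector of effects.
#' @param tau Positive precision.
#' @return `sum_i [ 0.5 log(tau) - 0.5 log(2 pi) - tau/2 v_i^2 ]`.
#' @export
iid_logprior <- function(v, tau) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  sum(stats::dnorm(v, 0, 1 / sqrt(tau), log = TRUE))
}

#' Joint log-posterior density (up to the RW2 constant)
#'
#' Likelihood of the configured family plus the IID priors on the spatial
#' effects and covariate slopes, the RW2 prior on the temporal effect, and the
#' hyperpriors: Gamma on each precision, Normal on the intercept, Normal on
#' `logit(pi)` and on `log(phi)` (with the change-of-variable Jacobians so the
#' density is with respect to the natural parameters).
#'
#' @param state A [parameter_state()]; its family-specific slots must match
#'   `spec` (`pi` iff zip, `phi` iff negbin).
#' @param panel A [panel_data()].
#' @param spec A [model_spec()].
#' @export
joint_logposterior <- function(state, panel, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "zip" && is.null(state$pi)) {
    stop("zip spec requires a state with pi", call. = FALSE)
  }
  if (spec$family == "negbin" && is.null(state$phi)) {
    stop("negbin spec requires a state with phi", call. = FALSE)
  }
  if (spec$family == "poisson" && (!is.null(state$pi) || !is.null(state$phi))) {
    stop("poisson spec does not accept pi or phi in the state", call. = FALSE)
  }
  pr <- spec$prior_settings
  lt <- linear_predictor(state, panel)
  ll <- sum(cell_logmass(panel$counts, lt$lam, spec$family,
                         pi = state$pi, phi = state$phi))
  lp <- ll +
    iid_logprior(state$gamma, state$tau_gamma) +
    rw2_logprior(state$delta, state$tau_delta) +
    iid_logprior(state$beta, state$tau_beta) +
    stats::dgamma(state$tau_gamma, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
    stats::dgamma(state$tau_delta, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
    stats::dgamma(state$tau_beta, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
    stats::dnorm(state$alpha, pr$alpha_mean, sqrt(pr$alpha_var), log = TRUE)
  if (spec$family == "zip") {
    eta <- stats::qlogis(state$pi)
    lp <- lp + stats::dnorm(eta, pr$pi_logit_mean, sqrt(pr$pi_logit_var),
                            log = TRUE) - log(state$pi) - log1p(-state$pi)
  }
  if (spec$family == "negbin") {
    lp <- lp + stats::dnorm(log(state$phi), pr$log_phi_mean,
                            sqrt(pr$log_phi_var), log = TRUE) - log(state$phi)
  }
  lp
}
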