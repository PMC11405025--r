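test_that("linear predictor assembles intercept, effects and covariate", {
  pan <- tiny_panel()
  n <- pan$n_areas; T <- pan$n_quarters

  st0 <- parameter_state(alpha = -9, gamma = numeric(n),
                         delta = numeric(T), beta = numeric(n))
  lt <- linear_predictor(st0, pan)
  expect_true(all(lt$nu == -9))
  expect_equal(lt$rho, exp(lt$nu))
  expect_equal(lt$lam, exp(lt$nu) * pan$offset)

  # hand sum: alpha 0, gamma_1 1, delta_1 2, beta_1 3, I_11 = 2 -> nu_11 = 9
  # (state built directly: linear_predictor is a pure arithmetic map and
  # does not itself impose the temporal identification)
  pan2 <- panel_data(matrix(0L, 2, 3), matrix(1, 2, 3),
                     matrix(c(2, 0, 0, 0, 0, 0), 2, 3))
  st <- structure(list(alpha = 0, gamma = c(1, 0), delta = c(2, 0, 0),
                       beta = c(3, 0)), class = "parameter_state")
  expect_equal(linear_predictor(st, pan2)$nu[1, 1], 9)

  # the per-100k inversion behind fixed-effect incidence reporting
  st35 <- structure(list(alpha = log(35 / 1e5), gamma = numeric(1),
                         delta = numeric(1), beta = numeric(1)),
                    class = "parameter_state")
  pan35 <- panel_data(matrix(0L, 1, 1), matrix(1e5, 1, 1))
  expect_equal(linear_predictor(st35, pan35)$lam[1, 1], 35, tolerance = 1e-10)
})

test_that("likelihood worked examples match hand computation", {
  expect_equal(poisson_loglik(matrix(0), matrix(1)), -1, tolerance = 1e-12)
  expect_equal(poisson_loglik(matrix(1), matrix(1)), -1, tolerance = 1e-12)
  expect_equal(poisson_loglik(matrix(3), matrix(2)),
               3 * log(2) - 2 - log(6), tolerance = 1e-10)

  expect_equal(zip_loglik(matrix(0), matrix(1), 0.5),
               log(0.5 + 0.5 * exp(-1)), tolerance = 1e-10)
  expect_equal(zip_loglik(matrix(2), matrix(1), 0.5),
               log(0.5) + (2 * log(1) - 1 - log(2)), tolerance = 1e-10)

  expect_equal(negbin_loglik(matrix(0), matrix(1), 1), log(0.5),
               tolerance = 1e-10)

  # multi-cell sums agree with the independently coded oracle
  set.seed(8)
  y <- matrix(rpois(12, 4), 3, 4)
  lam <- matrix(runif(12, 0.5, 8), 3, 4)
  expect_equal(poisson_loglik(y, lam),
               sum(oracle_cell_logmass(y, lam, "poisson")), tolerance = 1e-10)
  expect_equal(zip_loglik(y, lam, 0.25),
               sum(oracle_cell_logmass(y, lam, "zip", pi = 0.25)),
               tolerance = 1e-10)
  expect_equal(negbin_loglik(y, lam, 2.5),
               sum(oracle_cell_logmass(y, lam, "negbin", phi = 2.5)),
               tolerance = 1e-10)
})

test_that("family degeneracy limits hold", {
  set.seed(3)
  y <- matrix(rpois(20, 2), 4, 5)
  lam <- matrix(runif(20, 0.2, 5), 4, 5)
  expect_lt(abs(zip_loglik(y, lam, 0) - poisson_loglik(y, lam)), 1e-12)
  expect_lt(abs(negbin_loglik(y, lam, 1e8) - poisson_loglik(y, lam)), 1e-4)
})

test_that("likelihoods fall as lambda moves away from the data", {
  y <- matrix(5)
  lls <- sapply(c(5, 7, 10), function(l) poisson_loglik(y, matrix(l)))
  expect_true(all(diff(lls) < 0))
  lls <- sapply(c(5, 3, 1), function(l) negbin_loglik(y, matrix(l), 2))
  expect_true(all(diff(lls) < 0))
})

test_that("rw2 prior penalises curvature and ignores straight lines", {
  expect_equal(rw2_logprior(c(0, 0, 1), 2), 0.5 * log(2) - 1,
               tolerance = 1e-12)
  T <- 8
  base <- rw2_logprior(numeric(T), 3)
  expect_equal(rw2_logprior(1:T, 3), base, tolerance = 1e-10)
  for (ab in list(c(2, -1), c(-0.5, 0.3))) {
    d <- rnorm(T)
    shifted <- d + ab[1] + ab[2] * seq_len(T)
    expect_equal(rw2_logprior(d, 4), rw2_logprior(shifted, 4),
                 tolerance = 1e-8)
  }
  expect_error(rw2_logprior(c(0, 1), 1), "at least 3")
})

test_that("iid prior matches the Gaussian density and peaks at zero", {
  expect_equal(iid_logprior(0, 1), -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(iid_logprior(c(1, -1), 1), 2 * (-0.5 * log(2 * pi)) - 1,
               tolerance = 1e-10)
  for (tau in c(0.5, 4, 100)) {
    expect_gt(iid_logprior(numeric(3), tau), iid_logprior(c(0.1, 0, 0), tau))
  }
  expect_error(iid_logprior(1, 0), "positive")
})

test_that("joint posterior decomposes and dispatches by family", {
  pan <- tiny_panel()
  n <- pan$n_areas; T <- pan$n_quarters
  delta <- arealrisk:::project_temporal(rnorm(T))
  st <- parameter_state(alpha = -5.5, gamma = rnorm(n, 0, 0.3), delta = delta,
                        beta = rnorm(n, 0, 0.2), tau_gamma = 4, tau_delta = 25,
                        tau_beta = 4)
  spec <- model_spec("poisson")
  pr <- spec$prior_settings
  lt <- linear_predictor(st, pan)
  manual <- poisson_loglik(pan$counts, lt$lam) +
    iid_logprior(st$gamma, 4) + rw2_logprior(st$delta, 25) +
    iid_logprior(st$beta, 4) +
    dgamma(4, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
    dgamma(25, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
    dgamma(4, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
    dnorm(-5.5, 0, sqrt(1000), log = TRUE)
  expect_equal(joint_logposterior(st, pan, spec), manual, tolerance = 1e-10)

  # differences across alpha equal likelihood differences (priors cancel
  # except the near-flat intercept prior, included on both sides)
  st2 <- st; st2$alpha <- -5.0
  lt2 <- linear_predictor(st2, pan)
  expect_equal(
    joint_logposterior(st2, pan, spec) - joint_logposterior(st, pan, spec),
    (poisson_loglik(pan$counts, lt2$lam) + dnorm(-5, 0, sqrt(1000), log = TRUE)) -
      (poisson_loglik(pan$counts, lt$lam) + dnorm(-5.5, 0, sqrt(1000), log = TRUE)),
    tolerance = 1e-10)

  st_zip <- st; st_zip$pi <- 0.2
  expect_error(joint_logposterior(st_zip, pan, spec), "does not accept")
  expect_error(joint_logposterior(st, pan, model_spec("zip")), "requires")
})

test_that("joint posterior equals a brute-force cell sum on a small panel", {
  set.seed(17)
  pan <- panel_data(matrix(rpois(9, 2), 3, 3),
                    matrix(runif(9, 100, 500), 3, 3),
                    matrix(runif(9, 0, 0.3), 3, 3))
  delta <- arealrisk:::project_temporal(c(0.1, -0.2, 0.3))
  st <- parameter_state(alpha = -4, gamma = c(0.2, -0.1, 0), delta = delta,
                        beta = c(0.5, 0, -0.4), tau_gamma = 2, tau_delta = 9,
                        tau_beta = 3, pi = 0.15)
  spec <- model_spec("zip")
  pr <- spec$prior_settings
  brute <- 0
  for (i in 1:3) for (t in 1:3) {
    nu <- -4 + st$gamma[i] + delta[t] + st$beta[i] * pan$covariate[i, t]
    lam <- exp(nu) * pan$offset[i, t]
    y <- pan$counts[i, t]
    brute <- brute + sum(oracle_cell_logmass(matrix(y), matrix(lam), "zip",
                                             pi = 0.15))
  }
  brute <- brute + iid_logprior(st$gamma, 2) + rw2_logprior(delta, 9) +
    iid_logprior(st$beta, 3) +
    sum(dgamma(c(2, 9, 3), pr$tau_shape, rate = pr$tau_rate, log = TRUE)) +
    dnorm(-4, 0, sqrt(1000), log = TRUE) +
    dnorm(qlogis(0.15), -1, 1, log = TRUE) - log(0.15) - log(0.85)
  expect_equal(joint_logposterior(st, pan, spec), brute, tolerance = 1e-10)
})

test_that("parameter_state rejects unidentified temporal effects", {
  expect_error(parameter_state(0, numeric(2), c(1, 1, 1), numeric(2)),
               "identification")
  d_ok <- arealrisk:::project_temporal(c(1, -2, 0.5, 1))
  expect_s3_class(parameter_state(0, numeric(2), d_ok, numeric(2)),
                  "parameter_state")
})
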