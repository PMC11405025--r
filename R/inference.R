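#' Fit the spatiotemporal model by adaptive Metropolis-within-Gibbs
#'
#' Posterior inference for any family/panel pair. Precisions get closed-form
#' Gamma Gibbs updates; the intercept, spatial effects, covariate slopes,
#' temporal effect and the ZIP/NB parameters get adaptive random-walk
#' Metropolis updates (target acceptance 0.44 per scalar coordinate), with
#' adaptation frozen at the end of burn-in. The temporal effect is sampled in
#' an orthonormal basis of the identified subspace, so every stored draw
#' satisfies the sum-zero / zero-linear-trend constraints exactly. Spatial
#' effects and slopes are updated simultaneously component-wise (valid because
#' the likelihood factorises over areas and their priors are exchangeable).
#'
#' @param panel A [panel_data()].
#' @param spec A [model_spec()].
#' @param n_chains Number of independent chains (default 2).
#' @param n_iter Total iterations per chain.
#' @param n_burn Burn-in iterations discarded per chain (default `n_iter/2`).
#' @param thin Keep every `thin`-th post-burn-in iteration (default 5).
#' @param seed Root seed; chain `c` runs on a stream seeded
#'   `(seed * 1000 + c) mod (2^31 - 1)`, so runs are reproducible.
#' @param init Named list overriding initial values (`alpha`, `gamma`,
#'   `delta`, `beta`, `tau_gamma`, `tau_delta`, `tau_beta`, `pi`, `phi`).
#' @param clamp Character vector among `"gamma"`, `"delta"`, `"beta"`,
#'   `"pi"`, `"phi"`: hold those components fixed at their initial values
#'   (clamping an effect vector also freezes its precision). Used for
#'   intercept-only reference fits.
#' @return An object of class `posterior_draws`.
#' @export
fit_panel <- function(panel, spec, n_chains = 2, n_iter = 2000,
                      n_burn = floor(n_iter / 2), thin = 5, seed = 1,
                      init = list(), clamp = character()) {
  stopifnot(inherits(panel, "panel_data"), inherits(spec, "model_spec"),
            n_iter > n_burn, n_chains >= 1, thin >= 1)
  bad <- setdiff(clamp, c("gamma", "delta", "beta", "pi", "phi"))
  if (length(bad) > 0) stop("unknown clamp component(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)

  chains <- lapply(seq_len(n_chains), function(ch) {
    run_chain(panel, spec, n_iter, n_burn, thin,
              chain_seed = (seed * 1000 + ch) %% 2147483647L,
              init = init, clamp = clamp, chain_id = ch)
  })

  keep <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  keepv <- function(name) unlist(lapply(chains, `[[`, name), use.names = FALSE)
  n_kept <- length(chains[[1]]$alpha)

  structure(list(
    alpha = keepv("alpha"),
    gamma = keep("gamma"),
    delta = keep("delta"),
    beta = keep("beta"),
    tau_gamma = keepv("tau_gamma"),
    tau_delta = keepv("tau_delta"),
    tau_beta = keepv("tau_beta"),
    pi = if (spec$family == "zip") keepv("pi") else NULL,
    phi = if (spec$family == "negbin") keepv("phi") else NULL,
    chain = rep(seq_len(n_chains), each = n_kept),
    iter = rep(chains[[1]]$kept_iters, times = n_chains),
    n_chains = n_chains,
    n_kept = n_kept,
    seed = seed,
    acceptance_rates = lapply(chains, `[[`, "acceptance"),
    spec = spec,
    clamp = clamp,
    area_ids = panel$area_ids,
    age_group = panel$age_group
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<posterior_draws> family %s: %d chains x %d kept draws (%d areas, %d quarters)\n",
    x$spec$family, x$n_chains, x$n_kept, ncol(x$gamma), ncol(x$delta)))
  invisible(x)
}

# one MCMC chain; returns kept draws and acceptance bookkeeping
run_chain <- function(panel, spec, n_iter, n_burn, thin, chain_seed, init,
                      clamp, chain_id) {
  set.seed(chain_seed)
  y <- panel$counts; off <- panel$offset; I <- panel$covariate
  n <- panel$n_areas; T <- panel$n_quarters
  family <- spec$family
  pr <- spec$prior_settings
  if (T >= 3) {
    B <- rw2_constraint_basis(T)
    D2 <- diff(diag(T), differences = 2)        # second-difference operator
  } else {
    if (!("delta" %in% clamp)) {
      stop("panels with fewer than 3 quarters need the temporal effect clamped",
           call. = FALSE)
    }
    B <- matrix(0, T, 0)
    D2 <- matrix(0, 0, T)
  }
  K <- ncol(B)

  # --- initial state (crude moment-matching, inside the support) ---
  tot <- sum(y)
  alpha <- if (!is.null(init$alpha)) init$alpha else
    log((tot + 0.5 * (tot == 0)) / sum(off))
  gamma <- if (!is.null(init$gamma)) init$gamma else numeric(n)
  beta <- if (!is.null(init$beta)) init$beta else numeric(n)
  u <- if (!is.null(init$delta)) drop(crossprod(B, init$delta)) else numeric(K)
  delta <- drop(B %*% u)
  tau_gamma <- if (!is.null(init$tau_gamma)) init$tau_gamma else 10
  tau_delta <- if (!is.null(init$tau_delta)) init$tau_delta else 10
  tau_beta <- if (!is.null(init$tau_beta)) init$tau_beta else 10
  pi <- if (!is.null(init$pi)) init$pi else 0.1
  phi <- if (!is.null(init$phi)) init$phi else 1
  eta <- stats::qlogis(pi)
  lphi <- log(phi)

  up_gamma <- !("gamma" %in% clamp)
  up_delta <- !("delta" %in% clamp)
  up_beta <- !("beta" %in% clamp)
  up_pi <- family == "zip" && !("pi" %in% clamp)
  up_phi <- family == "negbin" && !("phi" %in% clamp)

  fam_pi <- if (family == "zip") pi else NULL
  fam_phi <- if (family == "negbin") phi else NULL
  lam <- exp(alpha + matrix(gamma, n, T) + matrix(delta, n, T, byrow = TRUE) +
               beta * I) * off
  cll <- cell_logmass(y, lam, family, pi = fam_pi, phi = fam_phi)
  if (!all(is.finite(cll))) {
    stop("non-finite log posterior at initialization (check offsets/init)",
         call. = FALSE)
  }
  Dd <- drop(D2 %*% delta)

  # --- adaptive proposal scales (log sd), one per scalar coordinate ---
  ls_a <- log(0.1)
  ls_g <- rep(log(0.1), n)
  ls_b <- rep(log(0.1), n)
  ls_u <- rep(log(0.1), K)
  ls_p <- log(0.3); ls_f <- log(0.3); ls_s <- log(0.1); ls_v <- log(0.3)
  acc_s <- att_s <- 0
  acc_v <- att_v <- 0
  acc_a <- att_a <- 0
  acc_g <- att_g <- numeric(n)
  acc_b <- att_b <- numeric(n)
  acc_u <- att_u <- numeric(K)
  acc_p <- att_p <- acc_f <- att_f <- 0
  post_acc <- list(alpha = c(0, 0), gamma = c(0, 0), delta = c(0, 0),
                   beta = c(0, 0), aux = c(0, 0))
  batch <- 0
  target <- 0.44

  kept_iters <- seq.int(n_burn + thin, n_iter, by = thin)
  S <- length(kept_iters)
  out <- list(alpha = numeric(S), gamma = matrix(0, S, n),
              delta = matrix(0, S, T), beta = matrix(0, S, n),
              tau_gamma = numeric(S), tau_delta = numeric(S),
              tau_beta = numeric(S), pi = numeric(S), phi = numeric(S))
  s_ix <- 0

  for (it in seq_len(n_iter)) {
    post <- it > n_burn

    ## intercept
    da <- stats::rnorm(1, 0, exp(ls_a))
    lam2 <- lam * exp(da)
    cll2 <- cell_logmass(y, lam2, family, pi = fam_pi, phi = fam_phi)
    logr <- sum(cll2) - sum(cll) +
      stats::dnorm(alpha + da, pr$alpha_mean, sqrt(pr$alpha_var), log = TRUE) -
      stats::dnorm(alpha, pr$alpha_mean, sqrt(pr$alpha_var), log = TRUE)
    att_a <- att_a + 1
    if (post) post_acc$alpha[2] <- post_acc$alpha[2] + 1
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      alpha <- alpha + da; lam <- lam2; cll <- cll2
      acc_a <- acc_a + 1
      if (post) post_acc$alpha[1] <- post_acc$alpha[1] + 1
    }

    ## spatial effects: simultaneous component-wise MH (rows independent)
    if (up_gamma) {
      d <- stats::rnorm(n, 0, exp(ls_g))
      lam2 <- lam * exp(d)
      cll2 <- cell_logmass(y, lam2, family, pi = fam_pi, phi = fam_phi)
      dr <- rowSums(cll2) - rowSums(cll) -
        tau_gamma / 2 * ((gamma + d)^2 - gamma^2)
      acc <- is.finite(dr) & log(stats::runif(n)) < dr
      gamma[acc] <- gamma[acc] + d[acc]
      lam[acc, ] <- lam2[acc, ]
      cll[acc, ] <- cll2[acc, ]
      att_g <- att_g + 1; acc_g <- acc_g + acc
      if (post) post_acc$gamma <- post_acc$gamma + c(sum(acc), n)
    }

    ## covariate slopes: same structure, per-row
    if (up_beta) {
      d <- stats::rnorm(n, 0, exp(ls_b))
      lam2 <- lam * exp(d * I)
      cll2 <- cell_logmass(y, lam2, family, pi = fam_pi, phi = fam_phi)
      dr <- rowSums(cll2) - rowSums(cll) -
        tau_beta / 2 * ((beta + d)^2 - beta^2)
      acc <- is.finite(dr) & log(stats::runif(n)) < dr
      beta[acc] <- beta[acc] + d[acc]
      lam[acc, ] <- lam2[acc, ]
      cll[acc, ] <- cll2[acc, ]
      att_b <- att_b + 1; acc_b <- acc_b + acc
      if (post) post_acc$beta <- post_acc$beta + c(sum(acc), n)
    }

    ## level interchange: alpha + d, gamma - d leaves the likelihood
    ## untouched (only alpha + gamma_i enters); the move trades level
    ## between the intercept and the spatial field under their priors,
    ## breaking the random-walk bottleneck on the confounded direction
    if (up_gamma) {
      d <- stats::rnorm(1, 0, exp(ls_s))
      logr <- stats::dnorm(alpha + d, pr$alpha_mean, sqrt(pr$alpha_var), log = TRUE) -
        stats::dnorm(alpha, pr$alpha_mean, sqrt(pr$alpha_var), log = TRUE) -
        tau_gamma / 2 * (sum((gamma - d)^2) - sum(gamma^2))
      att_s <- att_s + 1
      if (post) post_acc$alpha[2] <- post_acc$alpha[2] + 1
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        alpha <- alpha + d; gamma <- gamma - d
        acc_s <- acc_s + 1
        if (post) post_acc$alpha[1] <- post_acc$alpha[1] + 1
      }
    }

    ## temporal effect in the constrained basis, coordinate by coordinate
    if (up_delta) {
      for (k in seq_len(K)) {
        du <- stats::rnorm(1, 0, exp(ls_u[k]))
        delta2 <- delta + du * B[, k]
        lam2 <- lam * matrix(exp(du * B[, k]), n, T, byrow = TRUE)
        cll2 <- cell_logmass(y, lam2, family, pi = fam_pi, phi = fam_phi)
        Dd2 <- drop(D2 %*% delta2)
        logr <- sum(cll2) - sum(cll) -
          tau_delta / 2 * (sum(Dd2^2) - sum(Dd^2))
        att_u[k] <- att_u[k] + 1
        if (post) post_acc$delta[2] <- post_acc$delta[2] + 1
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          u[k] <- u[k] + du; delta <- delta2; Dd <- Dd2
          lam <- lam2; cll <- cll2
          acc_u[k] <- acc_u[k] + 1
          if (post) post_acc$delta[1] <- post_acc$delta[1] + 1
        }
      }
    }

    ## precision Gibbs steps (closed-form Gamma full conditionals)
    if (up_gamma) {
      tau_gamma <- gibbs_precision(gamma, pr$tau_shape, pr$tau_rate)
    }
    if (up_beta) {
      tau_beta <- gibbs_precision(beta, pr$tau_shape, pr$tau_rate)
    }
    if (up_delta) {
      tau_delta <- stats::rgamma(1, shape = pr$tau_shape + (T - 2) / 2,
                                 rate = pr$tau_rate + sum(Dd^2) / 2)
    }

    ## joint rescaling of the covariate slopes and their precision:
    ## beta -> beta e^s, tau_beta -> tau_beta e^{-2s}. The IID-prior
    ## quadratic form is invariant, so the move walks along the funnel
    ## direction that couples weakly identified slopes to tau_beta
    if (up_beta) {
      s <- stats::rnorm(1, 0, exp(ls_v))
      beta2 <- beta * exp(s)
      tau_b2 <- tau_beta * exp(-2 * s)
      lam2 <- lam * exp((beta2 - beta) * I)
      cll2 <- cell_logmass(y, lam2, family, pi = fam_pi, phi = fam_phi)
      logr <- sum(cll2) - sum(cll) - 2 * s +
        (pr$tau_shape - 1) * (-2 * s) - pr$tau_rate * (tau_b2 - tau_beta)
      att_v <- att_v + 1
      if (post) post_acc$beta[2] <- post_acc$beta[2] + 1
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        beta <- beta2; tau_beta <- tau_b2; lam <- lam2; cll <- cll2
        acc_v <- acc_v + 1
        if (post) post_acc$beta[1] <- post_acc$beta[1] + 1
      }
    }

    ## ZIP mixing weight on the logit scale
    if (up_pi) {
      de <- stats::rnorm(1, 0, exp(ls_p))
      pi2 <- stats::plogis(eta + de)
      cll2 <- cell_logmass(y, lam, family, pi = pi2)
      logr <- sum(cll2) - sum(cll) +
        stats::dnorm(eta + de, pr$pi_logit_mean, sqrt(pr$pi_logit_var), log = TRUE) -
        stats::dnorm(eta, pr$pi_logit_mean, sqrt(pr$pi_logit_var), log = TRUE)
      att_p <- att_p + 1
      if (post) post_acc$aux[2] <- post_acc$aux[2] + 1
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        eta <- eta + de; pi <- pi2; fam_pi <- pi2; cll <- cll2
        acc_p <- acc_p + 1
        if (post) post_acc$aux[1] <- post_acc$aux[1] + 1
      }
    }

    ## NB overdispersion on the log scale
    if (up_phi) {
      df <- stats::rnorm(1, 0, exp(ls_f))
      phi2 <- exp(lphi + df)
      cll2 <- cell_logmass(y, lam, family, phi = phi2)
      logr <- sum(cll2) - sum(cll) +
        stats::dnorm(lphi + df, pr$log_phi_mean, sqrt(pr$log_phi_var), log = TRUE) -
        stats::dnorm(lphi, pr$log_phi_mean, sqrt(pr$log_phi_var), log = TRUE)
      att_f <- att_f + 1
      if (post) post_acc$aux[2] <- post_acc$aux[2] + 1
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        lphi <- lphi + df; phi <- phi2; fam_phi <- phi2; cll <- cll2
        acc_f <- acc_f + 1
        if (post) post_acc$aux[1] <- post_acc$aux[1] + 1
      }
    }

    ## batch adaptation, frozen after burn-in
    if (!post && it %% 50 == 0) {
      batch <- batch + 1
      step <- min(0.1, 1 / sqrt(batch))
      ls_a <- ls_a + step * sign(acc_a / att_a - target)
      if (att_s > 0) ls_s <- ls_s + step * sign(acc_s / att_s - target)
      if (att_v > 0) ls_v <- ls_v + step * sign(acc_v / att_v - target)
      if (up_gamma) ls_g <- ls_g + step * sign(acc_g / att_g - target)
      if (up_beta) ls_b <- ls_b + step * sign(acc_b / att_b - target)
      if (up_delta) ls_u <- ls_u + step * sign(acc_u / att_u - target)
      if (up_pi && att_p > 0) ls_p <- ls_p + step * sign(acc_p / att_p - target)
      if (up_phi && att_f > 0) ls_f <- ls_f + step * sign(acc_f / att_f - target)
      acc_a <- att_a <- 0; acc_s <- att_s <- 0; acc_v <- att_v <- 0
      acc_g[] <- att_g[] <- 0; acc_b[] <- att_b[] <- 0
      acc_u[] <- att_u[] <- 0
      acc_p <- att_p <- acc_f <- att_f <- 0
    }

    if (post && (it - n_burn) %% thin == 0) {
      s_ix <- s_ix + 1
      out$alpha[s_ix] <- alpha
      out$gamma[s_ix, ] <- gamma
      out$delta[s_ix, ] <- delta
      out$beta[s_ix, ] <- beta
      out$tau_gamma[s_ix] <- tau_gamma
      out$tau_delta[s_ix] <- tau_delta
      out$tau_beta[s_ix] <- tau_beta
      out$pi[s_ix] <- pi
      out$phi[s_ix] <- phi
    }
  }

  out$kept_iters <- kept_iters
  out$acceptance <- vapply(post_acc, function(x)
    if (x[2] > 0) x[1] / x[2] else NA_real_, numeric(1))
  out
}

#' Gamma full-conditional draw for an IID effect precision
#'
#' Given an effect vector `v` with prior `v_i ~ N(0, 1/tau)` and hyperprior
#' `tau ~ Gamma(shape, rate)`, the full conditional is
#' `Gamma(shape + length(v)/2, rate + sum(v^2)/2)`.
#'
#' @param v Current effect vector.
#' @param shape,rate Hyperprior parameters.
#' @return One draw of the precision.
#' @export
gibbs_precision <- function(v, shape, rate) {
  stats::rgamma(1, shape = shape + length(v) / 2, rate = rate + sum(v^2) / 2)
}

# flatten draws into an iterations x parameters matrix per chain
draws_matrix_by_chain <- function(draws) {
  scalars <- cbind(alpha = draws$alpha,
                   tau_gamma = draws$tau_gamma,
                   tau_delta = draws$tau_delta,
                   tau_beta = draws$tau_beta)
  if (!is.null(draws$pi)) scalars <- cbind(scalars, pi = draws$pi)
  if (!is.null(draws$phi)) scalars <- cbind(scalars, phi = draws$phi)
  g <- draws$gamma; colnames(g) <- paste0("gamma[", seq_len(ncol(g)), "]")
  d <- draws$delta; colnames(d) <- paste0("delta[", seq_len(ncol(d)), "]")
  b <- draws$beta; colnames(b) <- paste0("beta[", seq_len(ncol(b)), "]")
  full <- cbind(scalars, g, d, b)
  lapply(seq_len(draws$n_chains), function(ch)
    full[draws$chain == ch, , drop = FALSE])
}

#' Convergence diagnostics for a fitted model
#'
#' Split-\eqn{\hat{R}} (each chain halved, between/within variance ratio) and
#' an autocorrelation-based effective sample size per scalar parameter.
#' Parameters with \eqn{\hat{R}} above the threshold are flagged; degenerate
#' zero-variance parameters (e.g. clamped components) are flagged as
#' undefined rather than failing.
#'
#' @param draws A [fit_panel()] result.
#' @param rhat_threshold Flagging threshold (default 1.05).
#' @return List of class `mcmc_diagnostics` with `rhat`, `ess`, `flags`.
#' @export
diagnose <- function(draws, rhat_threshold = 1.05) {
  stopifnot(inherits(draws, "posterior_draws"))
  by_chain <- draws_matrix_by_chain(draws)
  pnames <- colnames(by_chain[[1]])
  single <- draws$n_chains < 2
  if (single) {
    warning("R-hat undefined with a single chain; reporting ESS only",
            call. = FALSE)
  }

  rhat <- vapply(pnames, function(p) {
    if (single) return(NA_real_)
    halves <- unlist(lapply(by_chain, function(m) {
      x <- m[, p]
      h <- floor(length(x) / 2)
      list(x[seq_len(h)], x[(h + 1):(2 * h)])
    }), recursive = FALSE)
    split_rhat(halves)
  }, numeric(1))

  ess <- vapply(pnames, function(p) {
    sum(vapply(by_chain, function(m) ess_one(m[, p]), numeric(1)))
  }, numeric(1))

  flags <- pnames[is.nan(rhat) | (!is.na(rhat) & rhat > rhat_threshold)]
  undefined <- pnames[is.nan(rhat)]
  structure(list(rhat = rhat, ess = ess, flags = flags,
                 undefined = undefined, threshold = rhat_threshold),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat(sprintf("<mcmc_diagnostics> %d parameters; max R-hat %.3f; %d flagged\n",
              length(x$rhat), suppressWarnings(max(x$rhat, na.rm = TRUE)),
              length(x$flags)))
  invisible(x)
}

# split-Rhat over a list of equal-length sequences
split_rhat <- function(seqs) {
  m <- length(seqs); len <- length(seqs[[1]])
  if (len < 2) return(NA_real_)
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  Bv <- len * stats::var(means)
  if (W == 0) return(NaN)               # degenerate constant chains
  sqrt(((len - 1) / len * W + Bv / len) / W)
}

# initial-positive-sequence ESS for one chain
ess_one <- function(x) {
  S <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  maxlag <- min(S - 1, 200)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(ac) - 1) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- S / (1 + 2 * s)
  min(ess, S)
}

#' Export posterior draws to CSV with a JSON sidecar
#'
#' Writes one long-format CSV (`chain`, `iter`, `parameter`, `value`) and a
#' JSON sidecar recording the family, seed, chain geometry and a diagnostics
#' summary.
#'
#' @param draws A [fit_panel()] result.
#' @param path Output CSV path; the sidecar gets the same path with a
#'   `.json` extension.
#' @return Invisibly, the two paths written.
#' @export
export_draws <- function(draws, path) {
  by_chain <- draws_matrix_by_chain(draws)
  long <- do.call(rbind, lapply(seq_along(by_chain), function(ch) {
    m <- by_chain[[ch]]
    data.frame(chain = ch,
               iter = rep(draws$iter[draws$chain == ch], times = ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  dg <- suppressWarnings(diagnose(draws))
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, ".json")
  jsonlite::write_json(list(
    family = draws$spec$family,
    seed = draws$seed,
    n_chains = draws$n_chains,
    n_kept = draws$n_kept,
    clamp = draws$clamp,
    max_rhat = if (all(is.na(dg$rhat))) NA else
      max(dg$rhat[is.finite(dg$rhat)], na.rm = TRUE),
    min_ess = if (all(is.na(dg$ess))) NA else min(dg$ess, na.rm = TRUE),
    flagged = dg$flags
  ), side, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(path, side))
}
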