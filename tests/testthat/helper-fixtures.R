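# In-code fixtures shared across test files. Everything is generated at test
# time; nothing binary ships with the package.

# a small valid panel with fixed counts for deterministic checks
tiny_panel <- function(n = 3, T = 4, seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(n * T, 3), n, T)
  offset <- matrix(round(runif(n * T, 500, 2000)), n, T)
  covariate <- matrix(runif(n * T, 0, 0.2), n, T)
  panel_data(counts, offset, covariate,
             area_ids = sprintf("05%03d", seq_len(n)), age_group = "15-19")
}

# write a line-list CSV; rows is a character vector of raw CSV lines
write_linelist <- function(rows, header = "date,municipality,age,sex") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(header, rows), path)
  path
}

# population table covering the given codes for all six groups
pop_table <- function(codes, pop = 10000) {
  expand.grid(municipality_code = codes, age_group = age_groups()$label,
              stringsAsFactors = FALSE) |>
    transform(population = pop)
}

# hand-coded per-cell log-masses, independent of the package internals;
# used as the brute-force oracle for likelihoods, DIC/WAIC and posteriors
oracle_cell_logmass <- function(y, lam, family, pi = NULL, phi = NULL) {
  if (family == "poisson") {
    return(y * log(lam) - lam - lfactorial(y))
  }
  if (family == "zip") {
    out <- log(1 - pi) + y * log(lam) - lam - lfactorial(y)
    out[y == 0] <- log(pi + (1 - pi) * exp(-lam[y == 0]))
    return(out)
  }
  if (family == "negbin") {
    p <- phi / (phi + lam)
    return(lgamma(y + phi) - lgamma(phi) - lfactorial(y) +
             phi * log(p) + y * log1p(-p))
  }
  stop("unknown family")
}

# 1-D quadrature posterior for an intercept-only model: returns the posterior
# mean and sd of alpha given the panel, family and clamped nuisance values
oracle_intercept_posterior <- function(panel, family, pi = NULL, phi = NULL,
                                       alpha_prior_var = 1000,
                                       lo = -12, hi = 0, m = 20001) {
  grid <- seq(lo, hi, length.out = m)
  logpost <- vapply(grid, function(a) {
    lam <- exp(a) * panel$offset
    sum(oracle_cell_logmass(panel$counts, lam, family, pi, phi)) +
      dnorm(a, 0, sqrt(alpha_prior_var), log = TRUE)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  mu <- sum(w * grid)
  list(mean = mu, sd = sqrt(sum(w * (grid - mu)^2)))
}
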