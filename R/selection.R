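# Posterior-draw log-mass machinery shared by DIC and WAIC. Returns an
# S x (n*T) matrix of per-cell log-masses (one row per draw) and the
# cell-wise posterior mean of the expected count, used as the DIC plug-in.
draw_cell_logmass <- function(draws, panel) {
  spec <- draws$spec
  y <- panel$counts
  n <- panel$n_areas; T <- panel$n_quarters
  S <- length(draws$alpha)
  out <- matrix(0, S, n * T)
  lam_sum <- matrix(0, n, T)
  for (s in seq_len(S)) {
    nu <- draws$alpha[s] + matrix(draws$gamma[s, ], n, T) +
      matrix(draws$delta[s, ], n, T, byrow = TRUE) +
      draws$beta[s, ] * panel$covariate
    lam <- exp(nu) * panel$offset
    lam_sum <- lam_sum + lam
    out[s, ] <- as.vector(cell_logmass(
      y, lam, spec$family,
      pi = if (spec$family == "zip") draws$pi[s] else NULL,
      phi = if (spec$family == "negbin") draws$phi[s] else NULL))
  }
  list(logmass = out, lam_bar = lam_sum / S)
}

#' Deviance information criterion from posterior draws
#'
#' `DIC = 2 * mean(D(theta_s)) - D(theta_bar)` with `D = -2 loglik` (full
#' log-masses, constants included, so families are comparable). The plug-in
#' deviance is evaluated at the cell-wise posterior mean of the expected count
#' `lambda`, with the ZIP weight and NB scale averaged on the logit and log
#' scales respectively. `p_DIC = mean(D) - D(theta_bar)` is the effective
#' parameter count.
#'
#' @param draws A [fit_panel()] result.
#' @param panel The panel the model was fitted to.
#' @param spec The matching [model_spec()]; must agree with the draws' family.
#' @return List with `dic` and `p_dic`.
#' @export
compute_dic <- function(draws, panel, spec = draws$spec) {
  if (!identical(spec$family, draws$spec$family)) {
    stop("spec family does not match the draws", call. = FALSE)
  }
  dm <- draw_cell_logmass(draws, panel)
  dev <- -2 * rowSums(dm$logmass)
  pi_bar <- if (!is.null(draws$pi))
    stats::plogis(mean(stats::qlogis(draws$pi))) else NULL
  phi_bar <- if (!is.null(draws$phi)) exp(mean(log(draws$phi))) else NULL
  d_hat <- -2 * sum(cell_logmass(panel$counts, dm$lam_bar, spec$family,
                                 pi = pi_bar, phi = phi_bar))
  list(dic = 2 * mean(dev) - d_hat, p_dic = mean(dev) - d_hat)
}

#' Watanabe-Akaike information criterion from posterior draws
#'
#' Per cell: `lppd = log mean_s exp(log p(y | theta_s))` (log-sum-exp
#' stabilised) and a penalty equal to the sample variance (divisor `S - 1`) of
#' the per-draw log-masses; `WAIC = -2 * sum(lppd - penalty)`.
#'
#' @inheritParams compute_dic
#' @return List with `waic`, `p_waic` and `lppd` (the summed log pointwise
#'   predictive density).
#' @export
compute_waic <- function(draws, panel, spec = draws$spec) {
  if (!identical(spec$family, draws$spec$family)) {
    stop("spec family does not match the draws", call. = FALSE)
  }
  cl <- draw_cell_logmass(draws, panel)$logmass
  S <- nrow(cl)
  if (S < 2) stop("WAIC needs at least 2 draws", call. = FALSE)
  m <- apply(cl, 2, max)
  lppd_cell <- m + log(colMeans(exp(sweep(cl, 2, m)))) # log-sum-exp
  p_cell <- apply(cl, 2, stats::var)
  list(waic = -2 * sum(lppd_cell - p_cell),
       p_waic = sum(p_cell),
       lppd = sum(lppd_cell))
}

#' Select the best-fitting likelihood family by lowest DIC
#'
#' Ties (within exact equality) break toward the simpler family in the order
#' poisson, negbin, zip, with a note recorded in the report.
#'
#' @param reports Named list of per-family criterion lists, each with at least
#'   `dic` (and optionally `waic`, `p_dic`, `p_waic`, `lppd`), all computed on
#'   the same panel.
#' @param age_group Optional label carried into the report.
#' @return List of class `selection_report` with the per-family table, the
#'   `selected_family` and a `tie` note when applicable.
#' @export
select_model <- function(reports, age_group = NA_character_) {
  if (length(reports) < 2) {
    stop("model selection needs at least two fitted families on the same panel",
         call. = FALSE)
  }
  if (is.null(names(reports)) || any(names(reports) == "")) {
    stop("reports must be a named list keyed by family", call. = FALSE)
  }
  dics <- vapply(reports, function(r) r$dic, numeric(1))
  pref <- c(poisson = 1, negbin = 2, zip = 3)
  ord <- order(dics, pref[names(dics)])
  selected <- names(dics)[ord[1]]
  tie <- sum(dics == dics[ord[1]]) > 1
  structure(list(per_family = reports, dic = dics,
                 selected_family = selected,
                 tie = if (tie) paste0("DIC tie resolved toward '", selected,
                                       "' (simpler family)") else NULL,
                 age_group = age_group),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>", if (!is.na(x$age_group)) paste0("age group ", x$age_group), "\n")
  for (f in names(x$dic)) {
    cat(sprintf("  %-8s DIC %.3f%s\n", f, x$dic[f],
                if (f == x$selected_family) "  <- selected" else ""))
  }
  if (!is.null(x$tie)) cat("  note:", x$tie, "\n")
  invisible(x)
}
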