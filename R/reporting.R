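#' Exceedance-probability risk table
#'
#' For each area, the posterior probability that its relative risk exceeds 1,
#' i.e. the fraction of draws with spatial effect `gamma_i > 0`. Areas whose
#' probability exceeds the threshold (default 0.8) are classed high risk. A
#' per-state rollup uses the first two characters of the area code (the
#' state/departamento prefix of DIVIPOLA codes).
#'
#' @param draws A [fit_panel()] result.
#' @param threshold Exceedance probability above which an area is flagged;
#'   must lie strictly inside (0, 1). Default 0.8.
#' @return Data.frame of class `risk_table` with columns `area_id`,
#'   `exceedance_probability`, `high_risk` and `state_code`, plus attributes
#'   `by_state` (rollup data.frame) and `threshold`.
#' @export
exceedance_probabilities <- function(draws, threshold = 0.8) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  prob <- colMeans(draws$gamma > 0)
  ids <- draws$area_ids
  if (is.null(ids)) ids <- sprintf("A%03d", seq_along(prob))
  out <- data.frame(
    area_id = ids,
    exceedance_probability = prob,
    high_risk = prob > threshold,
    state_code = substr(ids, 1, 2),
    stringsAsFactors = FALSE
  )
  rollup <- stats::aggregate(cbind(n_high_risk = out$high_risk,
                                   n_total = rep(1L, nrow(out))),
                             by = list(state_code = out$state_code), FUN = sum)
  attr(out, "by_state") <- rollup
  attr(out, "threshold") <- threshold
  class(out) <- c("risk_table", class(out))
  out
}

#' Posterior summary of the fixed-effect incidence per 100,000
#'
#' Summarises `exp(alpha) * 100000` — the model's baseline incidence per
#' 100,000 person-quarters shared by all areas — across posterior draws.
#'
#' @param draws A [fit_panel()] result.
#' @return Named list with `mean`, `median`, `q025`, `q975`.
#' @export
fixed_effect_incidence <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"), length(draws$alpha) > 0)
  x <- exp(draws$alpha) * 1e5
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  list(mean = mean(x), median = q[2], q025 = q[1], q975 = q[3])
}

#' Per-area posterior spatial-effect surface
#'
#' Two honest readings of an "incidence attributed to the spatial effect" map
#' are emitted: the relative-risk surface `E[exp(gamma_i)]` and the combined
#' incidence surface `E[exp(alpha + gamma_i)] * 100000` per person-quarter.
#'
#' @param draws A [fit_panel()] result.
#' @param mode `"relative_risk"` or `"incidence"`.
#' @return Data.frame with `area_id` and `value` (posterior mean in the
#'   requested mode).
#' @export
spatial_effect_surface <- function(draws, mode = c("relative_risk", "incidence")) {
  stopifnot(inherits(draws, "posterior_draws"))
  mode <- match.arg(mode)
  value <- switch(mode,
    relative_risk = colMeans(exp(draws$gamma)),
    incidence = colMeans(exp(draws$alpha + draws$gamma)) * 1e5)
  ids <- draws$area_ids
  if (is.null(ids)) ids <- sprintf("A%03d", length(value))
  data.frame(area_id = ids, value = value, stringsAsFactors = FALSE)
}

#' Posterior temporal-effect curve
#'
#' Per quarter, the posterior mean and equal-tailed 95% band of
#' `exp(delta_t)`, the multiplicative temporal deviation from the baseline
#' rate. By identification each draw's `delta` sums to zero, so each draw's
#' curve has geometric mean exactly 1 over quarters.
#'
#' @param draws A [fit_panel()] result.
#' @return Data.frame with columns `quarter`, `mean`, `q025`, `q975`.
#' @export
temporal_effect_curve <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  ed <- exp(draws$delta)
  q <- apply(ed, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(quarter = seq_len(ncol(ed)),
             mean = colMeans(ed), q025 = q[1, ], q975 = q[2, ])
}

#' Credible-interval significance of per-area covariate slopes
#'
#' A slope is called significant when its equal-tailed 95% interval
#' (0.025 and 0.975 posterior quantiles) excludes zero — i.e. both quantiles
#' share a sign; the sign is reported for significant areas.
#'
#' @param draws A [fit_panel()] result.
#' @return Data.frame with `area_id`, `q025`, `q975`, `significant`, `sign`
#'   (`"+"`, `"-"`, or `NA` when not significant).
#' @export
covariate_significance <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  q <- apply(draws$beta, 2, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE)
  sig <- q[1, ] > 0 | q[2, ] < 0
  ids <- draws$area_ids
  if (is.null(ids)) ids <- sprintf("A%03d", ncol(draws$beta))
  data.frame(
    area_id = ids, q025 = q[1, ], q975 = q[2, ],
    significant = sig,
    sign = ifelse(sig, ifelse(q[1, ] > 0, "+", "-"), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Descriptive incidence series and maps
#'
#' Aggregates events to a period grid (month, quarter or year; optionally per
#' area) and reports cases, population at risk and the rate per 100,000.
#' Accepts either a line-list `records` data.frame (with `date` and
#' `municipality_code`) plus a population table, or a fitted `panel_data`
#' (quarterly resolution only).
#'
#' @param x Records data.frame or a `panel_data`.
#' @param population For records input: data.frame with `municipality_code`
#'   and `population` (rows are summed per municipality, so an age-stratified
#'   table may be passed directly). Ignored for panel input (the offset is the
#'   population).
#' @param grouping `"month"`, `"quarter"` or `"year"` (panel input: quarter).
#' @param by_area If `TRUE`, one row per area and period; the national series
#'   is the exact sum of the area series.
#' @return Data.frame with `period`, (optionally `area_id`,) `cases`,
#'   `population`, `rate_per_100k`. Zero-population rows carry `NA` rates and
#'   a `flagged` marker.
#' @export
descriptive_incidence <- function(x, population = NULL,
                                  grouping = c("month", "quarter", "year"),
                                  by_area = FALSE) {
  grouping <- match.arg(grouping)
  if (inherits(x, "panel_data")) {
    if (grouping != "quarter") {
      stop("panel input is quarterly; use grouping = 'quarter'", call. = FALSE)
    }
    if (by_area) {
      df <- data.frame(
        period = rep(sprintf("Q%02d", seq_len(x$n_quarters)), each = x$n_areas),
        area_id = rep(x$area_ids, x$n_quarters),
        cases = as.vector(x$counts),
        population = as.vector(x$offset))
    } else {
      df <- data.frame(period = sprintf("Q%02d", seq_len(x$n_quarters)),
                       cases = colSums(x$counts),
                       population = colSums(x$offset))
    }
  } else {
    if (is.null(population)) stop("records input needs a population table",
                                  call. = FALSE)
    rec <- x
    period <- switch(grouping,
      month = format(rec$date, "%Y-%m"),
      quarter = paste0(format(rec$date, "%Y"), "-Q",
                       ceiling(as.integer(format(rec$date, "%m")) / 3)),
      year = format(rec$date, "%Y"))
    pop <- population
    pop$municipality_code <- pad_code(pop$municipality_code)
    pop_by_area <- tapply(pop$population, pop$municipality_code, sum)
    if (by_area) {
      tab <- table(area_id = rec$municipality_code, period = period)
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      names(df)[names(df) == "Freq"] <- "cases"
      df$population <- as.numeric(pop_by_area[df$area_id])
      df <- df[order(df$period, df$area_id), c("period", "area_id", "cases",
                                               "population")]
    } else {
      tab <- table(period)
      df <- data.frame(period = names(tab), cases = as.integer(tab))
      df$population <- sum(pop_by_area)
    }
  }
  df$population[is.na(df$population)] <- 0
  df$rate_per_100k <- ifelse(df$population > 0,
                             1e5 * df$cases / df$population, NA_real_)
  df$flagged <- df$population <= 0
  rownames(df) <- NULL
  df
}

#' Enrich GeoJSON boundaries with per-area values for choropleth maps
#'
#' Joins a per-area table onto a GeoJSON FeatureCollection by municipality
#' code and writes the enriched file. Unmatched codes on either side are
#' returned in a join report; the output is still written.
#'
#' @param table Data.frame with an `area_id` column and one or more value
#'   columns to attach as feature properties.
#' @param boundaries Path to a GeoJSON FeatureCollection whose features carry
#'   the area code in a property.
#' @param out Output GeoJSON path.
#' @param key Name of the feature property holding the 5-digit code.
#' @return Invisibly, a list with `matched`, `unmatched_table`,
#'   `unmatched_features`.
#' @export
export_maps <- function(table, boundaries, out, key = "municipality_code") {
  stopifnot("area_id" %in% names(table))
  gj <- jsonlite::fromJSON(boundaries, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("boundaries file is not a FeatureCollection",
                                 call. = FALSE)
  feat_keys <- vapply(gj$features, function(f) {
    k <- f$properties[[key]]
    if (is.null(k)) NA_character_ else pad_code(k)
  }, character(1))
  if (all(is.na(feat_keys))) {
    stop("no feature carries the key property '", key, "'", call. = FALSE)
  }
  vals <- table[match(feat_keys, table$area_id), , drop = FALSE]
  value_cols <- setdiff(names(table), "area_id")
  for (i in seq_along(gj$features)) {
    if (!is.na(feat_keys[i]) && !is.na(match(feat_keys[i], table$area_id))) {
      for (cc in value_cols) {
        v <- vals[i, cc]
        if (is.logical(v)) v <- as.logical(v)
        gj$features[[i]]$properties[[cc]] <- unname(v)
      }
    }
  }
  jsonlite::write_json(gj, out, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  report <- list(
    matched = sum(!is.na(match(feat_keys, table$area_id))),
    unmatched_table = setdiff(table$area_id, feat_keys),
    unmatched_features = feat_keys[!is.na(feat_keys) &
                                     !(feat_keys %in% table$area_id)]
  )
  invisible(report)
}
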