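fake_draws <- function(gamma = NULL, alpha = NULL, delta = NULL, beta = NULL,
                       area_ids = NULL) {
  S <- max(length(alpha), nrow(gamma), nrow(delta), nrow(beta), 1)
  if (is.null(alpha)) alpha <- numeric(S)
  if (is.null(gamma)) gamma <- matrix(0, S, 1)
  if (is.null(delta)) delta <- matrix(0, S, 1)
  if (is.null(beta)) beta <- matrix(0, S, 1)
  if (is.null(area_ids)) area_ids <- sprintf("05%03d", seq_len(ncol(gamma)))
  structure(list(alpha = alpha, gamma = gamma, delta = delta, beta = beta,
                 pi = NULL, phi = NULL, chain = rep(1L, S), iter = seq_len(S),
                 n_chains = 1, n_kept = S, seed = 1,
                 spec = model_spec("poisson"), clamp = character(),
                 area_ids = area_ids), class = "posterior_draws")
}

test_that("exceedance probabilities count positive-gamma draws", {
  g <- cbind(c(0.5, -0.1, 0.2, 0.3), c(-1, -2, -0.5, -0.1))
  rt <- exceedance_probabilities(fake_draws(gamma = g), threshold = 0.7)
  expect_equal(rt$exceedance_probability, c(0.75, 0))
  expect_equal(rt$high_risk, c(TRUE, FALSE))
  expect_error(exceedance_probabilities(fake_draws(gamma = g), threshold = 1),
               "inside")
})

test_that("risk-table state rollups conserve counts", {
  set.seed(2)
  g <- matrix(rnorm(50 * 12), 50, 12)
  ids <- sprintf("%02d%03d", rep(1:3, c(4, 4, 4)), 1:12)
  rt <- exceedance_probabilities(fake_draws(gamma = g, area_ids = ids))
  roll <- attr(rt, "by_state")
  expect_equal(sum(roll$n_high_risk), sum(rt$high_risk))
  expect_equal(sum(roll$n_total), nrow(rt))
  # permutation invariance: shuffling draws leaves probabilities unchanged
  rt2 <- exceedance_probabilities(fake_draws(gamma = g[sample(50), ],
                                             area_ids = ids))
  expect_equal(rt$exceedance_probability, rt2$exceedance_probability)
})

test_that("fixed-effect incidence inverts the per-100k scale", {
  d <- fake_draws(alpha = rep(log(8.77e-5), 10))
  s <- fixed_effect_incidence(d)
  expect_equal(s$mean, 8.77, tolerance = 1e-10)
  expect_equal(s$median, 8.77, tolerance = 1e-10)
  d2 <- fake_draws(alpha = rep(log(1e-5), 10))
  expect_equal(fixed_effect_incidence(d2)$mean, 1, tolerance = 1e-12)
  # strictly increasing under a uniform shift of alpha
  set.seed(1)
  a <- rnorm(100, log(1e-4), 0.1)
  s1 <- fixed_effect_incidence(fake_draws(alpha = a))
  s2 <- fixed_effect_incidence(fake_draws(alpha = a + 0.2))
  expect_true(all(unlist(s2) > unlist(s1)))
})

test_that("spatial surfaces emit both honest map quantities", {
  S <- 6
  g <- cbind(rep(0, S), rep(log(2), S))
  d <- fake_draws(gamma = g, alpha = rep(log(1e-4), S))
  rr <- spatial_effect_surface(d, "relative_risk")
  expect_equal(rr$value, c(1, 2), tolerance = 1e-12)
  inc <- spatial_effect_surface(d, "incidence")
  expect_equal(inc$value, c(10, 20), tolerance = 1e-10)
  # rankings coincide when alpha is shared
  set.seed(3)
  g2 <- matrix(rnorm(S * 5), S, 5)
  d2 <- fake_draws(gamma = g2, alpha = rnorm(S, -9, 0.1))
  expect_equal(order(spatial_effect_surface(d2, "relative_risk")$value),
               order(spatial_effect_surface(d2, "incidence")$value))
  expect_error(spatial_effect_surface(d, "banana"))
})

test_that("temporal curve is identified and reflects single-quarter spikes", {
  d0 <- fake_draws(delta = matrix(0, 5, 8))
  crv <- temporal_effect_curve(d0)
  expect_true(all(crv$mean == 1))
  # per-draw geometric mean over quarters is exactly 1 (sum-zero)
  dd <- t(replicate(20, arealrisk:::project_temporal(rnorm(8, 0, 0.3))))
  crv2 <- temporal_effect_curve(fake_draws(delta = dd))
  gm <- exp(rowMeans(dd))
  expect_lt(max(abs(gm - 1)), 1e-12)
  expect_true(all(crv2$q975 >= crv2$q025))

  spike <- matrix(rep(c(log(2), rep(-log(2) / 7, 7)), each = 4), 4, 8)
  expect_equal(temporal_effect_curve(fake_draws(delta = spike))$mean[1], 2,
               tolerance = 1e-12)
})

test_that("covariate significance follows the shared-sign quantile rule", {
  set.seed(9)
  S <- 4000
  b <- cbind(rnorm(S, 0.05, 0.12),   # interval straddles 0 -> null
             rnorm(S, 0.25, 0.03),   # clearly positive
             rnorm(S, -0.25, 0.03))  # clearly negative
  cs <- covariate_significance(fake_draws(beta = b,
                                          area_ids = c("05001", "05002", "05003")))
  expect_equal(cs$significant, c(FALSE, TRUE, TRUE))
  expect_equal(cs$sign, c(NA, "+", "-"))
  expect_true(cs$q025[1] < 0 && cs$q975[1] > 0)
})

test_that("descriptive incidence conserves cases across areas and periods", {
  set.seed(4)
  recs <- data.frame(
    date = as.Date("2018-01-01") + sample(0:1095, 600, TRUE),
    municipality_code = sample(c("05001", "08001", "11001"), 600, TRUE),
    age = sample(5:80, 600, TRUE), sex = "F", stringsAsFactors = FALSE)
  pop <- pop_table(c("05001", "08001", "11001"), pop = 50000)

  monthly <- descriptive_incidence(recs, pop, "month")
  yearly <- descriptive_incidence(recs, pop, "year")
  expect_equal(sum(monthly$cases), 600)
  expect_equal(sum(yearly$cases), 600)
  y2018 <- yearly$cases[yearly$period == "2018"]
  m2018 <- monthly$cases[startsWith(monthly$period, "2018")]
  expect_equal(sum(m2018), y2018)

  by_area <- descriptive_incidence(recs, pop, "year", by_area = TRUE)
  nat <- tapply(by_area$cases, by_area$period, sum)
  expect_equal(as.integer(nat[yearly$period]), yearly$cases)
  expect_equal(monthly$rate_per_100k,
               1e5 * monthly$cases / monthly$population)

  # 50 cases over 100,000 people -> 50 per 100,000
  one <- descriptive_incidence(
    data.frame(date = rep(as.Date("2018-06-01"), 50),
               municipality_code = "05001", age = 20L, sex = "F"),
    data.frame(municipality_code = "05001", age_group = "20-24",
               population = 100000),
    "year")
  expect_equal(one$rate_per_100k, 50)
})

test_that("descriptive incidence accepts panels and reproduces generator rates", {
  cfg <- scenario_config(n_areas = 150, n_quarters = 8,
                         population_range = c(5e4, 5e4),
                         covariate_trajectory = "constant")
  tr <- simulate_truth(cfg, alpha = log(2e-4), tau_gamma = 1e12,
                       tau_delta = 1e12, tau_beta = 1e12, seed = 30)
  pan <- simulate_panel(tr, cfg)
  ds <- descriptive_incidence(pan, grouping = "quarter")
  expect_equal(sum(ds$cases), sum(pan$counts))
  # configured rate 20 per 100k per quarter, within binomial error
  expected <- 20
  tol <- 3 * sqrt(expected * 1e5 / (150 * 5e4)) # 3 SE of a Poisson rate
  expect_true(all(abs(ds$rate_per_100k - expected) < tol))
})

test_that("a planted temporal dip shows up in the fitted curve", {
  hits <- vapply(1:3, function(r) {
    cfg <- scenario_config(n_areas = 30, n_quarters = 12,
                           dip = list(start_t = 9, end_t = 11, depth = 0.4))
    tr <- simulate_truth(cfg, alpha = -8.5, seed = 40 + r)
    pan <- simulate_panel(tr, cfg)
    f <- fit_panel(pan, model_spec("poisson"), n_chains = 1, n_iter = 1000,
                   seed = 50 + r)
    crv <- temporal_effect_curve(f)
    mean(crv$mean[9:11]) < mean(crv$mean[1:8])
  }, logical(1))
  expect_true(all(hits))
})

test_that("geojson export joins by code and reports mismatches", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(municipality_code = "05001", name = "a"),
           geometry = list(type = "Point", coordinates = c(0, 0))),
      list(type = "Feature",
           properties = list(municipality_code = "5002", name = "b"),
           geometry = list(type = "Point", coordinates = c(1, 1))),
      list(type = "Feature",
           properties = list(municipality_code = "99999", name = "zz"),
           geometry = list(type = "Point", coordinates = c(2, 2)))))
  src <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, src, auto_unbox = TRUE)

  tab <- data.frame(area_id = c("05001", "05002", "13001"),
                    value = c(1.5, 2.5, 9), stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".geojson")
  rep1 <- export_maps(tab, src, out)
  expect_equal(rep1$matched, 2)  # "5002" matches after zero-padding
  expect_equal(rep1$unmatched_table, "13001")
  expect_equal(rep1$unmatched_features, "99999")
  enriched <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  expect_equal(enriched$features[[1]]$properties$value, 1.5)
  expect_equal(enriched$features[[2]]$properties$value, 2.5)
  expect_null(enriched$features[[3]]$properties$value)

  # idempotence: identical inputs give byte-identical output
  out2 <- tempfile(fileext = ".geojson")
  export_maps(tab, src, out2)
  expect_identical(readLines(out), readLines(out2))

  expect_error(export_maps(tab, src, out, key = "nope"), "key property")
})
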