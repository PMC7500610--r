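test_that("landscape generation is deterministic and structurally valid", {
  a <- generate_landscape(tiny_config())
  b <- generate_landscape(tiny_config())
  expect_identical(gr_values(a$rasters$elevation), gr_values(b$rasters$elevation))
  expect_identical(a$towns, b$towns)
  expect_identical(a$roads, b$roads)
  expect_identical(gr_values(a$monthly_rainfall[[5]]),
                   gr_values(b$monthly_rainfall[[5]]))

  land <- tiny_land()
  expect_true(all(vapply(land$rasters, function(r) {
    gr_aligned(r, land$rasters$elevation)
  }, logical(1))))
  expect_true(all(gr_values(land$rasters$rain_mean) >= 0))
  expect_gte(length(unique(as.vector(gr_values(land$regions)))), 2)
  # two towns forced above the 50k market threshold
  expect_gte(sum(land$towns$population > 50000), 2)
  # every town lies on a road cell: rasterized speeds at town cells are
  # road speeds
  sp <- rasterize_speeds(land$roads, land$rasters$landcover)
  expect_true(all(gr_values(sp)[cbind(land$towns$row, land$towns$col)] >= 30))
  expect_error(landscape_config(grid_shape = c(10, 10)), "grid_shape")
  expect_error(landscape_config(n_obs = 100, n_households = 200), "n_obs")
})

test_that("monthly rainfall covers every requested season", {
  land <- tiny_land()
  # Dec of (first year - 1) through May of the last year present
  expect_true("1999-12" %in% names(land$monthly_rainfall))
  ens <- seasonal_totals(land$monthly_rainfall)
  expect_identical(ens$years, 2000:2004)
})

test_that("zero interannual variance gives identical seasonal totals", {
  cfg <- tiny_config()
  cfg$rain_cv <- 0
  land <- generate_landscape(cfg)
  ens <- seasonal_totals(land$monthly_rainfall)
  for (y in names(ens$totals)) {
    expect_equal(gr_values(ens$totals[[y]]),
                 gr_values(land$rasters$rain_mean), tolerance = 1e-12)
  }
  expect_true(all(gr_values(ens$cv) == 0))
})

test_that("true yield oracle is concave and increasing where it should be", {
  expect_error(true_yield(-5, 900), "n_rate")
  expect_error(true_yield(5, -900), "seasonal_rain")
  # zero-N baseline
  y0 <- true_yield(0, 900, 20, 1000)
  expect_gt(y0, 0)
  # concavity in N on a 0-400 grid at 50 random pixels
  land <- tiny_land()
  set.seed(1)
  d <- gr_dim(land$rasters$soc)
  ii <- cbind(sample(d[1], 50, TRUE), sample(d[2], 50, TRUE))
  ngrid <- seq(0, 400, by = 10)
  for (k in seq_len(10)) {
    y <- true_yield(ngrid, gr_values(land$rasters$rain_mean)[ii[k, , drop = FALSE]],
                    gr_values(land$rasters$soc)[ii[k, , drop = FALSE]],
                    gr_values(land$rasters$elevation)[ii[k, , drop = FALSE]])
    expect_true(all(diff(y) > 0))          # strictly increasing
    expect_true(all(diff(diff(y)) < 1e-9)) # concave
  }
  # marginal product at 350 below marginal product at 50
  expect_lt(true_yield(351, 900) - true_yield(350, 900),
            true_yield(51, 900) - true_yield(50, 900))
  # increasing in rainfall over 500-1250 mm
  rains <- seq(500, 1250, by = 50)
  expect_true(all(diff(true_yield(55, rains)) > 0))
})

test_that("mean agronomic efficiency at 55 kg/ha sits in the calibrated band", {
  land <- default_land()
  set.seed(1)
  d <- gr_dim(land$rasters$soc)
  ii <- cbind(sample(d[1], 200, TRUE), sample(d[2], 200, TRUE))
  rain <- gr_values(land$rasters$rain_mean)[ii]
  soc <- gr_values(land$rasters$soc)[ii]
  elev <- gr_values(land$rasters$elevation)[ii]
  ae <- (true_yield(55, rain, soc, elev) - true_yield(0, rain, soc, elev)) / 55
  expect_gt(mean(ae), 7.2 - 1.0)
  expect_lt(mean(ae), 7.2 + 1.0)
})

test_that("survey reproduces the target covariate moments", {
  s <- generate_survey(default_land())
  tg <- survey_targets()
  expect_equal(nrow(s), 601)
  expect_equal(length(unique(s$hh_id)), 455)
  # yields from the DGP: mean within 10% relative
  expect_lt(abs(mean(s$yield) - 2604) / 2604, 0.10)
  # binary shares within 0.05 absolute
  for (v in c("fert_user", "intercrop", "rotation", "manure", "residue",
              "improved_seed", "fallow", "erosion_ctrl", "terraced")) {
    expect_lt(abs(mean(s[[v]]) - tg$mean[tg$variable == v]), 0.05)
  }
  # continuous means within 10% relative (log_area target is negative)
  for (v in c("weedings", "head_age", "hh_size", "head_education",
              "log_area")) {
    tgt <- tg$mean[tg$variable == v]
    expect_lt(abs(mean(s[[v]]) - tgt) / abs(tgt), 0.10)
  }
  expect_lt(abs(mean(s$n_rate[s$fert_user == 1]) - 35.2) / 35.2, 0.10)
  expect_true(all(s$yield >= 0))
  expect_true(all(s$n_rate >= 0))
})

test_that("noiseless survey yields equal the oracle exactly", {
  land <- tiny_land()
  s <- generate_survey(land, noise_sd = 0, management_effects = FALSE)
  expect_equal(s$yield,
               true_yield(s$n_rate, s$seasonal_rain, s$soc, s$elevation,
                          land$config$yield),
               tolerance = 1e-12)
})

test_that("price observations respect bounds and the noiseless contract", {
  land <- tiny_land()
  obs <- generate_price_observations(land)
  expect_true(all(obs$price >= 0.07 & obs$price <= 0.94))
  obs0 <- generate_price_observations(land, noise_sd = 0)
  truth <- agroprofit:::true_price_function(land)
  expect_equal(obs0$price, gr_values(truth)[cbind(obs0$row, obs0$col)],
               tolerance = 1e-12)
  # changing the root seed changes the noise but not the underlying
  # function the observations are drawn from
  land_reseeded <- land
  land_reseeded$config$seed <- 555L
  obs_b <- generate_price_observations(land_reseeded)
  expect_false(identical(obs$price, obs_b$price))
  expect_identical(gr_values(agroprofit:::true_price_function(land_reseeded)),
                   gr_values(truth))
})

test_that("adoption panel has valid structure and responds to the DGP", {
  land <- tiny_land()
  ref <- land$rasters$elevation
  nr_mean <- gr_map(function(s, e) 400 + 50 * s + 0.6 * e,
                    land$rasters$soc, land$rasters$elevation)
  nr_sd <- gr_const(ref, 80)
  p <- generate_adoption_panel(land, nr_mean, nr_sd)
  expect_true(all(p$fert_user %in% c(0, 1)))
  expect_equal(sort(unique(p$wave)), 1:3)
  expect_equal(length(unique(p$hh_id)), land$config$panel_households)
  # clusters nest within regions
  nest <- dplyr::distinct(p[, c("ea_cluster_id", "region_id")])
  expect_equal(nrow(nest), length(unique(p$ea_cluster_id)))

  # betas all zero: adoption rate equals the solved intercept up to
  # binomial error
  b0 <- adoption_betas(log_netrev = 0, sd_netrev = 0,
                       area_cultivated = 0, head_age = 0, female_head = 0,
                       head_education = 0, n_members = 0, log_assets = 0,
                       log_travel_time = 0, mean_annual_rainfall = 0)
  p0 <- generate_adoption_panel(land, nr_mean, nr_sd, betas = b0,
                                target_rate = 0.3, seed = 77)
  n <- nrow(p0)
  expect_lt(abs(mean(p0$fert_user) - 0.3), 4 * sqrt(0.3 * 0.7 / n) + 0.02)

  # higher revenue uncertainty lowers adoption, holding the rest of the
  # process fixed: a spatially varying SD raster must show lower adoption
  # among the households facing the larger SDs (a uniform SD shift would be
  # absorbed by the solved intercept)
  cfg <- tiny_config()
  cfg$panel_households <- 600L
  cfg$panel_clusters <- 40L
  land_big <- generate_landscape(cfg)
  nr_mean2 <- gr_map(function(s) 800 + 50 * s, land_big$rasters$soc)
  nr_sd2 <- gr_map(function(e) 20 + 0.15 * e, land_big$rasters$elevation)
  pp <- generate_adoption_panel(land_big, nr_mean2, nr_sd2, seed = 5)
  hi_sd <- pp$sd_netrev > stats::median(pp$sd_netrev)
  expect_gt(mean(pp$fert_user[!hi_sd]), mean(pp$fert_user[hi_sd]))
})
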