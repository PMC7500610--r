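test_that("logistic delivery multiplier is calibrated exactly", {
  tp <- transport_params()
  expect_equal(logistic_multiplier(0, tp), 1, tolerance = 1e-9)
  expect_equal(logistic_multiplier(5, tp), 3, tolerance = 1e-9)
  expect_equal(logistic_multiplier(2.5, tp), 2, tolerance = 1e-9)
  expect_equal(tp$t0, 2.5, tolerance = 1e-12)
  expect_equal(tp$k, log(3) / 2.5, tolerance = 1e-12)
  # strictly increasing and bounded in (0, L)
  t <- seq(0, 30, by = 0.25)
  m <- logistic_multiplier(t, tp)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > 0 & m < tp$L))
  expect_error(transport_params(L = 2.5), "L")
  expect_error(logistic_multiplier(-1), ">= 0")
})

test_that("farm-gate nitrogen prices follow the calibrated logistic", {
  tmat <- grid_raster(matrix(c(0, 2.5, 5, 40), 2, 2))
  pn <- farmgate_nitrogen_prices(tmat)
  expect_equal(gr_values(pn)[1, 1], 0.95, tolerance = 1e-9)
  expect_equal(gr_values(pn)[2, 1], 1.90, tolerance = 1e-9)
  expect_equal(gr_values(pn)[1, 2], 2.85, tolerance = 1e-9)
  # far from markets, price approaches L * base = 3.80
  expect_equal(gr_values(pn)[2, 2], 4 * 0.95, tolerance = 1e-3)
  expect_error(farmgate_nitrogen_prices(grid_raster(matrix(-1, 2, 2))),
               "negative")
  expect_equal(urea_to_n_price(0.437), 0.437 / 0.46)
})

toy_stack <- function(tmats) {
  layers <- lapply(tmats, grid_raster)
  structure(list(layers = layers,
                 nearest = Reduce(function(a, b) gr_map(pmin, a, b), layers)),
            class = "travel_time_stack")
}

test_that("farm-gate maize arbitrage picks the best market and flags losses", {
  # single market: p = 0.37 at 10 h and c = 0.01 gives 0.27
  st <- toy_stack(list(matrix(10, 2, 2)))
  fg <- farmgate_maize_prices(0.37, st, 0.01)
  expect_equal(gr_values(fg$price)[1, 1], 0.27, tolerance = 1e-12)

  # two markets: max(0.30 - 0.01*2, 0.50 - 0.01*25) = 0.28
  st2 <- toy_stack(list(matrix(2, 2, 2), matrix(25, 2, 2)))
  fg2 <- farmgate_maize_prices(c(0.30, 0.50), st2, 0.01)
  expect_equal(gr_values(fg2$price)[1, 1], 0.28, tolerance = 1e-12)

  # at the market cell (T = 0) the farm-gate price equals the market price
  st3 <- toy_stack(list(matrix(c(0, 3, 3, 6), 2, 2)))
  fg3 <- farmgate_maize_prices(0.40, st3, 0.01)
  expect_equal(gr_values(fg3$price)[1, 1], 0.40)

  # non-positive farm-gate prices masked and flagged, not truncated
  st4 <- toy_stack(list(matrix(10, 2, 2)))
  fg4 <- farmgate_maize_prices(0.05, st4, 0.01)
  expect_true(all(is.na(gr_values(fg4$price))))
  expect_true(all(gr_values(fg4$nonpositive) == 1))
  expect_error(farmgate_maize_prices(c(0.3, 0.4), st4), "length")
})

test_that("arbitrage surface is bounded by and monotone in town prices", {
  land <- tiny_land()
  speed <- rasterize_speeds(land$roads, land$rasters$landcover)
  tt <- travel_time_per_market(speed, land$towns)
  p <- seq(0.35, by = 0.05, length.out = length(tt$layers))
  fg <- farmgate_maize_prices(p, tt, 0.01)
  expect_true(all(gr_values(fg$price) <= max(p) + 1e-12, na.rm = TRUE))
  # the highest-priced town's own cell recovers its price exactly
  best <- which.max(p)
  tw <- tt$towns[best, ]
  expect_equal(gr_values(fg$price)[tw$row, tw$col], p[best],
               tolerance = 1e-12)
  # raising a town price never lowers any pixel's farm-gate price
  p2 <- p; p2[1] <- p2[1] + 0.10
  fg_up <- farmgate_maize_prices(p2, tt, 0.01)
  expect_true(all(gr_values(fg_up$price) >= gr_values(fg$price) - 1e-12,
                  na.rm = TRUE))
  # single-market landscape: price decays at exactly c per hour
  one <- toy_stack(list(gr_values(tt$layers[[1]])))
  fg1 <- farmgate_maize_prices(0.6, one, 0.01)
  dec <- (0.6 - gr_values(fg1$price)) / gr_values(one$layers[[1]])
  dec <- dec[!is.na(dec) & gr_values(one$layers[[1]]) > 0]
  expect_equal(unname(dec), rep(0.01, length(dec)), tolerance = 1e-12)
})

test_that("price forest is deterministic and handles degenerate targets", {
  mk <- default_market()
  obs <- generate_price_observations(mk$land, n = 200)
  m1 <- fit_market_price_model(obs, mk$predictors, seed = 11, num_trees = 100)
  m2 <- fit_market_price_model(obs, mk$predictors, seed = 11, num_trees = 100)
  s1 <- predict_market_prices(m1, mk$predictors)
  s2 <- predict_market_prices(m2, mk$predictors)
  expect_identical(gr_values(s1), gr_values(s2))

  obs_const <- obs
  obs_const$price <- 0.4
  mc <- fit_market_price_model(obs_const, mk$predictors, seed = 1,
                               num_trees = 100)
  sc <- predict_market_prices(mc, mk$predictors)
  rng <- range(gr_values(sc), na.rm = TRUE)
  expect_lt(diff(rng), 1e-6)
  expect_error(fit_market_price_model(obs[1:10, ], mk$predictors), "50")
})

test_that("price surface predictions track the generator's smooth function", {
  mk <- default_market()
  land <- mk$land
  # default observation density: out-of-sample skill
  obs <- generate_price_observations(land, noise_sd = 0)
  set.seed(4)
  hold <- sample(nrow(obs), 120)
  pm <- fit_market_price_model(obs[-hold, ], mk$predictors, seed = 2)
  idx <- cbind(obs$row[hold], obs$col[hold])
  X <- purrr::map_dfc(mk$predictors, function(r) gr_values(r)[idx])
  X$x <- obs$x[hold]; X$y <- obs$y[hold]
  ph <- predict(pm$forest, data = X, num.threads = 1)$predictions
  r2 <- 1 - sum((obs$price[hold] - ph)^2) /
    sum((obs$price[hold] - mean(obs$price[hold]))^2)
  expect_gte(r2, 0.8)

  # dense noiseless sampling: whole-surface error under 10% of the range
  obs_dense <- generate_price_observations(land, n = 5000, noise_sd = 0)
  pm_dense <- fit_market_price_model(obs_dense, mk$predictors, seed = 2)
  surf <- predict_market_prices(pm_dense, mk$predictors)
  truth <- agroprofit:::true_price_function(land)
  err <- abs(gr_values(surf) - gr_values(truth))
  expect_lt(max(err, na.rm = TRUE), 0.10 * diff(range(gr_values(truth))))

  # nodata propagation
  preds_na <- mk$predictors
  v <- gr_values(preds_na$rural_pop)
  v[1, 1] <- NA
  preds_na$rural_pop <- grid_raster(v, preds_na$rural_pop$cell_size)
  s_na <- predict_market_prices(pm_dense, preds_na)
  expect_true(is.na(gr_values(s_na)[1, 1]))
})
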