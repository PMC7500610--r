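test_that("yield forest fitting is deterministic and validates inputs", {
  land <- tiny_land()
  s <- generate_survey(land)
  m1 <- fit_yield_model(s, num_trees = 100, seed = 3)
  m2 <- fit_yield_model(s, num_trees = 100, seed = 3)
  expect_identical(m1$oob_r2, m2$oob_r2)

  expect_error(fit_yield_model(s[, -which(names(s) == "soc")]), "missing")
  s_const <- s
  s_const$yield <- 1000
  expect_error(fit_yield_model(s_const), "constant")
  expect_error(fit_yield_model(s[1:50, ]), "100")
})

test_that("forest recovers the noiseless response out of sample", {
  land <- default_land()
  s0 <- generate_survey(land, noise_sd = 0, management_effects = FALSE)
  set.seed(2)
  hold <- sample(nrow(s0), 150)
  m0 <- fit_yield_model(s0[-hold, ], seed = 9)
  ph <- predict(m0$forest, data = s0[hold, ], num.threads = 1)$predictions
  r2 <- 1 - sum((s0$yield[hold] - ph)^2) /
    sum((s0$yield[hold] - mean(s0$yield[hold]))^2)
  expect_gte(r2, 0.8)
})

test_that("yield surfaces are reproducible and broadcast the N rate", {
  land <- tiny_land()
  s <- generate_survey(land)
  m <- fit_yield_model(s, num_trees = 100, seed = 3)
  rain <- land$rasters$rain_mean
  y1 <- predict_yield_surface(m, land$rasters, 0, rain)
  y2 <- predict_yield_surface(m, land$rasters, 0, rain)
  expect_identical(gr_values(y1), gr_values(y2))
  y3 <- predict_yield_surface(m, land$rasters,
                              gr_const(rain, 0), rain)
  expect_identical(gr_values(y1), gr_values(y3))
  expect_error(predict_yield_surface(m, land$rasters, -5, rain), ">= 0")
  expect_error(predict_yield_surface(m, land$rasters, 0, rain,
                                     hh_means = c(p_rate = 10)),
               "missing predictors")
})

test_that("surface predictions track the oracle on a noiseless fit", {
  land <- default_land()
  s0 <- generate_survey(land, noise_sd = 0, management_effects = FALSE)
  m0 <- fit_yield_model(s0, seed = 9)
  y55 <- predict_yield_surface(m0, land$rasters, 55, land$rasters$rain_mean)
  oracle <- gr_map(function(r, so, e) true_yield(55, r, so, e,
                                                 land$config$yield),
                   land$rasters$rain_mean, land$rasters$soc,
                   land$rasters$elevation)
  rel <- abs(gr_values(y55) - gr_values(oracle)) / gr_values(oracle)
  expect_lt(median(rel, na.rm = TRUE), 0.10)
})

test_that("partial dependence reflects the monotone concave N response", {
  land <- default_land()
  s0 <- generate_survey(land, noise_sd = 0, management_effects = FALSE)
  m0 <- fit_yield_model(s0, seed = 9)
  grid <- seq(0, 350, length.out = 20)
  pd <- partial_dependence(m0, s0, "n_rate", grid)
  oracle <- true_yield(grid, 900, 20, 1000, land$config$yield)
  expect_gte(cor(pd$yhat, oracle, method = "spearman"), 0.95)
  # no drop larger than 2% of the curve range
  expect_lt(max(-diff(pd$yhat), 0) / diff(range(pd$yhat)), 0.02)
  # diminishing returns: slope beyond 300 below slope below 100
  slope_lo <- (pd$yhat[grid <= 100][sum(grid <= 100)] - pd$yhat[1]) /
    (grid[grid <= 100][sum(grid <= 100)] - grid[1])
  hi <- which(grid >= 300)
  slope_hi <- (pd$yhat[max(hi)] - pd$yhat[min(hi)]) /
    (grid[max(hi)] - grid[min(hi)])
  expect_lt(slope_hi, slope_lo)
  expect_error(partial_dependence(m0, s0, "not_a_var", grid), "unknown")
})

test_that("a constant-response forest has a flat partial dependence curve", {
  land <- tiny_land()
  s <- generate_survey(land)
  s$yield <- 2000 + rnorm(nrow(s), sd = 1e-6)  # numerically constant
  m <- fit_yield_model(s, num_trees = 50, seed = 1)
  pd <- partial_dependence(m, s, "n_rate", seq(0, 100, by = 25))
  expect_lt(diff(range(pd$yhat)), 1e-4)
})

test_that("agronomic efficiency arithmetic, masking and scaling identities", {
  y0 <- grid_raster(matrix(2000, 2, 2))
  yn <- grid_raster(matrix(2396, 2, 2))
  ae <- agronomic_efficiency(yn, y0, 55)
  expect_equal(gr_values(ae$ae), matrix(7.2, 2, 2), tolerance = 1e-12)
  expect_equal(ae$mean_ae, 7.2, tolerance = 1e-12)
  expect_error(agronomic_efficiency(yn, y0, 0), "positive")
  # equal yields give zero efficiency
  expect_equal(agronomic_efficiency(y0, y0, 55)$mean_ae, 0)

  # scaling the incremental response scales AE exactly, pixelwise
  ys <- scale_incremental_response(y0, yn, 1.25)
  ae_s <- agronomic_efficiency(ys, y0, 55)
  expect_equal(gr_values(ae_s$ae), 1.25 * gr_values(ae$ae),
               tolerance = 1e-12)
  expect_equal(ae_s$mean_ae, 1.25 * 7.2, tolerance = 1e-12)
  # the robustness-check anchor: s = 1.25 maps mean AE 7.2 to 9.0
  expect_equal(ae_s$mean_ae, 9.0, tolerance = 1e-12)

  # s = 1 is the identity; hand-computed case 2000 + 1.5 * 720 = 3080
  expect_equal(gr_values(scale_incremental_response(y0, yn, 1)),
               gr_values(yn))
  y720 <- grid_raster(matrix(2720, 2, 2))
  expect_equal(gr_values(scale_incremental_response(y0, y720, 1.5)),
               matrix(3080, 2, 2))
  expect_error(scale_incremental_response(y0, yn, -1), "non-negative")
})
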