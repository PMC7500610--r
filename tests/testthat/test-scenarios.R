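test_that("scenario spec validates its N grid", {
  expect_error(scenario_spec(n_grid = numeric()), "empty")
  expect_error(scenario_spec(n_grid = c(10, 5, 0)), "sorted")
  expect_error(scenario_spec(n_grid = seq(10, 100, 10)), "contain 0")
  sp <- scenario_spec()
  expect_true(all(c(0, 55) %in% sp$n_grid))
})

test_that("net revenue arithmetic and mask propagation", {
  y <- grid_raster(matrix(3000, 2, 2))
  pm <- grid_raster(matrix(0.30, 2, 2))
  pn <- grid_raster(matrix(2.00, 2, 2))
  r <- net_revenue(y, pm, pn, 55)
  expect_equal(gr_values(r), matrix(900 - 110, 2, 2))
  # zero N: revenue only
  expect_equal(gr_values(net_revenue(y, pm, pn, 0)), matrix(900, 2, 2))
  # nodata maize price propagates
  pm_na <- grid_raster(matrix(c(0.3, NA, 0.3, 0.3), 2, 2))
  r_na <- net_revenue(y, pm_na, pn, 55)
  expect_true(is.na(gr_values(r_na)[2, 1]))
  expect_error(net_revenue(y, pm, pn, -1), ">= 0")
})

test_that("per-pixel rate optimisation equals the exhaustive double loop", {
  land <- tiny_land()
  s <- generate_survey(land)
  m <- fit_yield_model(s, num_trees = 60, seed = 3)
  spec <- scenario_spec(n_grid = seq(0, 80, by = 20), bk_rate = 20)
  pm <- gr_map(function(e) 0.2 + 1e-5 * e, land$rasters$elevation)
  pn <- gr_map(function(t) 0.95 + 0.01 * t, land$rasters$soc)
  prices <- list(maize = pm, nitrogen = pn)
  opt <- optimize_rate(m, land$rasters, land$rasters$rain_mean, prices,
                       spec, objective = "netrev")

  # oracle: per-pixel loop over the grid, tie to the lowest rate, with the
  # same non-decreasing-in-N projection applied by hand
  ys <- lapply(spec$n_grid, function(n) {
    gr_values(predict_yield_surface(m, land$rasters, n,
                                    land$rasters$rain_mean))
  })
  for (k in seq_along(ys)[-1]) ys[[k]] <- pmax(ys[[k]], ys[[k - 1]])
  d <- gr_dim(pm)
  want <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      vals <- vapply(seq_along(spec$n_grid), function(k) {
        gr_values(pm)[i, j] * ys[[k]][i, j] -
          gr_values(pn)[i, j] * spec$n_grid[k]
      }, numeric(1))
      want[i, j] <- spec$n_grid[which.max(vals)]
    }
  }
  expect_equal(gr_values(opt), want)

  # with free nitrogen, maximising revenue is maximising yield
  opt_free <- optimize_rate(m, land$rasters, land$rasters$rain_mean,
                            list(maize = pm, nitrogen = gr_const(pm, 0)),
                            spec, objective = "netrev")
  opt_yield <- optimize_rate(m, land$rasters, land$rasters$rain_mean,
                             spec = spec, objective = "yield")
  expect_equal(gr_values(opt_free), gr_values(opt_yield))
})

test_that("the four scenarios satisfy their definitions and dominance", {
  land <- tiny_land()
  s <- generate_survey(land)
  m <- fit_yield_model(s, num_trees = 60, seed = 3)
  spec <- scenario_spec(n_grid = seq(0, 120, by = 15), bk_rate = 15)
  pm <- gr_const(land$rasters$soc, 0.3)
  pn <- gr_const(land$rasters$soc, 1.5)
  prices <- list(maize = pm, nitrogen = pn)
  scn <- run_scenarios(m, land$rasters, land$rasters$rain_mean, prices, spec)

  expect_true(all(gr_values(scn$BK$n_rate) == spec$bk_rate))
  expect_true(all(gr_values(scn$ZERO$n_rate) == 0))
  expect_equal(gr_values(scn$ZERO$netrev),
               0.3 * gr_values(scn$ZERO$yield), tolerance = 1e-12)
  for (nm in c("ZERO", "BK", "OPnetrev")) {
    expect_true(all(gr_values(scn$OPyield$yield) >=
                      gr_values(scn[[nm]]$yield) - 1e-9, na.rm = TRUE))
  }
  for (nm in c("ZERO", "BK", "OPyield")) {
    expect_true(all(gr_values(scn$OPnetrev$netrev) >=
                      gr_values(scn[[nm]]$netrev) - 1e-9, na.rm = TRUE))
  }

  # currency-scale equivariance: scaling both prices by alpha scales every
  # net revenue and leaves the optimal rates unchanged
  alpha <- 2.7
  scn2 <- run_scenarios(m, land$rasters, land$rasters$rain_mean,
                        list(maize = gr_map(function(p) alpha * p, pm),
                             nitrogen = gr_map(function(p) alpha * p, pn)),
                        spec)
  expect_equal(gr_values(scn2$OPnetrev$n_rate),
               gr_values(scn$OPnetrev$n_rate))
  expect_equal(gr_values(scn2$BK$netrev), alpha * gr_values(scn$BK$netrev),
               tolerance = 1e-9)
})

test_that("gains are differences of net revenue with weighted means", {
  r1 <- toy_result(grid_raster(matrix(0, 2, 2)),
                   grid_raster(matrix(1000, 2, 2)),
                   grid_raster(matrix(c(100, 200, 300, 400), 2, 2)))
  r2 <- toy_result(grid_raster(matrix(55, 2, 2)),
                   grid_raster(matrix(1400, 2, 2)),
                   grid_raster(matrix(c(150, 210, 330, 390), 2, 2)))
  g0 <- gains(r1, r1)
  expect_true(all(gr_values(g0$gains) == 0))
  w <- grid_raster(matrix(c(1, 2, 3, 4), 2, 2))
  g <- gains(r1, r2, maize_area = w)
  expect_equal(gr_values(g$gains), matrix(c(50, 10, 30, -10), 2, 2))
  expect_equal(g$mean_gain, (50 * 1 + 10 * 2 + 30 * 3 + (-10) * 4) / 10)
})
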