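# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# small, fast landscape for unit tests
tiny_config <- function(seed = 101) {
  landscape_config(
    grid_shape = c(24, 24), n_towns = 3, n_regions = 4, years = 2000:2004,
    n_households = 80, n_obs = 110, n_price_obs = 120,
    panel_households = 150, panel_clusters = 30, seed = seed
  )
}

tiny_land <- function() memo("tiny_land", function() {
  generate_landscape(tiny_config())
})

# default-scale landscape: the study conditions (60x60, 40 seasons, 601 obs)
default_land <- function() memo("default_land", function() {
  generate_landscape(landscape_config(seed = 1234))
})

# market-access + price stages on the default landscape
default_market <- function() memo("default_market", function() {
  land <- default_land()
  speed <- rasterize_speeds(land$roads, land$rasters$landcover)
  tt <- travel_time_per_market(speed, land$towns)
  list(land = land, speed = speed, tt = tt,
       predictors = price_predictors(land, speed, tt))
})

# predictor raster list for the market price model
price_predictors <- function(land, speed, tt) {
  port <- land$towns[which.max(land$towns$population), ]
  xy <- gr_xy(speed)
  d <- gr_dim(speed)
  dp <- matrix(NA_real_, d[1], d[2])
  dp[cbind(xy$row, xy$col)] <- sqrt((xy$x - port$x)^2 + (xy$y - port$y)^2)
  list(travel_time = tt$nearest,
       dist_port = grid_raster(dp, speed$cell_size),
       rural_pop = land$rasters$rural_pop,
       maize_area = land$rasters$maize_area,
       rain_mean = land$rasters$rain_mean)
}

# full price + yield + scenario stages on the default landscape
default_pipeline <- function() memo("default_pipeline", function() {
  mk <- default_market()
  land <- mk$land
  obs <- generate_price_observations(land)
  pmod <- fit_market_price_model(obs, mk$predictors, seed = 2)
  market_price <- predict_market_prices(pmod, mk$predictors)
  tp <- town_prices(market_price, mk$tt$towns)
  fg <- farmgate_maize_prices(tp$price, mk$tt, 0.01)
  prices <- list(maize = fg$price,
                 nitrogen = farmgate_nitrogen_prices(mk$tt$nearest))
  survey <- generate_survey(land)
  ymod <- fit_yield_model(survey, seed = 7)
  ens <- seasonal_totals(land$monthly_rainfall)
  scn <- run_scenarios(ymod, land$rasters, ens$mean, prices)
  list(land = land, tt = mk$tt, prices = prices, survey = survey,
       ymod = ymod, ens = ens, scn = scn, fg = fg)
})

# textbook O(n^2) Dijkstra over the raster graph: the independent oracle for
# travel_time(); no igraph, no shared code with the implementation
dijkstra_brute <- function(w, src_row, src_col, cell = 1, conn = 8) {
  nr <- nrow(w); nc <- ncol(w); n <- nr * nc
  dist <- rep(Inf, n)
  dist[(src_col - 1) * nr + src_row] <- 0
  done <- rep(FALSE, n)
  nbr <- rbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1))
  if (conn == 8) {
    nbr <- rbind(nbr, c(1, 1, sqrt(2)), c(1, -1, sqrt(2)),
                 c(-1, 1, sqrt(2)), c(-1, -1, sqrt(2)))
  }
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    ur <- (u - 1) %% nr + 1
    uc <- (u - 1) %/% nr + 1
    if (is.na(w[ur, uc])) next
    for (k in seq_len(nrow(nbr))) {
      vr <- ur + nbr[k, 1]; vc <- uc + nbr[k, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      if (is.na(w[vr, vc])) next
      v <- (vc - 1) * nr + vr
      alt <- dist[u] + nbr[k, 3] * cell * (1 / w[ur, uc] + 1 / w[vr, vc]) / 2
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  out <- matrix(ifelse(is.finite(dist), dist, NA), nr, nc)
  out[is.na(w)] <- NA
  out
}

# hand-rolled scenario_result for toy tests
toy_result <- function(n_rate, yield, netrev) {
  structure(list(n_rate = n_rate, yield = yield, netrev = netrev),
            class = "scenario_result")
}
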