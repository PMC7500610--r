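# Market price surfaces, farm-gate maize prices under transport-cost
# arbitrage, and farm-gate nitrogen prices from a calibrated logistic
# delivery-cost model.

#' Transport and fertilizer price parameters
#'
#' @param maize_rate last-mile maize transport cost, USD per kg per hour of
#'   travel (default 0.01).
#' @param n_base_price nitrogen price at a market, USD per kg N (default
#'   0.95, derived from a urea price at 46% N content; see
#'   [urea_to_n_price()]).
#' @param L upper asymptote of the logistic delivery-cost multiplier (must
#'   exceed 1). With the calibration constraints `m(0) = 1` and `m(5) = 3`,
#'   `L = 4` gives midpoint `t0 = 2.5` h and slope `k = log(3)/2.5` per hour.
#' @param treble_hours travel time (h) at which the delivered price is three
#'   times the market price.
#' @return A list of class `transport_params` with the solved logistic slope
#'   `k` and midpoint `t0`.
#' @export
transport_params <- function(maize_rate = 0.01, n_base_price = 0.95, L = 4,
                             treble_hours = 5) {
  if (maize_rate < 0) abort("`maize_rate` must be >= 0")
  if (n_base_price <= 0) abort("`n_base_price` must be positive")
  if (L <= 3) abort("`L` must exceed 3 so the multiplier can reach 3")
  # m(t) = L / (1 + exp(-k (t - t0))); m(0) = 1 and m(treble_hours) = 3
  # give exp(k t0) = L - 1 and exp(-k (treble - t0)) = (L - 3)/3
  k <- (log(L - 1) + log(3 / (L - 3))) / treble_hours
  t0 <- log(L - 1) / k
  structure(list(maize_rate = maize_rate, n_base_price = n_base_price,
                 L = L, k = k, t0 = t0, treble_hours = treble_hours),
            class = "transport_params")
}

#' Convert a urea price to a nitrogen price
#'
#' Urea is 46% nitrogen by mass, so the price per kg of N is the urea price
#' divided by 0.46.
#'
#' @param price_urea USD per kg of urea.
#' @param n_content nitrogen mass fraction of the fertilizer.
#' @return USD per kg N.
#' @export
urea_to_n_price <- function(price_urea, n_content = 0.46) {
  price_urea / n_content
}

#' Logistic delivery-cost multiplier
#'
#' `m(t) = L / (1 + exp(-k (t - t0)))`, calibrated so the delivered price
#' equals the market price at the market (`m(0) = 1`) and trebles at
#' `treble_hours` of travel. Strictly increasing in `t` and bounded by `L`.
#'
#' @param t_hours travel time in hours (>= 0).
#' @param params a [transport_params()].
#' @return Dimensionless multiplier, same length as `t_hours`.
#' @examples
#' logistic_multiplier(c(0, 2.5, 5))
#' @export
logistic_multiplier <- function(t_hours, params = transport_params()) {
  if (any(t_hours < 0, na.rm = TRUE)) abort("travel time must be >= 0")
  params$L / (1 + exp(-params$k * (t_hours - params$t0)))
}

#' Farm-gate nitrogen price surface
#'
#' `p_N(x) = n_base_price * m(T(x))` where `T` is the travel time to the
#' nearest market; strictly increasing in travel time and equal to the base
#' price at a market cell.
#'
#' @param nearest_market_time `grid_raster` of hours to the nearest market.
#' @param params a [transport_params()].
#' @return `grid_raster` of USD per kg N.
#' @export
farmgate_nitrogen_prices <- function(nearest_market_time,
                                     params = transport_params()) {
  v <- gr_values(nearest_market_time)
  if (any(v < 0, na.rm = TRUE)) abort("negative travel times")
  gr_map(function(t) params$n_base_price * logistic_multiplier(t, params),
         nearest_market_time)
}

#' Farm-gate maize price surface under spatial arbitrage
#'
#' A farmer sells to whichever market yields the highest net-of-transport
#' price: `p_fg(x) = max_m (p_m - c T(x, m))` with transport cost rate `c`
#' in USD/kg/hr. Cells where no market yields a positive farm-gate price are
#' set to nodata and flagged, so downstream revenue is never computed at a
#' fictitious price.
#'
#' @param town_prices numeric vector, one market price (USD/kg) per layer of
#'   `tt_stack`.
#' @param tt_stack a [travel_time_per_market()] result.
#' @param c_rate transport cost rate, USD/kg/hr.
#' @return A list with `price` (`grid_raster`, USD/kg, nodata where
#'   nonpositive) and `nonpositive` (`grid_raster` flag: 1 where no positive
#'   farm-gate price exists, 0 elsewhere, NA where travel time is nodata).
#' @export
farmgate_maize_prices <- function(town_prices, tt_stack, c_rate = 0.01) {
  if (c_rate < 0) abort("`c_rate` must be >= 0")
  if (length(town_prices) != length(tt_stack$layers)) {
    abort("`town_prices` length must match the number of market layers")
  }
  best <- purrr::reduce(seq_along(town_prices), .init = NULL, function(acc, i) {
    cand <- gr_map(function(t) town_prices[i] - c_rate * t,
                   tt_stack$layers[[i]])
    if (is.null(acc)) cand else gr_map(pmax, acc, cand)
  })
  v <- gr_values(best)
  flag <- ifelse(is.na(v), NA, as.numeric(v <= 0))
  v[!is.na(v) & v <= 0] <- NA
  list(
    price = grid_raster(v, best$cell_size, best$origin),
    nonpositive = grid_raster(flag, best$cell_size, best$origin)
  )
}

#' Fit the local market price model
#'
#' Regression forest of observed market prices on market-access, demand and
#' location predictors sampled at the observation sites: travel time to the
#' nearest market, distance to the port (the largest town), population
#' density, maize cropland area, mean seasonal precipitation, and the x/y
#' coordinates. In-sample and out-of-bag diagnostics are recorded at fit
#' time.
#'
#' @param price_obs tibble from [generate_price_observations()] (needs
#'   `row`, `col`, `x`, `y`, `price`).
#' @param predictors named list of aligned `grid_raster`s; must include
#'   `travel_time`, `dist_port`, `rural_pop`, `maize_area`, `rain_mean`.
#' @param seed integer seed for the forest.
#' @param num_trees,min_node_size forest hyperparameters.
#' @return A list of class `price_model` with the fitted forest, the
#'   predictor names, and diagnostics (`oob_r2`, `rmse`).
#' @export
fit_market_price_model <- function(price_obs, predictors, seed = 1,
                                   num_trees = 500, min_node_size = 5) {
  if (nrow(price_obs) < 50) abort("need at least 50 price observations")
  do.call(gr_check_aligned, unname(predictors))
  idx <- cbind(price_obs$row, price_obs$col)
  X <- purrr::map_dfc(predictors, function(r) gr_values(r)[idx])
  X$x <- price_obs$x
  X$y <- price_obs$y
  ok <- complete.cases(X)
  if (mean(ok) < 0.9) abort("predictors missing at more than 10% of sites")
  df <- dplyr::bind_cols(price = price_obs$price[ok], X[ok, ])
  fit <- ranger::ranger(price ~ ., data = df, num.trees = num_trees,
                        min.node.size = min_node_size, seed = seed,
                        num.threads = 1)
  structure(
    list(forest = fit, predictor_names = names(X),
         oob_r2 = fit$r.squared, rmse = sqrt(fit$prediction.error),
         n_obs = sum(ok), seed = seed),
    class = "price_model"
  )
}

#' Predict the market price surface
#'
#' @param model a [fit_market_price_model()] result.
#' @param predictors same named raster list used at fit time.
#' @return `grid_raster` of USD/kg; nodata wherever any predictor is nodata.
#' @export
predict_market_prices <- function(model, predictors) {
  do.call(gr_check_aligned, unname(predictors))
  ref <- predictors[[1]]
  xy <- gr_xy(ref)
  idx <- cbind(xy$row, xy$col)
  X <- purrr::map_dfc(predictors, function(r) gr_values(r)[idx])
  X$x <- xy$x
  X$y <- xy$y
  missing_cols <- setdiff(model$predictor_names, names(X))
  if (length(missing_cols)) {
    abort(paste("missing predictors:", paste(missing_cols, collapse = ", ")))
  }
  ok <- complete.cases(X)
  pred <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    pred[ok] <- predict(model$forest, data = X[ok, ],
                        num.threads = 1)$predictions
  }
  m <- matrix(NA_real_, gr_dim(ref)[1], gr_dim(ref)[2])
  m[idx] <- pred
  grid_raster(m, ref$cell_size, ref$origin)
}

#' Market prices at town locations
#'
#' Samples the predicted market price surface at each market town cell; these
#' are the prices the arbitrage rule trades against.
#'
#' @param price_surface `grid_raster` of market prices.
#' @param towns tibble with `town_id`, `row`, `col`.
#' @return The towns tibble with a `price` column.
#' @export
town_prices <- function(price_surface, towns) {
  towns |>
    dplyr::mutate(price = gr_values(price_surface)[cbind(.data$row, .data$col)])
}

#' @export
print.price_model <- function(x, ...) {
  cat(sprintf("<price_model: %d obs, OOB R^2 %.3f, RMSE %.3f USD/kg>\n",
              x$n_obs, x$oob_r2, x$rmse))
  invisible(x)
}
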