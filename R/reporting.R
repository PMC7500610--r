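# Regional aggregation, robustness CDF curves, and pipeline orchestration.

#' Regional summary of net revenue gains
#'
#' Per-region maize-area-weighted mean gains (per-hectare gains are weighted
#' by maize area, not population; rural population and maize area totals are
#' reported alongside). Regions with zero maize area get `NA` gains, not
#' zero.
#'
#' @param gains_list named list of gains rasters (`grid_raster`, USD/ha),
#'   e.g. `list(zero_to_opnetrev = ..., bk_to_opnetrev = ...)`.
#' @param regions `grid_raster` of region ids.
#' @param region_labels optional character labels, indexed by region id.
#' @param rural_pop,maize_area aligned rasters (persons/cell, ha/cell).
#' @return A tibble with one row per region.
#' @export
regional_summary <- function(gains_list, regions, rural_pop, maize_area,
                             region_labels = NULL) {
  do.call(gr_check_aligned,
          c(unname(gains_list), list(regions, rural_pop, maize_area)))
  rid <- as.vector(gr_values(regions))
  pop <- as.vector(gr_values(rural_pop))
  mz <- as.vector(gr_values(maize_area))
  ids <- sort(unique(rid[!is.na(rid)]))
  out <- tibble::tibble(
    region_id = ids,
    region = if (is.null(region_labels)) as.character(ids) else
      region_labels[ids],
    rural_pop_millions = vapply(ids, function(i) {
      sum(pop[rid == i], na.rm = TRUE) / 1e6
    }, numeric(1)),
    maize_area_km2 = vapply(ids, function(i) {
      sum(mz[rid == i], na.rm = TRUE) / 100
    }, numeric(1))
  )
  for (nm in names(gains_list)) {
    g <- as.vector(gr_values(gains_list[[nm]]))
    out[[paste0("gain_", nm)]] <- vapply(ids, function(i) {
      sel <- rid == i & !is.na(g) & !is.na(mz) & mz > 0
      if (!any(sel)) return(NA_real_)
      sum(g[sel] * mz[sel]) / sum(mz[sel])
    }, numeric(1))
  }
  out
}

#' Robustness of gains to the assumed agronomic efficiency
#'
#' For each response scaling factor `s`, scales the incremental yield
#' response of the BK scenario by `s` (see [scale_incremental_response()]),
#' recomputes the gain of BK over ZERO, and tabulates the empirical CDF of
#' gains over the maize mask along with the share of pixels exceeding
#' `exceed_threshold` USD/ha. Larger `s` shifts the whole gain distribution
#' upward (first-order stochastic dominance).
#'
#' @param zero_result,bk_result `scenario_result`s for ZERO and BK.
#' @param prices list with `maize` and `nitrogen` price rasters.
#' @param bk_rate the BK N rate, kg/ha.
#' @param s_values scaling factors (default 1, 1.25, 1.5).
#' @param thresholds gains grid (USD/ha) at which the CDF is evaluated.
#' @param maize_area mask raster.
#' @param exceed_threshold headline exceedance threshold, USD/ha.
#' @return A list with `cdf` (tibble: `s`, `threshold`, `cdf`) and
#'   `exceedance` (tibble: `s`, `share_above`).
#' @export
robustness_cdf <- function(zero_result, bk_result, prices, bk_rate = 55,
                           s_values = c(1, 1.25, 1.5),
                           thresholds = seq(-200, 600, by = 10),
                           maize_area = NULL, exceed_threshold = 100) {
  if (length(s_values) < 1) abort("need at least one scaling factor")
  per_s <- purrr::map(s_values, function(s) {
    y_s <- scale_incremental_response(zero_result$yield, bk_result$yield, s)
    r_s <- net_revenue(y_s, prices$maize, prices$nitrogen, bk_rate)
    gr_map(function(a, b) b - a, zero_result$netrev, r_s)
  })
  mask_ok <- function(g) {
    v <- as.vector(gr_values(g))
    keep <- !is.na(v)
    if (!is.null(maize_area)) {
      mz <- as.vector(gr_values(maize_area))
      keep <- keep & !is.na(mz) & mz > 0
    }
    if (!any(keep)) abort("empty mask")
    v[keep]
  }
  cdf <- purrr::map2_dfr(s_values, per_s, function(s, g) {
    v <- mask_ok(g)
    tibble::tibble(s = s, threshold = thresholds,
                   cdf = vapply(thresholds, function(t) mean(v <= t),
                                numeric(1)))
  })
  exceedance <- purrr::map2_dfr(s_values, per_s, function(s, g) {
    tibble::tibble(s = s,
                   share_above = exceedance_share(g, exceed_threshold,
                                                  mask = maize_area))
  })
  structure(list(cdf = cdf, exceedance = exceedance,
                 gains = setNames(per_s, s_values)),
            class = "robustness_cdf")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one synthetic landscape: data generation,
#' travel time, price surfaces, yield model, the four scenarios, rainfall
#' uncertainty, adoption validation, and regional reporting. Returns all
#' intermediate objects; if `out_dir` is given, writes the landscape, the
#' summary tables (CSV) and a JSON run manifest.
#'
#' @param config a [landscape_config()].
#' @param out_dir optional output directory.
#' @param speeds a [speed_table()].
#' @param transport a [transport_params()].
#' @param spec a [scenario_spec()].
#' @param min_population market town population threshold.
#' @return A list of class `agroprofit_run` with every stage's outputs.
#' @export
run_pipeline <- function(config = landscape_config(), out_dir = NULL,
                         speeds = speed_table(),
                         transport = transport_params(),
                         spec = scenario_spec(), min_population = 50000) {
  stage <- function(name, code) {
    message(sprintf("[%s] ...", name))
    tryCatch(force(code), error = function(e) {
      abort(paste0("pipeline failed at stage `", name, "`: ",
                   conditionMessage(e)))
    })
  }

  land <- stage("simulate-data", generate_landscape(config))
  speed <- stage("friction",
                 rasterize_speeds(land$roads, land$rasters$landcover, speeds))
  tt <- stage("travel-time",
              travel_time_per_market(speed, land$towns, min_population))

  price_obs <- stage("price-obs", generate_price_observations(land))
  port <- land$towns[which.max(land$towns$population), ]
  xy <- gr_xy(speed)
  dp <- matrix(NA_real_, gr_dim(speed)[1], gr_dim(speed)[2])
  dp[cbind(xy$row, xy$col)] <- sqrt((xy$x - port$x)^2 + (xy$y - port$y)^2)
  dist_port <- grid_raster(dp, speed$cell_size, speed$origin)
  predictors <- list(
    travel_time = tt$nearest, dist_port = dist_port,
    rural_pop = land$rasters$rural_pop, maize_area = land$rasters$maize_area,
    rain_mean = land$rasters$rain_mean
  )
  pmod <- stage("price-fit",
                fit_market_price_model(price_obs, predictors,
                                       seed = stage_seed(config$seed,
                                                         "price_forest")))
  market_price <- stage("price-predict",
                        predict_market_prices(pmod, predictors))
  tp <- town_prices(market_price, tt$towns)
  fg <- stage("farmgate-maize",
              farmgate_maize_prices(tp$price, tt, transport$maize_rate))
  p_n <- stage("farmgate-n", farmgate_nitrogen_prices(tt$nearest, transport))
  prices <- list(maize = fg$price, nitrogen = p_n)

  survey <- stage("survey", generate_survey(land))
  ymod <- stage("yield-fit",
                fit_yield_model(survey,
                                seed = stage_seed(config$seed, "yield_forest")))
  ens <- stage("rainfall", seasonal_totals(land$monthly_rainfall))
  scn <- stage("scenarios",
               run_scenarios(ymod, land$rasters, ens$mean, prices, spec))
  dist <- stage("uncertainty",
                revenue_ensemble(ymod, land$rasters, scn$OPnetrev$n_rate,
                                 prices, ens))
  dist_bk <- stage("uncertainty-bk",
                   revenue_ensemble(ymod, land$rasters, scn$BK$n_rate,
                                    prices, ens))

  panel <- stage("panel",
                 generate_adoption_panel(land, dist_bk$mean, dist_bk$sd,
                                         travel_time = tt$nearest))
  panel <- stage("attach",
                 attach_model_outputs(panel, dist_bk$mean, dist_bk$sd,
                                      tt$nearest))
  lpm <- stage("validate", mundlak_lpm(panel))

  g_zero <- gains(scn$ZERO, scn$OPnetrev, land$rasters$maize_area)
  g_bk <- gains(scn$BK, scn$OPnetrev, land$rasters$maize_area)
  regional <- stage("report", regional_summary(
    list(zero_to_opnetrev = g_zero$gains, bk_to_opnetrev = g_bk$gains),
    land$regions, land$rasters$rural_pop, land$rasters$maize_area,
    land$region_labels))
  robust <- stage("robustness",
                  robustness_cdf(scn$ZERO, scn$BK, prices, spec$bk_rate,
                                 maize_area = land$rasters$maize_area))

  out <- structure(
    list(config = config, landscape = land, speed = speed, travel = tt,
         price_model = pmod, market_price = market_price, prices = prices,
         survey = survey, yield_model = ymod, ensemble = ens,
         scenarios = scn, uncertainty = dist, uncertainty_bk = dist_bk,
         panel = panel, lpm = lpm, regional = regional, robustness = robust),
    class = "agroprofit_run"
  )
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.agroprofit_run <- function(x, ...) {
  cat("agroprofit pipeline run\n")
  cat(sprintf("  grid: %d x %d, seed %d\n", x$config$grid_shape[1],
              x$config$grid_shape[2], x$config$seed))
  cat(sprintf("  price model OOB R^2: %.3f\n", x$price_model$oob_r2))
  cat(sprintf("  yield model OOB R^2: %.3f\n", x$yield_model$oob_r2))
  cat(sprintf("  adoption LPM: %d obs, %d clusters\n",
              x$lpm$n_obs, x$lpm$n_clusters))
  invisible(x)
}
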