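# Rainfall-driven uncertainty of net revenue: historical-season ensemble
# propagated through the fitted yield model at frozen scenario N rates.

#' Seasonal rainfall totals from the monthly stack
#'
#' Sums December (of the prior calendar year) through May for every season
#' year; a season is labelled by its January year. Seasons whose December
#' layer is missing are dropped. Also returns the per-pixel coefficient of
#' variation across seasons.
#'
#' @param monthly named list of `grid_raster`s (`"YYYY-MM"`).
#' @param years season years to total (default: all complete seasons).
#' @return A list of class `rainfall_ensemble`: `totals` (named list by
#'   year), `mean` raster, `cv` raster.
#' @export
seasonal_totals <- function(monthly, years = NULL) {
  nm <- names(monthly)
  yrs_avail <- sort(unique(as.integer(substr(nm, 1, 4))))
  season_months <- function(y) {
    c(sprintf("%d-12", y - 1), sprintf("%d-%02d", y, 1:5))
  }
  if (is.null(years)) {
    years <- yrs_avail[vapply(yrs_avail,
                              function(y) all(season_months(y) %in% nm),
                              logical(1))]
  } else {
    ok <- vapply(years, function(y) all(season_months(y) %in% nm), logical(1))
    if (!all(ok)) {
      abort(paste("incomplete season(s):",
                  paste(years[!ok], collapse = ", ")))
    }
  }
  if (length(years) < 1) abort("no complete seasons in the monthly stack")
  totals <- setNames(
    purrr::map(years, function(y) {
      purrr::reduce(monthly[season_months(y)],
                    function(a, b) gr_map(`+`, a, b))
    }),
    as.character(years)
  )
  structure(
    c(stack_moments(totals), list(totals = totals, years = years)),
    class = "rainfall_ensemble"
  )
}

# mean / population sd / cv rasters of a list of aligned layers
stack_moments <- function(layers) {
  do.call(gr_check_aligned, unname(layers))
  ref <- layers[[1]]
  d <- gr_dim(ref)
  arr <- array(unlist(lapply(layers, gr_values), use.names = FALSE),
               dim = c(d[1], d[2], length(layers)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- sqrt(apply(arr, c(1, 2), function(x) mean((x - mean(x))^2)))
  cv <- ifelse(!is.na(mu) & mu > 0, sdv / mu, NA_real_)
  list(
    mean = grid_raster(mu, ref$cell_size, ref$origin),
    sd = grid_raster(sdv, ref$cell_size, ref$origin),
    cv = grid_raster(cv, ref$cell_size, ref$origin)
  )
}

#' Summarise a set of net revenue layers
#'
#' Per-pixel mean, population standard deviation (the ensemble is the full
#' historical record, not a sample) and coefficient of variation. The CV is
#' nodata where the mean is non-positive.
#'
#' @param revenue_layers list of aligned `grid_raster`s (USD/ha), one per
#'   season.
#' @return A list of class `revenue_distribution` with `mean`, `sd`, `cv`
#'   rasters and `n_layers`.
#' @export
revenue_distribution <- function(revenue_layers) {
  if (length(revenue_layers) < 2) abort("need at least 2 ensemble layers")
  structure(c(stack_moments(revenue_layers),
              list(n_layers = length(revenue_layers))),
            class = "revenue_distribution")
}

#' Net revenue distribution under rainfall variability
#'
#' For each season in the ensemble, predicts yield with that season's
#' rainfall total at the *frozen* scenario N rates (farmers commit to a rate
#' before the season; rates are not re-optimised per year), computes net
#' revenue at the farm-gate prices, and summarises per pixel.
#'
#' @param yield_model a [fit_yield_model()] result.
#' @param rasters named list with `elevation`, `slope`, `soc`, `ph`.
#' @param n_rate scenario N raster (or scalar), kg/ha, held fixed.
#' @param prices list with `maize` and `nitrogen` price rasters.
#' @param ensemble a [seasonal_totals()] result.
#' @return A `revenue_distribution`.
#' @export
revenue_ensemble <- function(yield_model, rasters, n_rate, prices, ensemble) {
  if (length(ensemble$totals) < 2) abort("need at least 2 ensemble layers")
  layers <- purrr::map(ensemble$totals, function(rain) {
    y <- predict_yield_surface(yield_model, rasters, n_rate, rain)
    net_revenue(y, prices$maize, prices$nitrogen, n_rate)
  })
  revenue_distribution(layers)
}

#' Share of the crop area with CV above a threshold
#'
#' @param distribution a `revenue_distribution`.
#' @param threshold CV threshold (e.g. 0.05).
#' @param mask optional mask/weight raster (e.g. maize area).
#' @return Percentage of valid masked pixels with CV above the threshold.
#' @export
cv_exceedance <- function(distribution, threshold = 0.05, mask = NULL) {
  exceedance_share(distribution$cv, threshold, mask)
}

#' @export
print.revenue_distribution <- function(x, ...) {
  cat(sprintf("<revenue_distribution: %d layers, mean CV %.3f>\n",
              x$n_layers, gr_mean(x$cv)))
  invisible(x)
}
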