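# Fertilizer application scenarios: ZERO, blanket 55 kg/ha (BK), and
# per-pixel rates optimised for yield (OPyield) or net revenue (OPnetrev).

#' Scenario specification
#'
#' @param n_grid search grid of N rates, kg/ha; must be sorted, non-negative
#'   and contain 0 and the blanket rate.
#' @param bk_rate blanket recommendation, kg/ha.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_grid = seq(0, 200, by = 5), bk_rate = 55) {
  if (length(n_grid) == 0) abort("empty N grid")
  if (is.unsorted(n_grid) || any(n_grid < 0)) {
    abort("`n_grid` must be sorted and non-negative")
  }
  if (!all(c(0, bk_rate) %in% n_grid)) {
    abort("`n_grid` must contain 0 and the blanket rate")
  }
  structure(list(n_grid = n_grid, bk_rate = bk_rate), class = "scenario_spec")
}

#' Net revenue of fertilizer use
#'
#' `R = p_maize * Y - p_N * N` in USD/ha. Nodata in the maize farm-gate
#' price (including cells flagged as having no positive farm-gate price)
#' propagates to the result.
#'
#' @param yield `grid_raster`, kg/ha.
#' @param p_maize `grid_raster`, USD/kg.
#' @param p_nitrogen `grid_raster`, USD/kg N.
#' @param n_rate scalar or aligned `grid_raster`, kg/ha.
#' @return `grid_raster`, USD/ha.
#' @export
net_revenue <- function(yield, p_maize, p_nitrogen, n_rate) {
  nvals <- if (is_grid_raster(n_rate)) gr_values(n_rate) else n_rate
  if (any(nvals < 0, na.rm = TRUE)) abort("`n_rate` must be >= 0")
  gr_map(function(y, pm, pn, n) pm * y - pn * n,
         yield, p_maize, p_nitrogen, n_rate)
}

# predicted yield surface for every rate in the grid (list over rates),
# projected to be non-decreasing in N per pixel (cumulative max along the
# grid): the agronomic response to nitrogen is non-decreasing over this
# range, and the projection removes pixel-level forest noise that would
# otherwise produce spurious negative responses to fertilization
yield_surfaces_over_grid <- function(yield_model, rasters, seasonal_rain,
                                     n_grid, monotone = TRUE) {
  ys <- setNames(
    purrr::map(n_grid, function(n) {
      predict_yield_surface(yield_model, rasters, n, seasonal_rain)
    }),
    as.character(n_grid)
  )
  if (monotone && length(ys) > 1) {
    for (i in seq_along(ys)[-1]) {
      ys[[i]] <- gr_map(pmax, ys[[i]], ys[[i - 1]])
    }
  }
  ys
}

# per-pixel argmax of value_of(n, yield_surface) over the grid, ascending so
# ties resolve to the lowest rate
argmax_n <- function(ys, n_grid, value_of) {
  ref <- ys[[1]]
  best_obj <- gr_values(value_of(n_grid[1], ys[[1]]))
  best_n <- matrix(ifelse(is.na(best_obj), NA_real_, n_grid[1]),
                   nrow(best_obj), ncol(best_obj))
  for (i in seq_along(n_grid)[-1]) {
    obj <- gr_values(value_of(n_grid[i], ys[[i]]))
    better <- !is.na(obj) & (is.na(best_obj) | obj > best_obj)
    best_obj[better] <- obj[better]
    best_n[better] <- n_grid[i]
  }
  best_n[is.na(best_obj)] <- NA
  grid_raster(best_n, ref$cell_size, ref$origin)
}

#' Per-pixel optimal nitrogen rate
#'
#' Exhaustive search over the N grid: for each pixel the rate maximising
#' predicted yield (`objective = "yield"`) or net revenue at that pixel's
#' farm-gate prices (`objective = "netrev"`). Ties are broken toward the
#' lowest (cheapest) rate. Optimisation uses the long-run mean seasonal
#' rainfall surface.
#'
#' @param yield_model a [fit_yield_model()] result.
#' @param rasters named list with `elevation`, `slope`, `soc`, `ph`.
#' @param seasonal_rain long-run mean seasonal rainfall `grid_raster`.
#' @param prices list with `maize` and `nitrogen` price rasters (required for
#'   `objective = "netrev"`).
#' @param spec a [scenario_spec()].
#' @param objective `"yield"` or `"netrev"`.
#' @param monotone project predicted yields to be non-decreasing in N per
#'   pixel (cumulative max along the grid) before the search; the agronomic
#'   response is non-decreasing over this range, so this removes pixel-level
#'   forest noise.
#' @return `grid_raster` of optimal N, kg/ha.
#' @export
optimize_rate <- function(yield_model, rasters, seasonal_rain, prices = NULL,
                          spec = scenario_spec(),
                          objective = c("netrev", "yield"), monotone = TRUE) {
  objective <- match.arg(objective)
  ys <- yield_surfaces_over_grid(yield_model, rasters, seasonal_rain,
                                 spec$n_grid, monotone)
  objective_surface <- function(n, y) {
    if (objective == "yield") y
    else net_revenue(y, prices$maize, prices$nitrogen, n)
  }
  argmax_n(ys, spec$n_grid, objective_surface)
}

#' Run the four fertilizer scenarios
#'
#' Evaluates ZERO (no N), BK (blanket rate), OPyield (per-pixel rate
#' maximising yield) and OPnetrev (per-pixel rate maximising net revenue) on
#' a shared N grid, all at the long-run mean seasonal rainfall. The shared
#' grid makes the dominance relations exact: OPyield's yield and OPnetrev's
#' net revenue are pixelwise maxima over all scenarios.
#'
#' @inheritParams optimize_rate
#' @return A named list of `scenario_result` objects (`n_rate`, `yield`,
#'   `netrev` rasters).
#' @export
run_scenarios <- function(yield_model, rasters, seasonal_rain, prices,
                          spec = scenario_spec(), monotone = TRUE) {
  if (is.null(prices$maize) || is.null(prices$nitrogen)) {
    abort("`prices` must provide maize and nitrogen surfaces")
  }
  ys <- yield_surfaces_over_grid(yield_model, rasters, seasonal_rain,
                                 spec$n_grid, monotone)
  nr_of <- function(n, y) net_revenue(y, prices$maize, prices$nitrogen, n)
  result <- function(n_raster) {
    # look up each pixel's yield from the per-rate surfaces
    ref <- ys[[1]]
    nv <- gr_values(n_raster)
    yv <- matrix(NA_real_, nrow(nv), ncol(nv))
    for (g in spec$n_grid) {
      sel <- !is.na(nv) & nv == g
      yv[sel] <- gr_values(ys[[as.character(g)]])[sel]
    }
    yr <- grid_raster(yv, ref$cell_size, ref$origin)
    structure(list(n_rate = n_raster, yield = yr,
                   netrev = nr_of(n_raster, yr)),
              class = "scenario_result")
  }
  ref <- ys[[1]]
  list(
    ZERO = result(gr_const(ref, 0)),
    BK = result(gr_const(ref, spec$bk_rate)),
    OPyield = result(argmax_n(ys, spec$n_grid, function(n, y) y)),
    OPnetrev = result(argmax_n(ys, spec$n_grid, nr_of))
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: mean N %.1f kg/ha, mean yield %.0f kg/ha>\n",
              gr_mean(x$n_rate), gr_mean(x$yield)))
  invisible(x)
}

#' Net revenue gains between scenarios
#'
#' Elementwise net revenue difference `b - a` (the gain from switching from
#' scenario `a` to scenario `b`) with its maize-area-weighted mean.
#'
#' @param result_a,result_b `scenario_result` objects.
#' @param maize_area optional weight raster for the mean.
#' @return A list with `gains` (`grid_raster`, USD/ha) and `mean_gain`.
#' @export
gains <- function(result_a, result_b, maize_area = NULL) {
  g <- gr_map(function(a, b) b - a, result_a$netrev, result_b$netrev)
  list(gains = g, mean_gain = gr_mean(g, weights = maize_area))
}
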