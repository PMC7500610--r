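# Regression-forest maize yield response: fitting, countrywide surfaces,
# partial dependence, agronomic efficiency.

yield_predictors <- function() {
  c("n_rate", "p_rate", "intercrop", "rotation", "manure", "residue",
    "improved_seed", "fallow", "erosion_ctrl", "terraced", "weedings",
    "log_area", "head_age", "hh_size", "head_education",
    "elevation", "slope", "soc", "ph", "seasonal_rain")
}

spatial_predictors <- function() {
  c("elevation", "slope", "soc", "ph", "seasonal_rain")
}

#' Household covariate means for countrywide simulation
#'
#' Means of the non-spatial predictors, used to hold management and household
#' conditions fixed when predicting yields across the landscape. By default
#' the means are taken from the survey itself.
#'
#' @param survey a [generate_survey()] tibble.
#' @return Named numeric vector covering every non-spatial predictor.
#' @export
household_means <- function(survey) {
  vars <- setdiff(yield_predictors(), c(spatial_predictors(), "n_rate"))
  vapply(vars, function(v) mean(survey[[v]]), numeric(1))
}

#' Fit the yield response forest
#'
#' Regression forest of plot maize yield on the applied N rate, P rate,
#' management and household covariates, and the spatial covariates
#' (elevation, slope, SOC, pH, seasonal December-May rainfall). Out-of-bag
#' variance explained and permutation importances are recorded.
#'
#' @param survey a [generate_survey()] tibble (>= 100 complete rows).
#' @param num_trees,min_node_size forest hyperparameters.
#' @param seed forest seed; refits with the same seed are identical.
#' @return A list of class `yield_model`.
#' @export
fit_yield_model <- function(survey, num_trees = 500, min_node_size = 5,
                            seed = 1) {
  vars <- yield_predictors()
  missing_cols <- setdiff(c("yield", vars), names(survey))
  if (length(missing_cols)) {
    abort(paste("survey is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  df <- survey[, c("yield", vars)]
  df <- df[complete.cases(df), ]
  if (nrow(df) < 100) abort("need at least 100 complete observations")
  if (sd(df$yield) == 0) abort("constant yield response")
  fit <- ranger::ranger(yield ~ ., data = df, num.trees = num_trees,
                        min.node.size = min_node_size, seed = seed,
                        importance = "permutation", num.threads = 1)
  structure(
    list(forest = fit, predictor_names = vars, oob_r2 = fit$r.squared,
         importance = sort(fit$variable.importance, decreasing = TRUE),
         hh_means = household_means(df), n_obs = nrow(df), seed = seed,
         num_trees = num_trees, min_node_size = min_node_size),
    class = "yield_model"
  )
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf("<yield_model: %d obs, %d trees, OOB R^2 %.3f>\n",
              x$n_obs, x$num_trees, x$oob_r2))
  cat("top importances:",
      paste(names(head(x$importance, 5)), collapse = ", "), "\n")
  invisible(x)
}

# assemble the per-pixel prediction frame: spatial predictors from rasters,
# everything else held at hh_means, n_rate scalar or raster
yield_prediction_frame <- function(model, rasters, hh_means, n_rate,
                                   seasonal_rain) {
  do.call(gr_check_aligned,
          unname(c(rasters[c("elevation", "slope", "soc", "ph")],
                   list(seasonal_rain))))
  ref <- rasters$elevation
  xy <- gr_xy(ref)
  idx <- cbind(xy$row, xy$col)
  X <- tibble::tibble(
    elevation = gr_values(rasters$elevation)[idx],
    slope = gr_values(rasters$slope)[idx],
    soc = gr_values(rasters$soc)[idx],
    ph = gr_values(rasters$ph)[idx],
    seasonal_rain = gr_values(seasonal_rain)[idx]
  )
  X$n_rate <- if (is_grid_raster(n_rate)) {
    gr_check_aligned(ref, n_rate)
    gr_values(n_rate)[idx]
  } else {
    n_rate
  }
  need <- setdiff(model$predictor_names, names(X))
  miss <- setdiff(need, names(hh_means))
  if (length(miss)) {
    abort(paste("household means missing predictors:",
                paste(miss, collapse = ", ")))
  }
  for (v in need) X[[v]] <- hh_means[[v]]
  list(X = X[, model$predictor_names], idx = idx, ref = ref)
}

#' Predict a countrywide yield surface
#'
#' Per-pixel forest prediction at a given N rate, spatial predictors from the
#' landscape rasters, seasonal rainfall from the supplied raster, and all
#' non-spatial predictors held at the household means. Nodata in any input
#' propagates to the output.
#'
#' @param model a [fit_yield_model()] result.
#' @param rasters named list with `elevation`, `slope`, `soc`, `ph`.
#' @param n_rate scalar kg/ha or aligned `grid_raster`.
#' @param seasonal_rain aligned `grid_raster` of seasonal rainfall, mm.
#' @param hh_means named vector (defaults to the means stored in the model).
#' @return `grid_raster` of predicted yield, kg/ha.
#' @export
predict_yield_surface <- function(model, rasters, n_rate, seasonal_rain,
                                  hh_means = NULL) {
  nvals <- if (is_grid_raster(n_rate)) gr_values(n_rate) else n_rate
  if (any(nvals < 0, na.rm = TRUE)) abort("`n_rate` must be >= 0")
  hh_means <- hh_means %||% model$hh_means
  pf <- yield_prediction_frame(model, rasters, hh_means, n_rate, seasonal_rain)
  ok <- complete.cases(pf$X)
  pred <- rep(NA_real_, nrow(pf$X))
  if (any(ok)) {
    pred[ok] <- predict(model$forest, data = pf$X[ok, ],
                        num.threads = 1)$predictions
  }
  if (any(pred < 0, na.rm = TRUE)) abort("negative yield prediction")
  d <- gr_dim(pf$ref)
  m <- matrix(NA_real_, d[1], d[2])
  m[pf$idx] <- pred
  grid_raster(m, pf$ref$cell_size, pf$ref$origin)
}

#' Partial dependence of the yield forest
#'
#' Average prediction over a background sample of survey rows with one
#' predictor clamped to each grid value in turn.
#'
#' @param model a [fit_yield_model()] result.
#' @param survey background data (survey tibble).
#' @param variable predictor to sweep.
#' @param grid numeric grid of values for `variable`.
#' @param sample_n background subsample size (for speed).
#' @param seed subsample seed.
#' @return A tibble with `value` and `yhat`.
#' @export
partial_dependence <- function(model, survey, variable, grid,
                               sample_n = 200, seed = 1) {
  if (!variable %in% model$predictor_names) {
    abort(paste("unknown variable:", variable))
  }
  df <- survey[, model$predictor_names]
  df <- df[complete.cases(df), ]
  bg <- eval_with_seed(seed, df[sample(nrow(df), min(sample_n, nrow(df))), ])
  yhat <- vapply(grid, function(g) {
    bg[[variable]] <- g
    mean(predict(model$forest, data = bg, num.threads = 1)$predictions)
  }, numeric(1))
  tibble::tibble(value = grid, yhat = yhat)
}

#' Agronomic efficiency surface
#'
#' `AE = (Y_N - Y_0) / N` in kg grain per kg N, elementwise, with the mean
#' reported over the maize-area mask.
#'
#' @param yield_at_n,yield_at_0 aligned yield rasters, kg/ha.
#' @param n_rate the N rate of `yield_at_n`, kg/ha (> 0).
#' @param maize_area optional weight/mask raster for the mean.
#' @return A list with `ae` (`grid_raster`) and `mean_ae` (scalar).
#' @export
agronomic_efficiency <- function(yield_at_n, yield_at_0, n_rate,
                                 maize_area = NULL) {
  if (n_rate <= 0) abort("`n_rate` must be positive")
  ae <- gr_map(function(a, b) (a - b) / n_rate, yield_at_n, yield_at_0)
  list(ae = ae, mean_ae = gr_mean(ae, weights = maize_area))
}

#' Scale the incremental yield response
#'
#' Robustness-check transform: `Y_s = Y_0 + s (Y_N - Y_0)`, leaving the
#' zero-N yield unchanged and multiplying the agronomic efficiency by `s`
#' exactly (e.g. `s = 1.25` maps a mean AE of 7.2 to 9.0 kg/kg).
#'
#' @param yield_at_0,yield_at_n aligned yield rasters, kg/ha.
#' @param s positive scaling factor.
#' @return `grid_raster` of scaled yields, kg/ha.
#' @export
scale_incremental_response <- function(yield_at_0, yield_at_n, s) {
  if (s < 0) abort("`s` must be non-negative")
  gr_map(function(y0, yn) y0 + s * (yn - y0), yield_at_0, yield_at_n)
}
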