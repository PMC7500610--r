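# Plain-text artifact I/O: ASCII grids for rasters, GeoJSON for vector
# layers, CSV for tables, YAML for configs, JSON for run manifests.

towns_to_geojson <- function(towns, path) {
  features <- purrr::pmap(towns, function(town_id, x, y, population, ...) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = list(town_id = town_id, population = population))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

roads_to_geojson <- function(roads, path) {
  features <- purrr::pmap(roads, function(x0, y0, x1, y1, class) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(x0, y0), c(x1, y1))),
         properties = list(class = class))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read roads back from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of two-point LineStrings with a
#'   `class` property.
#' @return A roads tibble (`x0`, `y0`, `x1`, `y1`, `class`).
#' @export
roads_from_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  purrr::map_dfr(gj$features, function(f) {
    cc <- f$geometry$coordinates
    tibble::tibble(
      x0 = cc[[1]][[1]], y0 = cc[[1]][[2]],
      x1 = cc[[2]][[1]], y1 = cc[[2]][[2]],
      class = f$properties$class
    )
  })
}

#' Write a landscape bundle to disk
#'
#' Rasters as ASCII grids, towns/roads as GeoJSON, the config as YAML.
#' Monthly rainfall is written as one ASCII grid per month under
#' `rainfall/`.
#'
#' @param landscape a [generate_landscape()] result.
#' @param dir output directory (created if needed).
#' @param monthly write the monthly rainfall stack too (can be large).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir, monthly = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(landscape$rasters)) {
    write_ascii_grid(landscape$rasters[[nm]], file.path(dir,
                                                        paste0(nm, ".asc")))
  }
  write_ascii_grid(landscape$regions, file.path(dir, "regions.asc"))
  towns_to_geojson(landscape$towns, file.path(dir, "towns.geojson"))
  roads_to_geojson(landscape$roads, file.path(dir, "roads.geojson"))
  cfg <- landscape$config
  cfg$yield <- unclass(cfg$yield)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yml"))
  if (monthly) {
    mdir <- file.path(dir, "rainfall")
    dir.create(mdir, showWarnings = FALSE)
    for (nm in names(landscape$monthly_rainfall)) {
      write_ascii_grid(landscape$monthly_rainfall[[nm]],
                       file.path(mdir, paste0(nm, ".asc")))
    }
  }
  invisible(dir)
}

#' Read a landscape config from YAML
#'
#' @param path YAML file written by [write_landscape()] or by hand.
#' @return A [landscape_config()].
#' @export
read_landscape_config <- function(path) {
  y <- yaml::read_yaml(path)
  yld <- if (!is.null(y$yield)) do.call(yield_dgp_params, y$yield) else
    yield_dgp_params()
  keep <- intersect(names(y), names(formals(landscape_config)))
  args <- y[setdiff(keep, "yield")]
  args$yield <- yld
  do.call(landscape_config, args)
}

#' Write pipeline outputs to disk
#'
#' Summary tables as CSV, headline rasters as ASCII grids, and a JSON run
#' manifest (seed, grid, diagnostics).
#'
#' @param run an `agroprofit_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_landscape(run$landscape, file.path(dir, "landscape"))
  readr::write_csv(run$survey, file.path(dir, "survey.csv"))
  readr::write_csv(run$panel, file.path(dir, "panel.csv"))
  readr::write_csv(run$regional, file.path(dir, "regional_summary.csv"))
  readr::write_csv(run$robustness$cdf, file.path(dir, "robustness_cdf.csv"))
  readr::write_csv(tidy(run$lpm), file.path(dir, "adoption_lpm.csv"))
  for (nm in names(run$scenarios)) {
    res <- run$scenarios[[nm]]
    write_ascii_grid(res$n_rate, file.path(dir, paste0(nm, "_n_rate.asc")))
    write_ascii_grid(res$netrev, file.path(dir, paste0(nm, "_netrev.asc")))
  }
  write_ascii_grid(run$prices$maize, file.path(dir, "farmgate_maize.asc"))
  write_ascii_grid(run$prices$nitrogen, file.path(dir, "farmgate_n.asc"))
  write_ascii_grid(run$uncertainty$cv, file.path(dir, "netrev_cv.asc"))
  manifest <- list(
    seed = run$config$seed,
    grid_shape = run$config$grid_shape,
    price_model_oob_r2 = run$price_model$oob_r2,
    yield_model_oob_r2 = run$yield_model$oob_r2,
    lpm_n_obs = run$lpm$n_obs,
    lpm_r_squared = run$lpm$r_squared,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
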