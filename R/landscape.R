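# Synthetic study landscapes with known ground truth.
#
# Every downstream stage (travel time, prices, yield response, scenarios,
# uncertainty, adoption) is exercised against landscapes generated here, so
# the generator carries the study-design constants: survey size (455
# households / 601 observations), the Table-1-style covariate moments, a mean
# agronomic efficiency at 55 kg N/ha of about 7.2 kg grain per kg N, and an
# adoption process driven positively by log expected net revenue and
# negatively by its standard deviation.

# ---- seeding ---------------------------------------------------------------

# Named substream: one root seed, stage-specific offsets, always < 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 99991 * (h %% 20011)) %% 2147483629)
}

# Run code under a seed without clobbering the caller's RNG state.
eval_with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# ---- smooth random fields --------------------------------------------------

conv_reflect <- function(x, k) {
  w <- (length(k) - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[pmin(w:1, n)], x, x[pmax(n - (1:w) + 1L, 1L)])
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(w + 1L):(w + n)])
}

# Separable Gaussian blur with reflected edges.
gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  m <- t(apply(m, 1, conv_reflect, k = k))
  m <- apply(m, 2, conv_reflect, k = k)
  m
}

# Standardised (mean 0, sd 1) spatially autocorrelated field.
smooth_field <- function(nr, nc, sigma = 6) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  s <- gaussian_smooth(z, sigma)
  (s - mean(s)) / sd(s)
}

# ---- configuration ---------------------------------------------------------

#' Parameters of the true yield data-generating process
#'
#' The noiseless yield surface is
#' `Y = Ymax(soc, elev) * (1 - exp(-k_N * (N + N_soil))) * rain / (rain + rain_halfsat)`
#' with `Ymax = Ymax_base * exp(soc_coef * (soc - 20)/20 + elev_coef * (elev - 1000)/1000)`.
#' The defaults are solved so that, at mean covariates (seasonal rain 900 mm,
#' SOC 20 g/kg, elevation 1000 m), the zero-N yield is close to 2510 kg/ha and
#' the agronomic efficiency at 55 kg N/ha is 7.2 kg grain per kg N.
#'
#' @param Ymax_base potential yield at mean SOC/elevation and unlimited water,
#'   kg/ha.
#' @param k_N response curvature per kg N/ha.
#' @param N_soil native soil N supply, kg/ha.
#' @param rain_halfsat seasonal rainfall (mm) at which the water modifier is
#'   1/2.
#' @param soc_coef,elev_coef log-linear modifiers of `Ymax` per relative unit
#'   of SOC and elevation.
#' @param noise_sd standard deviation of the additive yield noise, kg/ha.
#' @return A list of class `yield_dgp_params`.
#' @export
yield_dgp_params <- function(Ymax_base = 6520, k_N = 0.004, N_soil = 203,
                             rain_halfsat = 400, soc_coef = 0.30,
                             elev_coef = -0.20, noise_sd = 1000) {
  stopifnot(Ymax_base > 0, k_N > 0, N_soil >= 0, rain_halfsat > 0,
            noise_sd >= 0)
  structure(list(Ymax_base = Ymax_base, k_N = k_N, N_soil = N_soil,
                 rain_halfsat = rain_halfsat, soc_coef = soc_coef,
                 elev_coef = elev_coef, noise_sd = noise_sd),
            class = "yield_dgp_params")
}

#' Configure a synthetic landscape
#'
#' Holds the study-design constants for one synthetic study: grid geometry,
#' rainfall climatology, number of towns, survey size and adoption-panel
#' design. Defaults mirror the scale of the motivating smallholder maize
#' study: 455 surveyed households contributing 601 plot observations, 601
#' market price observations, 40 rainfall seasons (1980-2019), and a 3-wave
#' adoption panel of about 1940 households (~5,819 observations).
#'
#' @param grid_shape integer (rows, cols), at least 20 x 20.
#' @param cell_size_km cell edge length in km.
#' @param years seasons to simulate (labelled by their January year).
#' @param n_towns number of market towns (>= 2).
#' @param n_regions number of administrative regions (Voronoi partition).
#' @param n_households,n_obs survey households and plot observations
#'   (`n_obs >= n_households`).
#' @param n_price_obs number of market price observations.
#' @param seed root seed; all stages draw from named substreams of it.
#' @param yield [yield_dgp_params()].
#' @param rain_mean,rain_sd,rain_min,rain_max long-run seasonal rainfall field
#'   (mm): mean, spatial SD, clip range.
#' @param rain_cv interannual coefficient of variation of the seasonal total
#'   (0 gives identical seasons).
#' @param panel_households,panel_waves,panel_clusters adoption-panel design;
#'   defaults give 1940 x 3 = 5820 observations in about 194 enumeration-area
#'   clusters.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(grid_shape = c(60, 60), cell_size_km = 1,
                             years = 1980:2019, n_towns = 6, n_regions = 25,
                             n_households = 455, n_obs = 601,
                             n_price_obs = 601, seed = 1,
                             yield = yield_dgp_params(),
                             rain_mean = 900, rain_sd = 250,
                             rain_min = 300, rain_max = 1500, rain_cv = 0.15,
                             panel_households = 1940, panel_waves = 3,
                             panel_clusters = 194) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 20)) {
    abort("`grid_shape` must be two integers, each >= 20")
  }
  if (cell_size_km <= 0) abort("`cell_size_km` must be positive")
  if (n_obs < n_households) abort("`n_obs` must be >= `n_households`")
  if (n_towns < 2) abort("need at least 2 towns")
  if (n_regions < 2) abort("need at least 2 regions")
  if (rain_cv < 0 || rain_min < 0) abort("rainfall parameters must be non-negative")
  structure(
    list(grid_shape = grid_shape, cell_size_km = cell_size_km,
         years = as.integer(years), n_towns = as.integer(n_towns),
         n_regions = as.integer(n_regions),
         n_households = as.integer(n_households), n_obs = as.integer(n_obs),
         n_price_obs = as.integer(n_price_obs), seed = as.integer(seed),
         yield = yield, rain_mean = rain_mean, rain_sd = rain_sd,
         rain_min = rain_min, rain_max = rain_max, rain_cv = rain_cv,
         panel_households = as.integer(panel_households),
         panel_waves = as.integer(panel_waves),
         panel_clusters = as.integer(panel_clusters)),
    class = "landscape_config"
  )
}

# ---- yield DGP oracle ------------------------------------------------------

#' Noiseless true yield surface of the synthetic landscape
#'
#' Closed-form oracle behind the synthetic survey: a saturating-exponential
#' response in applied plus native nitrogen, times a Michaelis-Menten seasonal
#' rainfall modifier, times a log-linear soil/terrain potential. Strictly
#' increasing and concave in the nitrogen rate and increasing in rainfall.
#'
#' @param n_rate applied N, kg/ha (scalar or vector, >= 0).
#' @param seasonal_rain seasonal (December-May) rainfall total, mm (>= 0).
#' @param soc soil organic carbon, g/kg.
#' @param elevation elevation, m.
#' @param params [yield_dgp_params()].
#' @return Yield in kg/ha (noiseless).
#' @examples
#' true_yield(55, 900, 20, 1000)
#' @export
true_yield <- function(n_rate, seasonal_rain, soc = 20, elevation = 1000,
                       params = yield_dgp_params()) {
  if (any(n_rate < 0, na.rm = TRUE)) abort("`n_rate` must be >= 0")
  if (any(seasonal_rain < 0, na.rm = TRUE)) abort("`seasonal_rain` must be >= 0")
  ymax <- params$Ymax_base *
    exp(params$soc_coef * (soc - 20) / 20 +
        params$elev_coef * (elevation - 1000) / 1000)
  ymax * (1 - exp(-params$k_N * (n_rate + params$N_soil))) *
    seasonal_rain / (seasonal_rain + params$rain_halfsat)
}

# ---- landscape generator ---------------------------------------------------

# Cells covered by the segment (x0,y0)-(x1,y1), by dense sampling along it.
segment_cells <- function(r, x0, y0, x1, y1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len / (r$cell_size / 4)))
  t <- seq(0, 1, length.out = n)
  idx <- gr_cell_at(r, x0 + t * (x1 - x0), y0 + t * (y1 - y0))
  dplyr::distinct(idx)
}

# Minimum spanning tree over points (Prim), returning an edge tibble.
mst_edges <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    j <- which.min(dd)
    from <- which(in_tree)[(j - 1) %% nrow(dd) + 1]
    to <- which(!in_tree)[(j - 1) %/% nrow(dd) + 1]
    in_tree[to] <- TRUE
    edges[[i]] <- tibble::tibble(from = from, to = to)
  }
  dplyr::bind_rows(edges)
}

#' Generate a synthetic study landscape
#'
#' Builds the complete input bundle for the analysis: smooth spatially
#' autocorrelated rasters (elevation, slope, SOC, pH, long-run seasonal
#' rainfall), a categorical land cover layer, maize cropland area and rural
#' population, a monthly rainfall history, a connected road network linking
#' market towns (spanning tree; road class assigned by town-population rank),
#' and a Voronoi partition into administrative regions. Deterministic given
#' the config seed.
#'
#' Land cover classes: 1 = cropland, 2 = grassland, 3 = forest, 4 = water.
#' Monthly rainfall covers December of the year before the first season
#' through November of the last season year, so every requested season has
#' its full December-May window.
#'
#' @param config a [landscape_config()].
#' @return A list of class `landscape` with elements `config`, `rasters`
#'   (named list of `grid_raster`), `monthly_rainfall` (named list
#'   `"YYYY-MM"`), `roads` (tibble of segments with `class`), `towns` (tibble
#'   with `town_id`, `x`, `y`, `population`), `regions` (a `grid_raster` of
#'   region ids) and `region_labels`.
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "landscape_config")) {
    abort("`config` must be created with landscape_config()")
  }
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size_km
  template <- grid_raster(matrix(0, nr, nc), cs)

  eval_with_seed(stage_seed(config$seed, "landscape"), {
    as_gr <- function(m) grid_raster(m, cs)
    # ~4 km correlation length: enough independent patches on the default
    # 60 km domain for realized field variances to be stable across seeds
    elev_m <- pmin(pmax(1000 + 400 * smooth_field(nr, nc, 4), 0), 2500)
    soc_m <- pmin(pmax(20 + 6 * smooth_field(nr, nc, 4), 5), 40)
    ph_m <- pmin(pmax(6.2 + 0.7 * smooth_field(nr, nc, 4), 4.5), 8)
    rain_m <- pmin(pmax(config$rain_mean + config$rain_sd * smooth_field(nr, nc, 4),
                        config$rain_min), config$rain_max)

    # slope from central differences of elevation (degrees)
    gx <- (elev_m[, pmin(1:nc + 1, nc)] - elev_m[, pmax(1:nc - 1, 1)]) /
      (2 * cs * 1000)
    gy <- (elev_m[pmin(1:nr + 1, nr), ] - elev_m[pmax(1:nr - 1, 1), ]) /
      (2 * cs * 1000)
    slope_m <- atan(sqrt(gx^2 + gy^2)) * 180 / pi

    # land cover from quantiles of its own smooth field
    lc_f <- smooth_field(nr, nc, sigma = 4)
    q <- quantile(lc_f, c(0.45, 0.75, 0.95))
    lc_m <- matrix(1, nr, nc)
    lc_m[lc_f > q[1]] <- 2
    lc_m[lc_f > q[2]] <- 3
    lc_m[lc_f > q[3]] <- 4

    # maize area (ha per cell): a share of cropland/grassland cells
    share <- stats::plogis(0.8 * smooth_field(nr, nc, sigma = 5))
    maize_m <- 100 * cs^2 * share * 0.6
    maize_m[lc_m >= 3] <- 0

    pop_m <- exp(3 + 1.2 * smooth_field(nr, nc, sigma = 5))

    # towns on non-water cells; top two populations forced above 50,000
    land_cells <- which(lc_m != 4, arr.ind = TRUE)
    pick <- land_cells[sample(nrow(land_cells), config$n_towns), , drop = FALSE]
    pops <- sort(round(exp(rnorm(config$n_towns, log(25000), 0.8))),
                 decreasing = TRUE)
    pops[1] <- max(pops[1], 120000)
    pops[2] <- max(pops[2], 80000)
    towns <- tibble::tibble(
      town_id = seq_len(config$n_towns),
      row = as.integer(pick[, 1]), col = as.integer(pick[, 2]),
      x = (pick[, 2] - 0.5) * cs, y = (pick[, 1] - 0.5) * cs,
      population = pops
    )

    # roads: spanning tree over towns; class from larger endpoint population
    ed <- mst_edges(towns)
    roads <- ed |>
      dplyr::mutate(
        x0 = towns$x[.data$from], y0 = towns$y[.data$from],
        x1 = towns$x[.data$to], y1 = towns$y[.data$to],
        pop_max = pmax(towns$population[.data$from], towns$population[.data$to]),
        class = dplyr::case_when(
          .data$pop_max >= 50000 ~ "primary",
          .data$pop_max >= 20000 ~ "secondary",
          TRUE ~ "tertiary"
        )
      ) |>
      dplyr::select("x0", "y0", "x1", "y1", "class")

    # regions: Voronoi partition of random seed points
    rseed <- tibble::tibble(
      x = runif(config$n_regions, 0, nc * cs),
      y = runif(config$n_regions, 0, nr * cs)
    )
    xy <- gr_xy(template)
    d2 <- outer(xy$x, rseed$x, `-`)^2 + outer(xy$y, rseed$y, `-`)^2
    reg <- max.col(-d2)
    reg_m <- matrix(NA_real_, nr, nc)
    reg_m[cbind(xy$row, xy$col)] <- reg
    region_labels <- sprintf("R%02d", seq_len(config$n_regions))

    # monthly rainfall: per-season smooth anomaly factor, fixed month weights
    wet <- c("12" = 0.10, "01" = 0.18, "02" = 0.20, "03" = 0.20,
             "04" = 0.18, "05" = 0.14)
    dry_w <- 0.02  # of the seasonal total, per off-season month
    monthly <- list()
    for (yr in config$years) {
      fac <- if (config$rain_cv > 0) {
        exp(config$rain_cv * smooth_field(nr, nc, sigma = 8) -
              config$rain_cv^2 / 2)
      } else {
        matrix(1, nr, nc)
      }
      season_tot <- rain_m * fac
      monthly[[sprintf("%d-12", yr - 1)]] <- as_gr(season_tot * wet[["12"]])
      for (mo in c("01", "02", "03", "04", "05")) {
        monthly[[sprintf("%d-%s", yr, mo)]] <- as_gr(season_tot * wet[[mo]])
      }
      for (mo in c("06", "07", "08", "09", "10", "11")) {
        monthly[[sprintf("%d-%s", yr, mo)]] <- as_gr(season_tot * dry_w)
      }
    }
    monthly <- monthly[order(names(monthly))]

    structure(
      list(
        config = config,
        rasters = list(
          elevation = as_gr(elev_m), slope = as_gr(slope_m),
          soc = as_gr(soc_m), ph = as_gr(ph_m),
          rain_mean = as_gr(rain_m), landcover = as_gr(lc_m),
          maize_area = as_gr(maize_m), rural_pop = as_gr(pop_m)
        ),
        monthly_rainfall = monthly,
        roads = roads, towns = towns,
        regions = as_gr(reg_m), region_labels = region_labels
      ),
      class = "landscape"
    )
  })
}

#' @export
print.landscape <- function(x, ...) {
  d <- x$config$grid_shape
  cat(sprintf(paste0(
    "<landscape %d x %d km grid, %d towns, %d regions, %d monthly rainfall ",
    "layers>\n"), d[1], d[2], nrow(x$towns), x$config$n_regions,
    length(x$monthly_rainfall)))
  invisible(x)
}
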