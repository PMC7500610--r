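# Synthetic farm survey, market price observations, and adoption panel.

#' Target moments of the synthetic farm survey
#'
#' Means and standard deviations the survey generator reproduces: maize yield
#' and management covariates of a smallholder maize survey (455 households,
#' 601 plot observations). Binary shares are drawn as exact counts; continuous
#' covariates are moment-matched to the target mean/SD; yields are *not*
#' matched — they come from the yield DGP, so the sample mean yield is a
#' genuine check on the DGP calibration.
#'
#' @return A tibble with `variable`, `mean`, `sd`, `type`.
#' @export
survey_targets <- function() {
  tibble::tribble(
    ~variable,        ~mean,   ~sd,     ~type,
    "yield",          2604.0,  1832.8,  "dgp",
    "fert_user",      0.357,   0.479,   "binary",
    "n_rate_users",   35.2,    98.0,    "positive",
    "p_rate_users",   11.5,    45.4,    "positive",
    "intercrop",      0.573,   0.4950,  "binary",
    "rotation",       0.062,   0.2407,  "binary",
    "manure",         0.203,   0.4028,  "binary",
    "residue",        0.090,   0.2864,  "binary",
    "weedings",       1.827,   0.5542,  "count",
    "improved_seed",  0.148,   0.3557,  "binary",
    "fallow",         0.040,   0.1961,  "binary",
    "erosion_ctrl",   0.245,   0.4304,  "binary",
    "terraced",       0.035,   0.1839,  "binary",
    "log_area",       -0.507,  0.9556,  "continuous",
    "head_age",       47.702,  13.7150, "continuous",
    "hh_size",        5.692,   3.1144,  "count",
    "head_education", 7.067,   3.5461,  "continuous"
  )
}

# rescale draws to hit the target mean and sd exactly
match_moments <- function(x, mean, sd) {
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}

# exact-count binary vector with share as close to p as n allows
exact_binary <- function(n, p) {
  sample(c(rep(1, round(n * p)), rep(0, n - round(n * p))))
}

# additive management effects on yield (kg/ha); centred near zero at the
# target covariate shares so they perturb, not shift, the mean yield
mgmt_effect <- function(s) {
  875 * s$improved_seed + 625 * s$manure + 250 * s$residue -
    500 * s$intercrop + 200 * s$rotation + 375 * s$fallow +
    125 * s$erosion_ctrl + 125 * s$terraced + 375 * (s$weedings - 1.827) +
    5 * s$p_rate
}

#' Generate the synthetic farm survey
#'
#' Draws `n_households` locations on maize-growing cells, assigns
#' `n_obs - n_households` repeat observations to randomly chosen households,
#' builds management and household covariates matching [survey_targets()],
#' and produces yields from [true_yield()] at each plot's covariates plus
#' additive management effects and Gaussian noise.
#'
#' @param landscape a [generate_landscape()] result.
#' @param params [yield_dgp_params()]; defaults to the landscape config's.
#' @param noise_sd override for the yield noise SD (kg/ha); `NULL` uses
#'   `params$noise_sd`. Zero gives noiseless oracle yields.
#' @param management_effects if `FALSE`, yields omit the additive management
#'   effects, so with `noise_sd = 0` every yield equals the [true_yield()]
#'   oracle at that plot's covariates.
#' @return A tibble with one row per plot observation: identifiers,
#'   coordinates, yield, input rates, management dummies and household
#'   covariates, plus the plot's season year and covariate columns
#'   (`seasonal_rain`, `soc`, `elevation`, `slope`, `ph`).
#' @export
generate_survey <- function(landscape, params = NULL, noise_sd = NULL,
                            management_effects = TRUE) {
  config <- landscape$config
  params <- params %||% config$yield
  noise_sd <- noise_sd %||% params$noise_sd
  tg <- survey_targets()
  tgt <- function(v) tg[tg$variable == v, ]
  n <- config$n_obs

  eval_with_seed(stage_seed(config$seed, "survey"), {
    maize <- landscape$rasters$maize_area
    cells <- which(gr_values(maize) > 0, arr.ind = TRUE)
    if (nrow(cells) < config$n_households) abort("too few maize cells for survey")
    hh_cells <- cells[sample(nrow(cells), config$n_households), , drop = FALSE]
    cs <- maize$cell_size
    hh <- tibble::tibble(
      hh_id = seq_len(config$n_households),
      row = as.integer(hh_cells[, 1]), col = as.integer(hh_cells[, 2]),
      x = (hh_cells[, 2] - 1 + runif(config$n_households)) * cs,
      y = (hh_cells[, 1] - 1 + runif(config$n_households)) * cs
    )
    extra <- sample(hh$hh_id, n - config$n_households, replace = TRUE)
    s <- hh[c(hh$hh_id, extra), ] |>
      dplyr::mutate(obs_id = dplyr::row_number())

    # input use: exact user share; rates heavy-tailed, moment-matched mean
    s$fert_user <- exact_binary(n, tgt("fert_user")$mean)
    nu <- sum(s$fert_user)
    # heavy-tailed lognormal rates among users (CV 1.8, median ~17 kg/ha):
    # dispersed like observed smallholder rates while keeping the mid-range
    # of the response curve populated enough to be learnable at n ~ 600
    s2 <- log(1 + 1.8^2)
    raw <- stats::rlnorm(nu, log(35.2) - s2 / 2, sqrt(s2))
    s$n_rate <- 0
    # cap at 300 kg/ha: beyond any observed smallholder practice
    s$n_rate[s$fert_user == 1] <-
      pmin(raw / mean(raw) * tgt("n_rate_users")$mean, 300)
    praw <- 0.25 * s$n_rate[s$fert_user == 1] +
      rgamma(nu, shape = 0.5, rate = 1) * 5
    s$p_rate <- 0
    s$p_rate[s$fert_user == 1] <- praw / mean(praw) * tgt("p_rate_users")$mean

    for (v in c("intercrop", "rotation", "manure", "residue", "improved_seed",
                "fallow", "erosion_ctrl", "terraced")) {
      s[[v]] <- exact_binary(n, tgt(v)$mean)
    }
    s$weedings <- 1 + exact_binary(n, tgt("weedings")$mean - 1)
    s$log_area <- match_moments(rnorm(n), tgt("log_area")$mean,
                                tgt("log_area")$sd)
    s$head_age <- match_moments(rnorm(n), tgt("head_age")$mean,
                                tgt("head_age")$sd)
    s$hh_size <- pmax(1, round(match_moments(rnorm(n), tgt("hh_size")$mean,
                                             tgt("hh_size")$sd)))
    s$head_education <- pmax(0, match_moments(rnorm(n),
                                              tgt("head_education")$mean,
                                              tgt("head_education")$sd))

    # season: one of the simulated years per observation
    s$season <- sample(config$years, n, replace = TRUE)
    idx <- cbind(s$row, s$col)
    s$soc <- gr_values(landscape$rasters$soc)[idx]
    s$elevation <- gr_values(landscape$rasters$elevation)[idx]
    s$slope <- gr_values(landscape$rasters$slope)[idx]
    s$ph <- gr_values(landscape$rasters$ph)[idx]
    seas <- seasonal_totals(landscape$monthly_rainfall, years = config$years)
    s$seasonal_rain <- vapply(seq_len(n), function(i) {
      gr_values(seas$totals[[as.character(s$season[i])]])[s$row[i], s$col[i]]
    }, numeric(1))

    base_yield <- true_yield(s$n_rate, s$seasonal_rain, s$soc, s$elevation,
                             params)
    mg <- if (management_effects) mgmt_effect(s) else 0
    s$yield <- pmax(0, base_yield + mg + rnorm(n, sd = noise_sd))
    dplyr::select(
      s, "hh_id", "obs_id", "x", "y", "row", "col", "season", "yield",
      "n_rate", "p_rate", "fert_user", "intercrop", "rotation", "manure",
      "residue", "improved_seed", "fallow", "erosion_ctrl", "terraced",
      "weedings", "log_area", "head_age", "hh_size", "head_education",
      "seasonal_rain", "soc", "elevation", "slope", "ph"
    )
  })
}

# known smooth market-price function (USD/kg): increases with remoteness from
# towns, decreases with local demand (population), mild coordinate trend
true_price_function <- function(landscape) {
  towns <- landscape$towns
  pop <- landscape$rasters$rural_pop
  xy <- gr_xy(pop)
  d <- sqrt(outer(xy$x, towns$x, `-`)^2 + outer(xy$y, towns$y, `-`)^2)
  dmin <- apply(d, 1, min)
  # remoteness kernel is flat at d = 0 with a ~25 km length scale, so the
  # function is resolvable at the survey's sampling density (601 sites)
  p <- 0.18 + 0.40 * (1 - exp(-(dmin / 25)^2)) +
    0.12 * (1 - as.vector(t(gr_values(pop))) /
              (as.vector(t(gr_values(pop))) + 60)) +
    0.05 * sin(xy$x / 15) * cos(xy$y / 15)
  m <- matrix(NA_real_, gr_dim(pop)[1], gr_dim(pop)[2])
  m[cbind(xy$row, xy$col)] <- pmin(pmax(p, 0.07), 0.94)
  grid_raster(m, pop$cell_size, pop$origin)
}

#' Generate observed market maize prices
#'
#' Samples locations over the landscape and reads prices off a known smooth
#' function of remoteness (distance to the nearest town), population density
#' and location, plus optional Gaussian noise, clipped to `bounds`.
#'
#' @param landscape a [generate_landscape()] result.
#' @param n number of observations (default from config).
#' @param noise_sd observation noise SD in USD/kg; 0 recovers the true
#'   function exactly.
#' @param bounds length-2 price bounds in USD/kg.
#' @return A tibble with `obs_id`, `x`, `y`, `row`, `col`, `price`.
#' @export
generate_price_observations <- function(landscape, n = NULL, noise_sd = 0.05,
                                        bounds = c(0.07, 0.94)) {
  config <- landscape$config
  n <- n %||% config$n_price_obs
  truth <- true_price_function(landscape)
  eval_with_seed(stage_seed(config$seed, "prices"), {
    d <- gr_dim(truth)
    rows <- sample(d[1], n, replace = TRUE)
    cols <- sample(d[2], n, replace = TRUE)
    cs <- truth$cell_size
    base <- gr_values(truth)[cbind(rows, cols)]
    price <- pmin(pmax(base + rnorm(n, sd = noise_sd), bounds[1]), bounds[2])
    tibble::tibble(
      obs_id = seq_len(n), row = rows, col = cols,
      x = (cols - 0.5) * cs, y = (rows - 0.5) * cs, price = price
    )
  })
}

#' Default adoption-process coefficients
#'
#' Linear-probability coefficients of the synthetic adoption DGP. Adoption
#' responds positively to log expected net revenue (+0.10 per log USD/ha) and
#' negatively to its standard deviation (-0.0007 per USD/ha); the remaining
#' covariate effects are small. The intercept is solved internally so the
#' average adoption rate matches `target_rate`.
#'
#' @param log_netrev,sd_netrev headline coefficients.
#' @param ... further named coefficients overriding the defaults.
#' @return Named numeric vector.
#' @export
adoption_betas <- function(log_netrev = 0.10, sd_netrev = -0.0007, ...) {
  out <- c(
    log_netrev = log_netrev, sd_netrev = sd_netrev,
    area_cultivated = 0.0005, head_age = -0.0001, female_head = -0.006,
    head_education = 0.0096, n_members = 0.001, log_assets = 0.0064,
    log_travel_time = -0.037, mean_annual_rainfall = 0.0001
  )
  dots <- c(...)
  out[names(dots)] <- dots
  out
}

#' Generate the synthetic adoption panel
#'
#' Households are grouped in enumeration-area clusters (clusters nest within
#' regions); each household is observed for `panel_waves` waves. Fertilizer
#' use is drawn from a linear probability process with known coefficients on
#' log expected net revenue and its standard deviation (sampled from the
#' supplied rasters at the household location), plus covariate effects,
#' region and year effects, and a household effect correlated with the
#' household's time-average of log assets — so pooled OLS without the Mundlak
#' time-averages is inconsistent.
#'
#' @param landscape a [generate_landscape()] result.
#' @param netrev_mean,netrev_sd aligned `grid_raster`s of expected net revenue
#'   and its SD (USD/ha).
#' @param betas named coefficients, see [adoption_betas()].
#' @param travel_time optional `grid_raster` of hours to the nearest market;
#'   if `NULL`, a distance-based proxy (km to nearest town / 10 km/h) is used.
#' @param target_rate average adoption rate the intercept is solved for.
#' @param seed optional seed override (defaults to the config's panel stream);
#'   lets simulation studies redraw many panels over one landscape.
#' @return A tibble of household x wave records.
#' @export
generate_adoption_panel <- function(landscape, netrev_mean, netrev_sd,
                                    betas = adoption_betas(),
                                    travel_time = NULL,
                                    target_rate = 0.22, seed = NULL) {
  config <- landscape$config
  gr_check_aligned(landscape$rasters$elevation, netrev_mean, netrev_sd)
  seed <- seed %||% stage_seed(config$seed, "panel")
  n_hh <- config$panel_households
  n_cl <- config$panel_clusters
  waves <- seq_len(config$panel_waves)

  if (is.null(travel_time)) {
    towns <- landscape$towns
    xy <- gr_xy(netrev_mean)
    d <- sqrt(outer(xy$x, towns$x, `-`)^2 + outer(xy$y, towns$y, `-`)^2)
    m <- matrix(NA_real_, gr_dim(netrev_mean)[1], gr_dim(netrev_mean)[2])
    m[cbind(xy$row, xy$col)] <- apply(d, 1, min) / 10
    travel_time <- grid_raster(m, netrev_mean$cell_size, netrev_mean$origin)
  }

  eval_with_seed(seed, {
    # cluster centres on cells where net revenue is defined and positive
    ok <- which(!is.na(gr_values(netrev_mean)) & gr_values(netrev_mean) > 0,
                arr.ind = TRUE)
    if (nrow(ok) < n_cl) abort("too few positive net-revenue cells for clusters")
    ctr <- ok[sample(nrow(ok), n_cl), , drop = FALSE]
    cs <- netrev_mean$cell_size
    d <- gr_dim(netrev_mean)
    cl_of_hh <- sort(rep_len(seq_len(n_cl), n_hh))
    # household cells: small jitter around the cluster centre, snapped to
    # valid cells
    jr <- ctr[cl_of_hh, 1] + sample(-2:2, n_hh, replace = TRUE)
    jc <- ctr[cl_of_hh, 2] + sample(-2:2, n_hh, replace = TRUE)
    jr <- pmin(pmax(jr, 1), d[1]); jc <- pmin(pmax(jc, 1), d[2])
    bad <- is.na(gr_values(netrev_mean)[cbind(jr, jc)]) |
      gr_values(netrev_mean)[cbind(jr, jc)] <= 0
    jr[bad] <- ctr[cl_of_hh, 1][bad]; jc[bad] <- ctr[cl_of_hh, 2][bad]

    idx <- cbind(jr, jc)
    # a cluster's region is taken from its centre so clusters nest in regions
    region_id <- gr_values(landscape$regions)[ctr][cl_of_hh]

    hh <- tibble::tibble(
      hh_id = seq_len(n_hh), ea_cluster_id = cl_of_hh,
      region_id = as.integer(region_id),
      row = as.integer(jr), col = as.integer(jc),
      x = (jc - 0.5) * cs, y = (jr - 0.5) * cs,
      netrev = gr_values(netrev_mean)[idx],
      sd_netrev = gr_values(netrev_sd)[idx],
      travel_hr = gr_values(travel_time)[idx],
      mean_annual_rainfall = gr_values(landscape$rasters$rain_mean)[idx],
      female_head = rbinom(n_hh, 1, 0.25),
      head_education = pmax(0, rnorm(n_hh, 7, 3.5)),
      base_age = round(runif(n_hh, 25, 70)),
      assets_level = rnorm(n_hh, 6, 1)
    )

    panel <- tidyr::expand_grid(hh_id = hh$hh_id, wave = waves) |>
      dplyr::left_join(hh, by = "hh_id") |>
      dplyr::mutate(
        year = 2008 + 2 * (.data$wave - 1),
        # reported age: two years per wave plus reporting noise (ages are
        # misreported in household surveys; this also keeps age from being
        # spanned exactly by the year indicators)
        head_age = .data$base_age + 2 * (.data$wave - 1) +
          sample(-2:2, dplyr::n(), replace = TRUE),
        area_cultivated = pmax(0.05, exp(rnorm(dplyr::n(), 0.2, 0.7))),
        n_members = pmax(1, rpois(dplyr::n(), 5)),
        log_assets = .data$assets_level + rnorm(dplyr::n(), 0, 0.5),
        log_travel_time = log(.data$travel_hr + 0.1),
        log_netrev = log(.data$netrev)
      )

    # household effect correlated with the time-average of log assets:
    # the Mundlak device is required for consistent pooled estimation
    abar <- panel |>
      dplyr::group_by(.data$hh_id) |>
      dplyr::summarise(abar = mean(.data$log_assets), .groups = "drop")
    c_i <- 0.05 * (abar$abar - mean(abar$abar)) + rnorm(n_hh, 0, 0.03)
    region_eff <- rnorm(max(hh$region_id, na.rm = TRUE), 0, 0.015)
    year_eff <- seq(0, by = 0.02, length.out = length(waves))

    b <- betas
    lin <- with(panel,
      b[["log_netrev"]] * log_netrev + b[["sd_netrev"]] * sd_netrev +
      b[["area_cultivated"]] * area_cultivated + b[["head_age"]] * head_age +
      b[["female_head"]] * female_head +
      b[["head_education"]] * head_education +
      b[["n_members"]] * n_members + b[["log_assets"]] * log_assets +
      b[["log_travel_time"]] * log_travel_time +
      b[["mean_annual_rainfall"]] * mean_annual_rainfall) +
      c_i[panel$hh_id] + region_eff[panel$region_id] + year_eff[panel$wave]
    intercept <- target_rate - mean(lin)
    p <- pmin(pmax(intercept + lin, 0.01), 0.99)
    panel$fert_user <- rbinom(nrow(panel), 1, p)

    dplyr::select(
      panel, "hh_id", "wave", "year", "ea_cluster_id", "region_id",
      "row", "col", "x", "y", "fert_user", "netrev", "sd_netrev",
      "log_netrev", "area_cultivated", "head_age", "female_head",
      "head_education", "n_members", "log_assets", "log_travel_time",
      "mean_annual_rainfall"
    )
  })
}
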