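# Out-of-sample validation: does predicted profitability (and its
# uncertainty) explain observed fertilizer adoption? Pooled linear
# probability model with the Mundlak-Chamberlain device, region and year
# indicators, and enumeration-area cluster-robust standard errors.

#' Attach model outputs to the adoption panel
#'
#' Samples the predicted net revenue mean/SD and travel-time rasters at each
#' household's location, takes the natural log of net revenue, and drops
#' (and counts) rows with non-positive or missing net revenue.
#'
#' @param panel adoption panel tibble with `row`, `col` cell indices.
#' @param netrev_mean,netrev_sd,travel_time aligned `grid_raster`s.
#' @return The augmented panel with columns `netrev`, `sd_netrev`,
#'   `log_netrev`, `log_travel_time`; attribute `n_dropped` counts excluded
#'   rows.
#' @export
attach_model_outputs <- function(panel, netrev_mean, netrev_sd, travel_time) {
  gr_check_aligned(netrev_mean, netrev_sd, travel_time)
  d <- gr_dim(netrev_mean)
  if (any(panel$row < 1 | panel$row > d[1] |
          panel$col < 1 | panel$col > d[2])) {
    abort("household coordinates outside raster bounds")
  }
  idx <- cbind(panel$row, panel$col)
  out <- panel |>
    dplyr::mutate(
      netrev = gr_values(netrev_mean)[idx],
      sd_netrev = gr_values(netrev_sd)[idx],
      log_travel_time = log(gr_values(travel_time)[idx] + 0.1)
    )
  keep <- !is.na(out$netrev) & out$netrev > 0 & !is.na(out$sd_netrev)
  out <- out |>
    dplyr::filter(keep) |>
    dplyr::mutate(log_netrev = log(.data$netrev))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Cluster-robust (CR1) covariance matrix
#'
#' Sandwich estimator with scores summed within clusters and the CR1
#' finite-sample factor `G/(G-1) * (n-1)/(n-k)`. With every observation its
#' own cluster this reduces exactly to the HC1 heteroskedasticity-robust
#' estimator.
#'
#' @param X design matrix (n x k).
#' @param residuals OLS residuals, length n.
#' @param clusters cluster id vector, length n (>= 2 distinct values).
#' @return k x k covariance matrix.
#' @export
cluster_robust_vcov <- function(X, residuals, clusters) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  cl <- as.factor(clusters)
  G <- nlevels(cl)
  if (G < 2) abort("need at least 2 clusters")
  bread <- tryCatch(solve(crossprod(X)),
                    error = function(e) abort("singular design (bread) matrix"))
  scores <- X * residuals
  sg <- rowsum(scores, cl)
  meat <- crossprod(sg)
  adj <- G / (G - 1) * (n - 1) / (n - k)
  adj * bread %*% meat %*% bread
}

#' Mundlak linear probability model of fertilizer adoption
#'
#' Pooled OLS of the binary adoption indicator on the regressors, the
#' household time-averages of the time-varying regressors (the
#' Mundlak-Chamberlain device: the correlated time-invariant heterogeneity
#' is modelled as a function of those averages; the averages are estimated
#' but not interpreted), and full region and year indicator sets. Standard
#' errors are clustered at the enumeration area (CR1).
#'
#' @param panel adoption panel tibble; must contain `fert_user`, the
#'   regressors, `hh_id`, `ea_cluster_id`, `region_id`, `year`.
#' @param regressors character vector of regressor columns.
#' @param mundlak subset of `regressors` whose household time-averages enter
#'   the model (the time-varying ones).
#' @param cluster column name of the cluster id.
#' @return A list of class `mundlak_lpm` with a coefficient table (tibble),
#'   `vcov`, `n_obs`, `r_squared`, `n_clusters`, and the underlying `lm`
#'   fit.
#' @export
mundlak_lpm <- function(panel,
                        regressors = c("log_netrev", "sd_netrev",
                                       "area_cultivated", "head_age",
                                       "female_head", "head_education",
                                       "n_members", "log_assets",
                                       "log_travel_time",
                                       "mean_annual_rainfall"),
                        mundlak = c("area_cultivated", "head_age",
                                    "n_members", "log_assets"),
                        cluster = "ea_cluster_id") {
  wave_col <- if ("wave" %in% names(panel)) panel$wave else panel$year
  if (length(unique(wave_col)) < 2) abort("need at least 2 waves")
  if (!all(mundlak %in% regressors)) {
    abort("`mundlak` must be a subset of `regressors`")
  }
  df <- panel
  for (v in mundlak) {
    bar <- stats::ave(df[[v]], df$hh_id)
    if (stats::var(df[[v]] - bar) == 0) {
      abort(paste0("regressor `", v, "` does not vary within households; ",
                   "its Mundlak average is collinear with it"))
    }
    df[[paste0("mbar_", v)]] <- bar
  }
  df$.region <- factor(df$region_id)
  df$.year <- factor(df$year)
  rhs <- c(regressors, paste0("mbar_", mundlak))
  if (nlevels(df$.region) > 1) rhs <- c(rhs, ".region")
  if (nlevels(df$.year) > 1) rhs <- c(rhs, ".year")
  use <- complete.cases(df[, c("fert_user", regressors, cluster)])
  df <- df[use, ]
  f <- stats::as.formula(paste("fert_user ~", paste(rhs, collapse = " + ")))
  fit <- lm(f, data = df)
  X <- model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    aliased <- names(which(is.na(coef(fit))))
    abort(paste("perfect collinearity among:",
                paste(aliased, collapse = ", ")))
  }
  if (length(unique(df[[cluster]])) < 30) {
    warn("fewer than 30 clusters; cluster-robust inference may be unreliable")
  }
  V <- cluster_robust_vcov(X, resid(fit), df[[cluster]])
  se <- sqrt(diag(V))
  est <- coef(fit)
  G <- length(unique(df[[cluster]]))
  tstat <- est / se
  pval <- 2 * stats::pt(abs(tstat), df = G - 1, lower.tail = FALSE)
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(tstat), p.value = unname(pval),
    mundlak_average = grepl("^mbar_", names(est))
  )
  structure(
    list(coefficients = coefs, vcov = V, fit = fit,
         n_obs = nrow(df), n_clusters = G,
         r_squared = summary(fit)$r.squared,
         regressors = regressors, mundlak = mundlak),
    class = "mundlak_lpm"
  )
}

#' @export
print.mundlak_lpm <- function(x, ...) {
  cat(sprintf("Mundlak LPM: %d obs, %d clusters, R-squared %.3f\n",
              x$n_obs, x$n_clusters, x$r_squared))
  main <- x$coefficients[!x$coefficients$mundlak_average &
                           !grepl("^\\.|\\(Intercept\\)",
                                  x$coefficients$term), ]
  print(as.data.frame(main[, 1:5]), digits = 3, row.names = FALSE)
  cat("Region FE: yes; Year FE: yes; Mundlak-Chamberlain device: yes\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mundlak_lpm <- function(x, ...) x$coefficients

#' @export
glance.mundlak_lpm <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_obs,
                 n.clusters = x$n_clusters)
}

#' @export
tidy.price_model <- function(x, ...) {
  tibble::tibble(term = x$predictor_names)
}

#' @export
glance.price_model <- function(x, ...) {
  tibble::tibble(oob.r.squared = x$oob_r2, rmse = x$rmse, nobs = x$n_obs)
}

#' @export
tidy.yield_model <- function(x, ...) {
  tibble::tibble(term = names(x$importance),
                 importance = unname(x$importance))
}

#' @export
glance.yield_model <- function(x, ...) {
  tibble::tibble(oob.r.squared = x$oob_r2, nobs = x$n_obs,
                 num.trees = x$num_trees)
}
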