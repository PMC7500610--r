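#' Lightweight gridded raster layers
#'
#' All spatial layers in the package (elevation, soils, rainfall, travel time,
#' prices, yields, net revenue) are `grid_raster` objects: a numeric matrix of
#' cell values plus a square cell size in kilometres and an origin for the
#' lower-left corner. `NA` encodes nodata. Row 1 is the southernmost row, so
#' the y coordinate of a cell centre is `origin[2] + (row - 0.5) * cell_size`.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param cell_size positive cell edge length in km.
#' @param origin numeric length-2 vector, (x, y) of the lower-left corner in km.
#' @return A `grid_raster` object.
#' @examples
#' r <- grid_raster(matrix(1:12, 3, 4))
#' gr_dim(r)
#' @export
grid_raster <- function(values, cell_size = 1, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("`cell_size` must be a single positive number.")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "grid_raster"
  )
}

#' @rdname grid_raster
#' @param x object to test or coerce.
#' @export
is_grid_raster <- function(x) inherits(x, "grid_raster")

#' @rdname grid_raster
#' @export
gr_dim <- function(x) dim(x$values)

#' @rdname grid_raster
#' @export
gr_values <- function(x) x$values

#' @export
print.grid_raster <- function(x, ...) {
  d <- gr_dim(x)
  v <- x$values
  cat(sprintf("<grid_raster %d x %d, cell %g km, %d nodata>\n",
              d[1], d[2], x$cell_size, sum(is.na(v))))
  if (any(!is.na(v))) {
    cat(sprintf("  range: [%g, %g]\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' Test or assert that rasters share shape and geotransform
#'
#' @param ... `grid_raster` objects.
#' @return `gr_aligned()` returns `TRUE`/`FALSE`; `gr_check_aligned()` returns
#'   invisibly or raises an error.
#' @export
gr_aligned <- function(...) {
  rs <- list(...)
  ref <- rs[[1]]
  all(vapply(rs, function(r) {
    identical(gr_dim(r), gr_dim(ref)) &&
      isTRUE(all.equal(r$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(r$origin, ref$origin))
  }, logical(1)))
}

#' @rdname gr_aligned
#' @export
gr_check_aligned <- function(...) {
  if (!gr_aligned(...)) abort("rasters are not aligned (shape/cell size/origin differ)")
  invisible(TRUE)
}

#' Elementwise combination of aligned rasters
#'
#' Applies `f` elementwise to the values of aligned rasters (scalars are
#' recycled); the result inherits the first raster's geometry. `NA` propagates
#' through `f` in the usual vectorised way.
#'
#' @param f vectorised function.
#' @param ... `grid_raster` objects and/or scalars.
#' @return A `grid_raster`.
#' @export
gr_map <- function(f, ...) {
  args <- list(...)
  rs <- args[vapply(args, is_grid_raster, logical(1))]
  if (length(rs) == 0) abort("at least one argument must be a grid_raster")
  do.call(gr_check_aligned, rs)
  ref <- rs[[1]]
  vals <- lapply(args, function(a) if (is_grid_raster(a)) a$values else a)
  out <- do.call(f, vals)
  grid_raster(matrix(out, nrow = nrow(ref$values), ncol = ncol(ref$values)),
              ref$cell_size, ref$origin)
}

#' @rdname gr_map
#' @param template `grid_raster` supplying the geometry.
#' @param value scalar fill value.
#' @export
gr_const <- function(template, value) {
  grid_raster(matrix(value, nrow(template$values), ncol(template$values)),
              template$cell_size, template$origin)
}

#' Cell centres and point lookup
#'
#' `gr_xy()` returns every cell centre; `gr_cell_at()` maps x/y coordinates to
#' (row, col) indices of the containing cell; `gr_extract()` reads raster
#' values at point coordinates (nearest cell).
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates in km.
#' @return `gr_xy()` a tibble with row, col, x, y; `gr_cell_at()` a tibble with
#'   row, col; `gr_extract()` a numeric vector.
#' @export
gr_xy <- function(r) {
  d <- gr_dim(r)
  tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2])) |>
    dplyr::mutate(
      x = r$origin[1] + (.data$col - 0.5) * r$cell_size,
      y = r$origin[2] + (.data$row - 0.5) * r$cell_size
    )
}

#' @rdname gr_xy
#' @export
gr_cell_at <- function(r, x, y) {
  d <- gr_dim(r)
  col <- pmin(pmax(ceiling((x - r$origin[1]) / r$cell_size), 1L), d[2])
  row <- pmin(pmax(ceiling((y - r$origin[2]) / r$cell_size), 1L), d[1])
  if (any(x < r$origin[1] | x > r$origin[1] + d[2] * r$cell_size |
          y < r$origin[2] | y > r$origin[2] + d[1] * r$cell_size)) {
    abort("coordinates fall outside the raster extent")
  }
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' @rdname gr_xy
#' @export
gr_extract <- function(r, x, y) {
  idx <- gr_cell_at(r, x, y)
  r$values[cbind(idx$row, idx$col)]
}

#' Masked, optionally weighted, mean of a raster
#'
#' The mean is taken over cells that are non-missing in the raster, in the
#' mask (if given) and in the weights (if given). Per-hectare quantities are
#' conventionally weighted by maize area.
#'
#' @param r a `grid_raster`.
#' @param weights optional `grid_raster` of non-negative weights.
#' @param mask optional `grid_raster`; cells with `NA` or 0 are excluded.
#' @return scalar mean (NA if no valid cells).
#' @export
gr_mean <- function(r, weights = NULL, mask = NULL) {
  v <- r$values
  w <- if (is.null(weights)) matrix(1, nrow(v), ncol(v)) else {
    gr_check_aligned(r, weights)
    weights$values
  }
  if (!is.null(mask)) {
    gr_check_aligned(r, mask)
    keep <- !is.na(mask$values) & mask$values != 0
    w[!keep] <- NA
  }
  ok <- !is.na(v) & !is.na(w) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w[ok]) / sum(w[ok])
}

#' Share of masked cells exceeding a threshold
#'
#' Computes 100 x (valid masked cells strictly above `threshold`) / (valid
#' masked cells). Used for territorial shares such as "percent of the maize
#' area with net revenue above 100 USD/ha".
#'
#' @param r a `grid_raster`.
#' @param threshold finite numeric threshold.
#' @param mask optional `grid_raster`; cells with `NA` or 0 are excluded.
#' @return percentage in \[0, 100\].
#' @export
exceedance_share <- function(r, threshold, mask = NULL) {
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  v <- r$values
  keep <- !is.na(v)
  if (!is.null(mask)) {
    gr_check_aligned(r, mask)
    keep <- keep & !is.na(mask$values) & mask$values != 0
  }
  if (!any(keep)) abort("no valid cells under the mask")
  100 * sum(v[keep] > threshold) / sum(keep)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble grid_raster
#' @export
as_tibble.grid_raster <- function(x, ...) {
  df <- gr_xy(x)
  df$value <- as.vector(t(x$values))
  df
}

#' Plot a raster layer
#'
#' @param object a `grid_raster`.
#' @param ... unused.
#' @param name legend title.
#' @return A ggplot.
#' @export
autoplot.grid_raster <- function(object, ..., name = "value") {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values, north row
#' first. Values are written at full double precision.
#'
#' @param r a `grid_raster`.
#' @param path file path (conventionally `.asc`).
#' @param nodata value standing in for `NA` on disk.
#' @return `write_ascii_grid()` the path, invisibly; `read_ascii_grid()` a
#'   `grid_raster`.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  d <- gr_dim(r)
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- vapply(rev(seq_len(d[1])), function(i) {
    paste(formatC(v[i, ], format = "g", digits = 17), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, character(1), 1))
  val <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(val) <- key
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]
  m[m == val[["nodata_value"]]] <- NA
  grid_raster(m, cell_size = val[["cellsize"]],
              origin = c(val[["xllcorner"]], val[["yllcorner"]]))
}
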