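# Friction surfaces and least-accumulated-time market access.

#' Travel speed lookup table
#'
#' Speeds (km/h) by road class and by land cover class for off-road cells.
#' Water is impassable off-road (`NA` speed). All road speeds must be at
#' least as fast as every off-road speed.
#'
#' @param primary,secondary,tertiary road-class speeds, km/h.
#' @param cropland,grassland,forest off-road speeds by land cover, km/h.
#' @param water off-road water speed; `NA` = impassable.
#' @return A list of class `speed_table` with `roads` and `landcover`
#'   lookups (land cover codes 1 = cropland, 2 = grassland, 3 = forest,
#'   4 = water).
#' @export
speed_table <- function(primary = 80, secondary = 50, tertiary = 30,
                        cropland = 10, grassland = 10, forest = 5,
                        water = NA) {
  roads <- c(primary = primary, secondary = secondary, tertiary = tertiary)
  lc <- c(cropland, grassland, forest, water)
  if (any(roads <= 0) || any(lc <= 0, na.rm = TRUE)) {
    abort("all speeds must be positive")
  }
  if (min(roads) < max(lc, na.rm = TRUE)) {
    abort("road speeds must be >= off-road speeds")
  }
  structure(list(roads = roads, landcover = lc), class = "speed_table")
}

#' Rasterize travel speeds from roads and land cover
#'
#' Cells intersected by a road take that road class's speed, with the
#' highest (fastest) class winning where classes overlap; all other cells
#' take the speed of their land cover class. Water cells without a road are
#' impassable (`NA`).
#'
#' @param roads tibble of segments (`x0`, `y0`, `x1`, `y1`, `class`).
#' @param landcover `grid_raster` of land cover codes (1-4).
#' @param speeds a [speed_table()].
#' @return `grid_raster` of speeds in km/h.
#' @export
rasterize_speeds <- function(roads, landcover, speeds = speed_table()) {
  lc <- gr_values(landcover)
  codes <- sort(unique(as.vector(lc[!is.na(lc)])))
  if (any(!codes %in% seq_along(speeds$landcover))) {
    abort("land cover class missing from the speed table")
  }
  sp <- matrix(speeds$landcover[lc], nrow(lc), ncol(lc))
  # draw slower classes first so the highest class wins on overlap
  for (cl in c("tertiary", "secondary", "primary")) {
    segs <- roads[roads$class == cl, , drop = FALSE]
    if (nrow(segs) == 0) next
    for (i in seq_len(nrow(segs))) {
      cells <- segment_cells(landcover, segs$x0[i], segs$y0[i],
                             segs$x1[i], segs$y1[i])
      sp[cbind(cells$row, cells$col)] <- speeds$roads[[cl]]
    }
  }
  grid_raster(sp, landcover$cell_size, landcover$origin)
}

# edge list of the raster travel graph: per-step time in hours =
# step length / harmonic mean of the two cells' speeds
raster_graph_edges <- function(speed, connectivity = 8) {
  d <- gr_dim(speed)
  nr <- d[1]; nc <- d[2]
  v <- gr_values(speed)
  id <- function(row, col) (col - 1L) * nr + row
  steps <- list(c(1L, 0L, 1), c(0L, 1L, 1))
  if (connectivity == 8) {
    steps <- c(steps, list(c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2))))
  } else if (connectivity != 4) {
    abort("`connectivity` must be 4 or 8")
  }
  out <- lapply(steps, function(s) {
    dr <- s[1]; dc <- s[2]; len <- s[3] * speed$cell_size
    rows <- seq_len(nr - abs(dr))
    if (dr < 0) rows <- rows - dr
    cols <- seq_len(nc - abs(dc))
    if (dc < 0) cols <- cols - dc
    g <- expand.grid(row = rows, col = cols)
    from <- id(g$row, g$col)
    to <- id(g$row + dr, g$col + dc)
    s1 <- v[from]; s2 <- v[to]
    w <- len * (1 / s1 + 1 / s2) / 2
    ok <- !is.na(w) & is.finite(w)
    tibble::tibble(from = from[ok], to = to[ok], weight = w[ok])
  })
  dplyr::bind_rows(out)
}

#' Least accumulated travel time over a friction surface
#'
#' Exact single-source shortest path over the raster adjacency graph
#' (8-connected by default, diagonal steps sqrt(2) long). The cost of a step
#' between adjacent cells is the step length divided by the harmonic mean of
#' the two cells' speeds, which makes step costs symmetric. Cells unreachable
#' from every source (for example across water) are `NA`.
#'
#' @param speed `grid_raster` of speeds in km/h (`NA` = impassable).
#' @param sources tibble/data frame with `row` and `col` of source cells.
#' @param connectivity 4 or 8 (default) neighbourhood.
#' @return `grid_raster` of hours; exactly 0 at the source cells.
#' @export
travel_time <- function(speed, sources, connectivity = 8) {
  d <- gr_dim(speed)
  if (nrow(sources) < 1) abort("need at least one source cell")
  if (any(sources$row < 1 | sources$row > d[1] |
          sources$col < 1 | sources$col > d[2])) {
    abort("source outside grid")
  }
  v <- gr_values(speed)
  if (all(is.na(v))) abort("speed raster is all nodata")
  edges <- raster_graph_edges(speed, connectivity)
  n <- prod(d)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  src <- (sources$col - 1L) * d[1] + sources$row
  dm <- igraph::distances(g, v = src, weights = edges$weight)
  t_hr <- apply(dm, 2, min)
  t_hr[!is.finite(t_hr)] <- NA
  t_hr[is.na(v)] <- NA
  grid_raster(matrix(t_hr, d[1], d[2]), speed$cell_size, speed$origin)
}

#' Travel time to every qualifying market town
#'
#' One travel-time layer per town with population above `min_population`,
#' plus the elementwise minimum (time to the nearest qualifying market).
#'
#' @param speed `grid_raster` of speeds, km/h.
#' @param towns tibble with `town_id`, `row`, `col`, `population`.
#' @param min_population towns at or below this are not markets.
#' @param connectivity passed to [travel_time()].
#' @return A list of class `travel_time_stack`: `layers` (named list of
#'   `grid_raster`, one per market town), `nearest` (min raster), `towns`
#'   (the qualifying towns).
#' @export
travel_time_per_market <- function(speed, towns, min_population = 50000,
                                   connectivity = 8) {
  mk <- towns[towns$population > min_population, , drop = FALSE]
  if (nrow(mk) == 0) abort("no towns above the population threshold")
  layers <- purrr::map(seq_len(nrow(mk)), function(i) {
    travel_time(speed, mk[i, c("row", "col")], connectivity)
  })
  names(layers) <- as.character(mk$town_id)
  nearest <- purrr::reduce(layers, function(a, b) gr_map(pmin, a, b))
  structure(list(layers = layers, nearest = nearest, towns = mk),
            class = "travel_time_stack")
}

#' @export
print.travel_time_stack <- function(x, ...) {
  cat(sprintf("<travel_time_stack: %d market towns>\n", length(x$layers)))
  invisible(x)
}
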