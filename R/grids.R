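# Grid containers: burn scene, landscape stack, weather cube.
#
# Conventions (used everywhere):
#  - matrices are row-major rasters with the top-left origin: row 1 is the
#    northern edge, column 1 the western edge;
#  - `origin = c(x0, y0)` is the outer corner of pixel (1, 1): x0 the west
#    edge, y0 the north edge, in meters of a local equal-area frame;
#  - pixel (r, c) at resolution `res` has center
#    x = x0 + (c - 0.5) res,  y = y0 - (r - 0.5) res;
#  - point -> cell uses ceiling(offset / res), so a point exactly on a cell
#    boundary deterministically belongs to the lower cell index.

#' Create a burn scene
#'
#' A burn scene is the spatial substrate of the analysis: a day-of-burn
#' raster (integer day-of-year per pixel, 0 = unburned) plus a fire-event
#' identifier raster on the same grid.
#'
#' @param day_of_burn Integer matrix; 0 for unburned pixels, otherwise the
#'   day-of-year the pixel burned.
#' @param fire_id Optional integer matrix of fire-event IDs (0 = none). If
#'   `NULL`, call [label_fire_events()] to derive one.
#' @param pixel_size Pixel size in meters (default 300).
#' @param origin Numeric length-2, `c(x0, y0)`: the north-west corner of the
#'   raster in projected (equal-area) coordinates. Defaults to
#'   `c(0, nrow * pixel_size)` so all pixel centers have positive y.
#' @param crs Free-form identifier of the projected coordinate frame; only
#'   compared for equality across inputs.
#' @param year Calendar year of the scene (carried through to records).
#' @return An object of class `burn_scene`.
#' @export
burn_scene <- function(day_of_burn, fire_id = NULL, pixel_size = 300,
                       origin = NULL, crs = "local-equal-area", year = NA_integer_) {
  stopifnot(is.matrix(day_of_burn))
  mode(day_of_burn) <- "integer"
  if (is.null(origin)) origin <- c(0, nrow(day_of_burn) * pixel_size)
  if (!is.null(fire_id)) {
    stopifnot(is.matrix(fire_id), all(dim(fire_id) == dim(day_of_burn)))
    mode(fire_id) <- "integer"
    if (any((fire_id > 0) != (day_of_burn > 0))) {
      stop("fire_id > 0 must hold exactly where day_of_burn > 0")
    }
  }
  structure(
    list(day_of_burn = day_of_burn, fire_id = fire_id,
         pixel_size = pixel_size, origin = as.numeric(origin),
         crs = crs, year = year),
    class = "burn_scene"
  )
}

#' @export
print.burn_scene <- function(x, ...) {
  nb <- sum(x$day_of_burn > 0)
  nf <- if (is.null(x$fire_id)) NA_integer_ else length(setdiff(unique(as.vector(x$fire_id)), 0L))
  cat(sprintf("<burn_scene> %d x %d pixels @ %g m, %d burned, %s fires\n",
              nrow(x$day_of_burn), ncol(x$day_of_burn), x$pixel_size, nb,
              ifelse(is.na(nf), "unlabeled", nf)))
  invisible(x)
}

#' Create a landscape layer
#'
#' @param values Matrix of layer values at the layer's native resolution.
#' @param res Cell size in meters.
#' @param kind One of `"continuous"`, `"categorical"`, `"binary"`.
#' @return A `landscape_layer` object.
#' @export
landscape_layer <- function(values, res, kind = c("continuous", "categorical", "binary")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, res = res, kind = kind), class = "landscape_layer")
}

#' Create a landscape stack
#'
#' Bundles the bottom-up driver layers at their native resolutions: percent
#' tree cover, aboveground biomass (Mg/ha), categorical land cover, burn
#' history (years since last fire), elevation (m), and binary road and
#' surface-water presence. Layers share one origin/CRS but each keeps its
#' own cell size; all lookups are nearest-cell at native resolution.
#'
#' @param layers Named list of [landscape_layer()] objects. Recognized names:
#'   `tree_cover`, `agb`, `land_cover`, `burn_history`, `elevation`, `road`,
#'   `water`. Extra layers are carried but not tested.
#' @param origin,crs As in [burn_scene()].
#' @return A `landscape_stack` object.
#' @export
landscape_stack <- function(layers, origin, crs = "local-equal-area") {
  stopifnot(is.list(layers), !is.null(names(layers)))
  ok <- vapply(layers, inherits, logical(1), "landscape_layer")
  if (!all(ok)) stop("all elements of `layers` must be landscape_layer objects")
  structure(list(layers = layers, origin = as.numeric(origin), crs = crs),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat("<landscape_stack>\n")
  for (nm in names(x$layers)) {
    l <- x$layers[[nm]]
    cat(sprintf("  %-12s %4d x %4d @ %4g m (%s)\n", nm,
                nrow(l$values), ncol(l$values), l$res, l$kind))
  }
  invisible(x)
}

#' Create an hourly weather cube
#'
#' Gridded hourly weather on a coarse cell grid (reanalysis-style): 2 m
#' temperature and dewpoint (deg C), 10 m wind components u (east) and
#' v (north) in m/s, and 0-7 cm volumetric soil moisture (m3/m3). Arrays
#' are `[hour, row, col]`; the time axis is hourly and strictly increasing,
#' hour 1 being 00-01 UTC of `start_doy`.
#'
#' @param t2m,d2m,u10,v10,sm Numeric arrays `[n_hours, n_rows, n_cols]`.
#' @param start_doy Day-of-year of the first hour.
#' @param cell_size Cell size in meters of the coarse weather grid.
#' @param origin,crs As in [burn_scene()].
#' @return A `weather_cube` object.
#' @export
weather_cube <- function(t2m, d2m, u10, v10, sm, start_doy, cell_size,
                         origin, crs = "local-equal-area") {
  dims <- dim(t2m)
  stopifnot(length(dims) == 3)
  for (a in list(d2m, u10, v10, sm)) stopifnot(all(dim(a) == dims))
  if (any(sm < 0 | sm > 1, na.rm = TRUE)) stop("soil moisture must lie in [0, 1]")
  structure(
    list(t2m = t2m, d2m = d2m, u10 = u10, v10 = v10, sm = sm,
         start_doy = as.integer(start_doy), cell_size = cell_size,
         origin = as.numeric(origin), crs = crs,
         n_hours = dims[1], n_rows = dims[2], n_cols = dims[3]),
    class = "weather_cube"
  )
}

#' @export
print.weather_cube <- function(x, ...) {
  cat(sprintf("<weather_cube> %d h from doy %d, %d x %d cells @ %g m\n",
              x$n_hours, x$start_doy, x$n_rows, x$n_cols, x$cell_size))
  invisible(x)
}

# ---- coordinate helpers (internal) ----------------------------------------

# point offset -> 1-based cell index; exact boundaries go to the lower index
fs_cell_index <- function(offset, res, n) {
  pmin(pmax(ceiling(offset / res), 1L), n)
}

fs_pixel_center <- function(row, col, res, origin) {
  list(x = origin[1] + (col - 0.5) * res,
       y = origin[2] - (row - 0.5) * res)
}

fs_point_to_rc <- function(x, y, res, origin, nrow, ncol) {
  list(row = fs_cell_index(origin[2] - y, res, nrow),
       col = fs_cell_index(x - origin[1], res, ncol))
}

# vectorized nearest-cell lookup on a landscape layer
fs_layer_at <- function(layer, x, y, origin) {
  v <- layer$values
  rc <- fs_point_to_rc(x, y, layer$res, origin, nrow(v), ncol(v))
  v[cbind(rc$row, rc$col)]
}

fs_scene_at <- function(scene, x, y, what = c("day_of_burn", "fire_id")) {
  what <- match.arg(what)
  m <- scene[[what]]
  rc <- fs_point_to_rc(x, y, scene$pixel_size, scene$origin, nrow(m), ncol(m))
  m[cbind(rc$row, rc$col)]
}

fs_check_crs <- function(scene, cube = NULL, stack = NULL) {
  bad <- character(0)
  if (!is.null(cube) && !identical(cube$crs, scene$crs)) bad <- c(bad, "weather_cube")
  if (!is.null(stack) && !identical(stack$crs, scene$crs)) bad <- c(bad, "landscape_stack")
  if (length(bad)) {
    stop("CRS mismatch between burn_scene ('", scene$crs, "') and: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
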