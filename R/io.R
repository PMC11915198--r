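# Plain-text I/O: ESRI ASCII grids for rasters, CSV for stops/records and
# weather cubes, GeoJSON for stop points, YAML for scenario configs. All
# formats round-trip exactly enough for the pipeline (text-precision
# doubles) and need no binary dependencies.

#' Write / read a raster as an ESRI ASCII grid
#'
#' The standard `.asc` text raster: a six-line header (NCOLS, NROWS,
#' XLLCORNER, YLLCORNER, CELLSIZE, NODATA_value) followed by rows from the
#' north edge down.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param file Path.
#' @param res Cell size, meters.
#' @param origin `c(x0, y0)`: north-west corner (note the header stores the
#'   lower-left corner).
#' @param nodata NODATA sentinel (default -9999).
#' @return `write_ascii_grid`: the path, invisibly. `read_ascii_grid`: a
#'   list with `values`, `res`, `origin`.
#' @export
write_ascii_grid <- function(values, file, res, origin, nodata = -9999) {
  stopifnot(is.matrix(values))
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(
    paste("NCOLS", ncol(v)), paste("NROWS", nrow(v)),
    paste("XLLCORNER", format(origin[1], scientific = FALSE)),
    paste("YLLCORNER", format(origin[2] - nrow(v) * res, scientific = FALSE)),
    paste("CELLSIZE", format(res, scientific = FALSE)),
    paste("NODATA_value", nodata))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(file) {
  hdr <- readLines(file, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  h <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                       toupper(vapply(kv, `[`, character(1), 1)))
  v <- as.matrix(utils::read.table(file, skip = 6))
  dimnames(v) <- NULL
  v[v == h[["NODATA_VALUE"]]] <- NA
  res <- h[["CELLSIZE"]]
  list(values = v, res = res,
       origin = c(h[["XLLCORNER"]], h[["YLLCORNER"]] + h[["NROWS"]] * res))
}

#' Write / read fire stops as CSV
#'
#' @param stops Stop tibble ([extract_fire_stops()]).
#' @param file Path.
#' @return The path (write) or the tibble (read).
#' @export
write_stops <- function(stops, file) {
  readr::write_csv(stops, file)
  invisible(file)
}

#' @rdname write_stops
#' @export
read_stops <- function(file) {
  readr::read_csv(file, show_col_types = FALSE,
                  col_types = readr::cols(
                    stop_id = "i", fire_id = "i", row = "i", col = "i",
                    last_burn_date = "i", nb_row = "i", nb_col = "i",
                    year = "i", direction_defined = "l", .default = "d"))
}

#' Write attribution records as CSV
#'
#' @param records An `fs_records` tibble.
#' @param file Path.
#' @export
write_records <- function(records, file) {
  readr::write_csv(records, file)
  invisible(file)
}

#' @rdname write_records
#' @export
read_records <- function(file) {
  out <- readr::read_csv(file, show_col_types = FALSE)
  class(out) <- unique(c("fs_records", class(out)))
  out
}

#' Write fire stops as GeoJSON points
#'
#' A FeatureCollection of point features with `fire_id`, `last_burn_date`
#' and the outward direction as properties. Coordinates stay in the
#' projected frame of the scene.
#'
#' @param stops Stop tibble.
#' @param file Path.
#' @export
write_stops_geojson <- function(stops, file) {
  feats <- purrr::map(seq_len(nrow(stops)), function(i) {
    s <- stops[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(s$x, s$y)),
         properties = list(stop_id = s$stop_id, fire_id = s$fire_id,
                           last_burn_date = s$last_burn_date,
                           dir_x = s$dir_x, dir_y = s$dir_y))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Write / read a weather cube as long-format CSV
#'
#' Columns `hour` (1-based from the cube start), `row`, `col`, then one
#' column per variable. Intended for the small synthetic cubes; real
#' reanalysis archives are not desk-scale.
#'
#' @param cube A [weather_cube()].
#' @param file Path.
#' @export
write_weather_cube <- function(cube, file) {
  g <- expand.grid(hour = seq_len(cube$n_hours), row = seq_len(cube$n_rows),
                   col = seq_len(cube$n_cols))
  df <- tibble::tibble(
    hour = g$hour, row = g$row, col = g$col,
    t2m = as.vector(cube$t2m), d2m = as.vector(cube$d2m),
    u10 = as.vector(cube$u10), v10 = as.vector(cube$v10),
    sm = as.vector(cube$sm))
  attr_hdr <- sprintf("# start_doy=%d cell_size=%g x0=%g y0=%g crs=%s",
                      cube$start_doy, cube$cell_size, cube$origin[1],
                      cube$origin[2], cube$crs)
  writeLines(c(attr_hdr,
               strsplit(readr::format_csv(df), "\n", fixed = TRUE)[[1]]),
             file)
  invisible(file)
}

#' @rdname write_weather_cube
#' @export
read_weather_cube <- function(file) {
  hdr <- readLines(file, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z0-9_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  df <- readr::read_csv(file, skip = 1, show_col_types = FALSE)
  nh <- max(df$hour); nr <- max(df$row); nc <- max(df$col)
  arr <- function(v) array(v, c(nh, nr, nc))
  df <- df[order(df$col, df$row, df$hour), ]
  weather_cube(arr(df$t2m), arr(df$d2m), arr(df$u10), arr(df$v10),
               arr(df$sm), start_doy = as.integer(meta[["start_doy"]]),
               cell_size = as.numeric(meta[["cell_size"]]),
               origin = as.numeric(c(meta[["x0"]], meta[["y0"]])),
               crs = meta[["crs"]])
}

#' Write / read a scenario configuration as YAML
#'
#' @param config A [scenario_config()].
#' @param file Path.
#' @export
write_scenario_config <- function(config, file) {
  x <- unclass(config)
  x$planted_causes <- purrr::map(x$planted_causes, unclass)
  x$fires <- if (is.null(x$fires)) NULL else purrr::map(x$fires, unclass)
  x$layer_res <- as.list(x$layer_res)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(file) {
  x <- yaml::read_yaml(file)
  causes <- purrr::map(x$planted_causes %||% list(), function(cs) {
    do.call(cause_spec, cs[c("kind", "size", "side", "distance_px",
                             "width_m", "offset_m", "values", "fire")])
  })
  fires <- if (is.null(x$fires)) NULL else {
    purrr::map(x$fires, function(f) {
      fire_spec(unlist(f$ignition), f$start_doy, f$n_days)
    })
  }
  scenario_config(
    grid_shape = unlist(x$grid_shape), pixel_size = x$pixel_size,
    fires = fires, n_fires = x$n_fires,
    fire_size_range = unlist(x$fire_size_range),
    burn_start_doy = x$burn_start_doy, planted_causes = causes,
    noise = x$noise, baseline = x$baseline, sm_phi = x$sm_phi,
    weather_cell_px = x$weather_cell_px,
    layer_res = unlist(x$layer_res), year = x$year, seed = x$seed)
}

#' Write a grid summary as CSV plus one ASCII grid per driver share
#'
#' @param summary An `fs_grid_summary` from [grid_aggregate()].
#' @param csv_file Path of the CSV table.
#' @param asc_dir Optional directory; if given, each `share_*` column is
#'   also rasterized to an `.asc` grid there.
#' @export
write_grid_summary <- function(summary, csv_file, asc_dir = NULL) {
  readr::write_csv(summary, csv_file)
  if (!is.null(asc_dir)) {
    dir.create(asc_dir, showWarnings = FALSE, recursive = TRUE)
    cs <- attr(summary, "cell_size")
    nx <- max(summary$cell_x); ny <- max(summary$cell_y)
    for (cn in grep("^share_", names(summary), value = TRUE)) {
      m <- matrix(NA_real_, ny, nx)
      m[cbind(ny - summary$cell_y + 1, summary$cell_x)] <- summary[[cn]]
      write_ascii_grid(m, file.path(asc_dir, paste0(cn, ".asc")),
                       res = cs, origin = c(0, ny * cs))
    }
  }
  invisible(csv_file)
}
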