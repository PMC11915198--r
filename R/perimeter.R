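# Perimeter module: from a day-of-burn raster to dated fire stops with
# outward directions. All adjacency is first-order Queen (8-neighbor) and
# grid-native; no vectorized perimeter tracing.

# Queen neighbor offsets
fs_queen <- matrix(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L,
                     -1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L), ncol = 2)

#' Label fire events from a day-of-burn raster
#'
#' Spatiotemporal connected components: two burned pixels belong to the same
#' fire event iff they are Queen-adjacent and their burn dates differ by at
#' most `max_gap_days`. IDs are dense from 1 in raster scan order.
#'
#' @param day_of_burn Integer matrix (0 = unburned, else day-of-year).
#' @param max_gap_days Maximum date gap (days) for two adjacent pixels to
#'   join one event (default 14).
#' @return Integer matrix of fire IDs (0 where unburned).
#' @export
label_fire_events <- function(day_of_burn, max_gap_days = 14) {
  stopifnot(is.matrix(day_of_burn))
  nr <- nrow(day_of_burn); nc <- ncol(day_of_burn)
  burned <- which(day_of_burn > 0)
  id <- matrix(0L, nr, nc)
  if (length(burned) == 0) return(id)

  # union-find over burned cell linear indices
  parent <- seq_len(nr * nc)
  mode(parent) <- "integer"
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # union with the 4 "previous" Queen neighbors only (each pair seen once)
  prev <- matrix(c(-1L, -1L, -1L, 0L, -1L, 0L, 1L, -1L), ncol = 2)
  rr <- ((burned - 1L) %% nr) + 1L
  cc <- ((burned - 1L) %/% nr) + 1L
  for (k in seq_along(burned)) {
    r <- rr[k]; c <- cc[k]; i <- burned[k]
    for (q in 1:4) {
      r2 <- r + prev[q, 1]; c2 <- c + prev[q, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      j <- (c2 - 1L) * nr + r2
      if (day_of_burn[j] > 0 &&
          abs(day_of_burn[i] - day_of_burn[j]) <= max_gap_days) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(burned, find, integer(1))
  id[burned] <- as.integer(factor(roots, levels = unique(roots)))
  id
}

#' Remove fires smaller than a minimum pixel count
#'
#' Fires smaller than `min_pixels` contiguous pixels (default 6, i.e.
#' 0.54 km2 at 300 m) are removed from the scene: their pixels are set
#' unburned and their IDs dropped. Remaining fires keep their IDs.
#'
#' @param scene A labeled [burn_scene()].
#' @param min_pixels Minimum fire size in pixels (default 6).
#' @return The filtered `burn_scene`.
#' @export
filter_small_fires <- function(scene, min_pixels = 6) {
  stopifnot(inherits(scene, "burn_scene"), !is.null(scene$fire_id))
  if (min_pixels <= 1) return(scene)
  tab <- table(scene$fire_id[scene$fire_id > 0])
  small <- as.integer(names(tab)[tab < min_pixels])
  if (length(small)) {
    drop <- scene$fire_id %in% small
    scene$day_of_burn[drop] <- 0L
    scene$fire_id[drop] <- 0L
  }
  scene
}

#' Extract fire stops from a labeled burn scene
#'
#' Buffers each fire's burned pixels by a single pixel under first-order
#' Queen's adjacency; every in-bounds unburned pixel in that buffer becomes
#' one fire stop for that fire (a pixel touching two fires yields one stop
#' per fire). Each stop carries the burn date of the nearest burned pixel of
#' its fire (orthogonal neighbors are nearer than diagonal ones; ties on
#' distance take the latest date, i.e. where spread last halted) and an
#' outward unit direction from the local burned-pixel centroid (see
#' [compute_outward_direction()]).
#'
#' @param scene A labeled (and normally size-filtered) [burn_scene()].
#' @param neighborhood_radius Radius in pixels of the window used for the
#'   outward direction (default 1, a 3x3 window).
#' @return A tibble with one row per stop: `stop_id`, `fire_id`, `row`,
#'   `col`, `x`, `y`, `last_burn_date`, `nb_row`, `nb_col` (nearest burned
#'   pixel), `dir_x`, `dir_y`, `direction_defined`, `year`.
#' @export
extract_fire_stops <- function(scene, neighborhood_radius = 1) {
  stopifnot(inherits(scene, "burn_scene"), !is.null(scene$fire_id))
  fid <- scene$fire_id
  dob <- scene$day_of_burn
  nr <- nrow(fid); nc <- ncol(fid)
  burned <- which(fid > 0)

  out <- list()
  if (length(burned)) {
    rr <- ((burned - 1L) %% nr) + 1L
    cc <- ((burned - 1L) %/% nr) + 1L
    # candidate stop cells: Queen ring of every burned pixel, keyed per fire
    cand_r <- integer(0); cand_c <- integer(0); cand_f <- integer(0)
    for (q in 1:8) {
      r2 <- rr + fs_queen[q, 1]; c2 <- cc + fs_queen[q, 2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      if (!any(ok)) next
      r2 <- r2[ok]; c2 <- c2[ok]
      unb <- dob[cbind(r2, c2)] == 0
      cand_r <- c(cand_r, r2[unb]); cand_c <- c(cand_c, c2[unb])
      cand_f <- c(cand_f, fid[burned][ok][unb])
    }
    key <- paste(cand_f, cand_r, cand_c)
    keep <- !duplicated(key)
    out <- list(fire_id = cand_f[keep], row = cand_r[keep], col = cand_c[keep])
  }
  if (!length(out) || length(out$row) == 0) {
    return(tibble::tibble(
      stop_id = integer(0), fire_id = integer(0), row = integer(0),
      col = integer(0), x = numeric(0), y = numeric(0),
      last_burn_date = integer(0), nb_row = integer(0), nb_col = integer(0),
      dir_x = numeric(0), dir_y = numeric(0),
      direction_defined = logical(0), year = integer(0)))
  }

  n <- length(out$row)
  last_date <- integer(n); nb_row <- integer(n); nb_col <- integer(n)
  dir_x <- numeric(n); dir_y <- numeric(n); dir_ok <- logical(n)
  R <- neighborhood_radius
  for (i in seq_len(n)) {
    r <- out$row[i]; c <- out$col[i]; f <- out$fire_id[i]
    # nearest burned pixel of this fire among Queen neighbors; orthogonal
    # (distance 1) beats diagonal (sqrt 2); ties take the latest burn date
    best_d <- Inf; best_date <- -1L; best_rc <- c(NA_integer_, NA_integer_)
    for (q in 1:8) {
      r2 <- r + fs_queen[q, 1]; c2 <- c + fs_queen[q, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (fid[r2, c2] != f) next
      d <- abs(r2 - r) + abs(c2 - c)  # 1 orthogonal, 2 diagonal
      dt <- dob[r2, c2]
      if (d < best_d || (d == best_d && dt > best_date)) {
        best_d <- d; best_date <- dt; best_rc <- c(r2, c2)
      }
    }
    last_date[i] <- best_date; nb_row[i] <- best_rc[1]; nb_col[i] <- best_rc[2]

    # outward direction: from centroid of this fire's burned pixels in the
    # (2R+1)^2 window to the stop center; fallback: from the single nearest
    # burned pixel
    rs <- max(1, r - R):min(nr, r + R)
    cs <- max(1, c - R):min(nc, c + R)
    w <- fid[rs, cs, drop = FALSE] == f
    if (any(w)) {
      idx <- which(w, arr.ind = TRUE)
      vx <- c - mean(cs[idx[, 2]])   # +x east  = +col
      vy <- mean(rs[idx[, 1]]) - r   # +y north = -row
    } else {
      vx <- 0; vy <- 0
    }
    if (vx == 0 && vy == 0) {
      vx <- c - best_rc[2]; vy <- best_rc[1] - r
    }
    nv <- sqrt(vx^2 + vy^2)
    if (nv > 0) {
      dir_x[i] <- vx / nv; dir_y[i] <- vy / nv; dir_ok[i] <- TRUE
    } else {
      dir_x[i] <- NA_real_; dir_y[i] <- NA_real_; dir_ok[i] <- FALSE
    }
  }

  ctr <- fs_pixel_center(out$row, out$col, scene$pixel_size, scene$origin)
  tibble::tibble(
    stop_id = seq_len(n), fire_id = out$fire_id,
    row = out$row, col = out$col, x = ctr$x, y = ctr$y,
    last_burn_date = last_date, nb_row = nb_row, nb_col = nb_col,
    dir_x = dir_x, dir_y = dir_y, direction_defined = dir_ok,
    year = rep(scene$year, n)
  ) |> dplyr::arrange(.data$fire_id, .data$row, .data$col) |>
    dplyr::mutate(stop_id = dplyr::row_number())
}

#' Outward direction of a single fire stop
#'
#' The unit vector (x east, y north) from the centroid of the stop's fire's
#' burned pixels within a `(2 * neighborhood_radius + 1)` square window to
#' the stop pixel center: it points from burned toward unburned, i.e. the
#' direction the fire front was heading when it stopped. If the windowed
#' centroid coincides with the stop center (symmetric surround), the
#' direction falls back to the vector from the single nearest burned pixel;
#' a stop with no resolvable direction is flagged undefined.
#'
#' @param stop A one-row stop tibble (see [extract_fire_stops()]).
#' @param scene The labeled [burn_scene()].
#' @param neighborhood_radius Window radius in pixels (default 1).
#' @return A list with `dir` (length-2 unit vector) and `defined` (logical).
#' @export
compute_outward_direction <- function(stop, scene, neighborhood_radius = 1) {
  stopifnot(nrow(stop) == 1)
  fid <- scene$fire_id
  nr <- nrow(fid); nc <- ncol(fid)
  r <- stop$row; c <- stop$col; R <- neighborhood_radius
  rs <- max(1, r - R):min(nr, r + R)
  cs <- max(1, c - R):min(nc, c + R)
  w <- fid[rs, cs, drop = FALSE] == stop$fire_id
  vx <- 0; vy <- 0
  if (any(w)) {
    idx <- which(w, arr.ind = TRUE)
    vx <- c - mean(cs[idx[, 2]])
    vy <- mean(rs[idx[, 1]]) - r
  }
  if (vx == 0 && vy == 0 && is.finite(stop$nb_row)) {
    vx <- c - stop$nb_col; vy <- stop$nb_row - r
  }
  nv <- sqrt(vx^2 + vy^2)
  if (nv == 0) return(list(dir = c(NA_real_, NA_real_), defined = FALSE))
  list(dir = c(vx, vy) / nv, defined = TRUE)
}

#' Per-fire pixel counts and areas
#'
#' @param scene A labeled [burn_scene()].
#' @return Tibble `fire_id`, `n_pixels`, `area_km2`.
#' @export
fire_areas <- function(scene) {
  stopifnot(inherits(scene, "burn_scene"), !is.null(scene$fire_id))
  tab <- table(scene$fire_id[scene$fire_id > 0])
  tibble::tibble(
    fire_id = as.integer(names(tab)),
    n_pixels = as.integer(tab),
    area_km2 = as.integer(tab) * (scene$pixel_size / 1000)^2
  )
}
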