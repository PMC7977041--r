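#' Hexagonal grid specification
#'
#' A deterministic hexagonal tessellation of latitude-longitude space used to
#' bin occurrences into grid cells. The tessellation is axial, anchored so
#' that one cell is centred exactly on (`origin_lat`, `origin_lon`), with
#' `inner_diameter` measured edge-to-edge in degrees. Coordinates are treated
#' as planar degrees ("10 degrees latitude-longitude"); points are assigned to
#' the nearest cell centre, with longitude wrapping at +-180 and distance
#' ties broken toward the lexicographically smaller cell id.
#'
#' @param inner_diameter hexagon inner (edge-to-edge) diameter in degrees.
#' @param origin_lat,origin_lon centre of the anchor cell, degrees.
#' @param orientation `"flat-top"` (default) or `"pointy-top"`.
#' @return an object of class `hex_grid`.
#' @export
hex_grid <- function(inner_diameter = 10, origin_lat = 0, origin_lon = 0,
                     orientation = c("flat-top", "pointy-top")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(inner_diameter) || inner_diameter <= 0)
    stop("inner_diameter must be > 0")
  structure(list(inner_diameter = inner_diameter,
                 origin_lat = origin_lat, origin_lon = origin_lon,
                 orientation = orientation,
                 size = inner_diameter / sqrt(3)),  # circumradius
            class = "hex_grid")
}

# axial (q, r) -> planar offsets (x = lon offset, y = lat offset)
hex_axial_to_xy <- function(q, r, grid) {
  s <- grid$size
  if (grid$orientation == "flat-top")
    list(x = 1.5 * s * q, y = grid$inner_diameter * (r + q / 2))
  else
    list(x = grid$inner_diameter * (q + r / 2), y = 1.5 * s * r)
}

# planar offsets -> fractional axial coordinates
hex_xy_to_axial <- function(x, y, grid) {
  s <- grid$size
  if (grid$orientation == "flat-top")
    list(q = (2 / 3) * x / s, r = (-1 / 3 * x + sqrt(3) / 3 * y) / s)
  else
    list(q = (sqrt(3) / 3 * x - 1 / 3 * y) / s, r = (2 / 3) * y / s)
}

# cube rounding of fractional axial coordinates (vectorized)
hex_round <- function(q, r) {
  x <- q; z <- r; y <- -x - z
  rx <- round(x); ry <- round(y); rz <- round(z)
  dx <- abs(rx - x); dy <- abs(ry - y); dz <- abs(rz - z)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

hex_cell_id <- function(q, r) sprintf("q%dr%d", q, r)

#' Parse cell ids back to axial coordinates
#' @keywords internal
hex_cell_axial <- function(cell_id) {
  m <- regmatches(cell_id, regexec("^q(-?[0-9]+)r(-?[0-9]+)$", cell_id))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("malformed cell id(s): ", paste(cell_id[bad], collapse = ", "))
  list(q = as.integer(vapply(m, `[`, "", 2L)),
       r = as.integer(vapply(m, `[`, "", 3L)))
}

#' Centre coordinates of grid cells
#' @param cell_id character vector of cell ids (`"q<q>r<r>"`).
#' @param grid a [hex_grid()].
#' @return data.table with `cell_id`, `center_lat`, `center_lon` (longitude
#'   normalized into `[-180, 180)`).
#' @export
hex_cell_center <- function(cell_id, grid) {
  ax <- hex_cell_axial(cell_id)
  xy <- hex_axial_to_xy(ax$q, ax$r, grid)
  lon <- ((grid$origin_lon + xy$x + 180) %% 360) - 180
  data.table::data.table(cell_id = cell_id,
                         center_lat = grid$origin_lat + xy$y,
                         center_lon = lon)
}

#' Assign coordinates to hexagonal grid cells
#'
#' Deterministic nearest-centre assignment on the planar lat-lon tessellation
#' with longitude wrap at +-180. Only cells whose centre longitude lies in
#' `[-180, 180)` are minted (the canonical column range); near the dateline a
#' point may therefore be claimed by the nearest canonical centre across the
#' wrap. Ties go to the lexicographically smaller cell id.
#'
#' @param lat,lon numeric vectors, degrees; `lat` in `[-90, 90]`, `lon` in
#'   `[-180, 180)`.
#' @param grid a [hex_grid()].
#' @return character vector of cell ids.
#' @export
hex_cell_of <- function(lat, lon, grid) {
  stopifnot(inherits(grid, "hex_grid"), length(lat) == length(lon))
  if (length(lat) == 0L) return(character(0))
  if (any(!is.finite(lat) | lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(!is.finite(lon) | lon < -180 | lon >= 180))
    stop("longitude out of range [-180, 180)")

  n <- length(lat)
  y <- lat - grid$origin_lat
  # canonical column/row bound used to reject cells whose centre falls
  # outside [-180, 180) in longitude
  col_ok <- function(q, r) {
    xy <- hex_axial_to_xy(q, r, grid)
    lon_c <- grid$origin_lon + xy$x
    lon_c >= -180 & lon_c < 180
  }
  # neighbour offsets of an axial hex (same for both orientations)
  nq <- c(0L, 1L, -1L, 0L, 0L, 1L, -1L)
  nr <- c(0L, 0L, 0L, 1L, -1L, -1L, 1L)

  best_d <- rep(Inf, n)
  best_id <- rep(NA_character_, n)
  for (shift in c(-360, 0, 360)) {
    x <- lon + shift - grid$origin_lon
    fr <- hex_xy_to_axial(x, y, grid)
    rc <- hex_round(fr$q, fr$r)
    for (k in seq_along(nq)) {
      q <- rc$q + nq[k]; r <- rc$r + nr[k]
      ok <- col_ok(q, r)
      if (!any(ok)) next
      xy <- hex_axial_to_xy(q, r, grid)
      lon_c <- grid$origin_lon + xy$x
      lat_c <- grid$origin_lat + xy$y
      dlon <- ((lon - lon_c + 180) %% 360) - 180
      d <- dlon^2 + (lat - lat_c)^2
      id <- hex_cell_id(q, r)
      upd <- ok & (d < best_d - 1e-12 |
                     (abs(d - best_d) <= 1e-12 & id < best_id & !is.na(best_id)))
      if (any(upd)) {
        best_d[upd] <- d[upd]
        best_id[upd] <- id[upd]
      }
    }
  }
  if (anyNA(best_id)) stop("internal error: unassigned coordinates")
  best_id
}
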