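#' Regular geographic grid specification
#'
#' Cells are half-open in both axes, `[west, east) x [south, north)`, indexed
#' row 1 = southernmost row, column 1 = westernmost column. `lat0`/`lon0` is
#' the grid's south-west corner.
#'
#' @param resolution_deg cell size in decimal degrees.
#' @param lat0,lon0 south-west corner of the grid, decimal degrees.
#' @param n_rows,n_cols number of cells along latitude / longitude.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(resolution_deg, lat0, lon0, n_rows, n_cols) {
  stopifnot(resolution_deg > 0, n_rows >= 1, n_cols >= 1)
  if (lat0 < -90 || lat0 + n_rows * resolution_deg > 90 + 1e-9)
    stop("grid exceeds latitude range [-90, 90]")
  if (lon0 < -180 || lon0 + n_cols * resolution_deg > 180 + 1e-9)
    stop("grid exceeds longitude range [-180, 180]")
  structure(list(resolution_deg = resolution_deg, lat0 = lat0, lon0 = lon0,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' Spherical-Earth constants for cell geometry
#'
#' The grid-cell area model treats the Earth as a sphere of radius
#' `earth_radius_km` and a parallel as divided into `n_cells_lon` cells.
#' When `n_cells_lon` is `NULL` it is derived as `round(360 / resolution_deg)`
#' at the point of use, so coarse test grids stay consistent with their own
#' resolution.
#'
#' @param earth_radius_km Earth radius, km.
#' @param minutes_per_degree arc minutes per degree.
#' @param meters_per_minute meters per arc minute (one nautical mile).
#' @param n_cells_lon number of cells in a full parallel, or `NULL` to derive
#'   from the grid resolution.
#' @return A list of class `geodesy_constants`.
#' @export
geodesy_constants <- function(earth_radius_km = 6378,
                              minutes_per_degree = 60,
                              meters_per_minute = 1852,
                              n_cells_lon = NULL) {
  stopifnot(earth_radius_km > 0, minutes_per_degree > 0, meters_per_minute > 0)
  structure(list(earth_radius_km = earth_radius_km,
                 minutes_per_degree = minutes_per_degree,
                 meters_per_minute = meters_per_minute,
                 n_cells_lon = n_cells_lon),
            class = "geodesy_constants")
}

n_cells_lon_for <- function(spec, const) {
  if (!is.null(const$n_cells_lon)) const$n_cells_lon
  else round(360 / spec$resolution_deg)
}

#' Cell height in meters
#'
#' Constant over the grid: `resolution_deg * minutes_per_degree *
#' meters_per_minute` (one arc minute of latitude being one nautical mile).
#'
#' @param spec a `grid_spec`.
#' @param const `geodesy_constants`.
#' @return height of a cell in meters.
#' @export
cell_height_m <- function(spec, const = geodesy_constants()) {
  spec$resolution_deg * const$minutes_per_degree * const$meters_per_minute
}

#' Cell width in meters at a latitude
#'
#' Earth's perimeter at the latitude, `2 pi R cos(lat)`, divided by the
#' number of cells per parallel.
#'
#' @param latitude_deg latitude (or vector of latitudes), decimal degrees.
#' @param const `geodesy_constants`; `n_cells_lon` must be set, or pass
#'   `spec` to derive it.
#' @param spec optional `grid_spec` used to derive `n_cells_lon`.
#' @return width in meters (vectorized over latitude).
#' @export
cell_width_m <- function(latitude_deg, const = geodesy_constants(), spec = NULL) {
  stopifnot(all(abs(latitude_deg) <= 90))
  n_cells <- if (!is.null(const$n_cells_lon)) const$n_cells_lon
             else if (!is.null(spec)) n_cells_lon_for(spec, const)
             else stop("n_cells_lon not set and no grid_spec supplied")
  perimeter_m <- 2 * pi * const$earth_radius_km * 1000 *
    cos(latitude_deg * pi / 180)
  perimeter_m / n_cells
}

#' Cell area in km2 at a latitude
#'
#' `cell area = cell height * cell width`, evaluated at the given latitude
#' (use the cell-center latitude for per-cell areas).
#'
#' @inheritParams cell_width_m
#' @param spec a `grid_spec`.
#' @return area in km2 (vectorized over latitude).
#' @export
cell_area_km2 <- function(latitude_deg, spec, const = geodesy_constants()) {
  h <- cell_height_m(spec, const)
  w <- cell_width_m(latitude_deg, const, spec = spec)
  h * w / 1e6
}

#' Exact spherical-quadrilateral cell area
#'
#' Independent of the strip formula in [cell_area_km2()]: the exact area on a
#' sphere of a cell bounded by two meridians and two parallels,
#' `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))`. Used to cross-check the
#' formula-based areas (they agree within 0.5% away from the poles, where the
#' cylindrical-strip approximation degrades).
#'
#' @param lat_south_deg southern edge latitude(s) of the cell, degrees.
#' @param spec a `grid_spec`.
#' @param const `geodesy_constants`.
#' @return area in km2.
#' @export
cell_area_spherical_km2 <- function(lat_south_deg, spec,
                                    const = geodesy_constants()) {
  r <- const$earth_radius_km
  dlon <- spec$resolution_deg * pi / 180
  lat_n <- (lat_south_deg + spec$resolution_deg) * pi / 180
  lat_s <- lat_south_deg * pi / 180
  r^2 * dlon * (sin(lat_n) - sin(lat_s))
}

#' Cell-center coordinates and per-cell areas
#'
#' @param spec a `grid_spec`.
#' @return `cell_center_lats()`/`cell_center_lons()`: vectors of length
#'   `n_rows`/`n_cols`. `cell_area_grid()`: an `n_rows x n_cols` matrix of
#'   areas (km2), constant within a row.
#' @export
cell_center_lats <- function(spec) {
  spec$lat0 + (seq_len(spec$n_rows) - 0.5) * spec$resolution_deg
}

#' @rdname cell_center_lats
#' @export
cell_center_lons <- function(spec) {
  spec$lon0 + (seq_len(spec$n_cols) - 0.5) * spec$resolution_deg
}

#' @rdname cell_center_lats
#' @param const `geodesy_constants`.
#' @export
cell_area_grid <- function(spec, const = geodesy_constants()) {
  row_areas <- cell_area_km2(cell_center_lats(spec), spec, const)
  matrix(rep(row_areas, spec$n_cols), nrow = spec$n_rows, ncol = spec$n_cols)
}

#' Zonal aggregation over a grid
#'
#' Sums `values * areas` per zone. With indicator (0/1 or logical) values
#' this is the zonal area; with effort values and unit areas it is a zonal
#' total. Cells with `NA` zone are skipped; zones absent from the input are
#' absent from the output.
#'
#' @param values numeric matrix/vector of per-cell values.
#' @param zones matrix/vector of per-cell zone labels (character or factor).
#' @param areas numeric matrix/vector of per-cell weights; defaults to 1.
#' @return named numeric vector of per-zone totals.
#' @export
zonal_sum <- function(values, zones, areas = 1) {
  if (length(areas) == 1L) areas <- rep(areas, length(values))
  if (length(values) != length(zones) || length(values) != length(areas))
    stop("values, zones and areas must share the grid shape")
  v <- as.vector(values) * as.vector(areas)
  z <- as.vector(zones)
  keep <- !is.na(z) & !is.na(v)
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  tot <- tapply(v[keep], z[keep], sum)
  stats::setNames(as.numeric(tot), names(tot))
}

#' Read / write a grid as an ESRI ASCII raster
#'
#' Plain-text exchange format for regular grids: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values, northernmost row first.
#'
#' @param mat numeric matrix (row 1 = southernmost row).
#' @param spec a `grid_spec`.
#' @param path file path (`.asc`).
#' @param digits decimal digits written for cell values.
#' @param nodata value standing in for `NA`.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   a list with `spec` (a `grid_spec`) and `data` (matrix, row 1 = south).
#' @export
write_ascii_grid <- function(mat, spec, path, digits = 3, nodata = -99999) {
  stopifnot(nrow(mat) == spec$n_rows, ncol(mat) == spec$n_cols)
  header <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$lon0),
    sprintf("yllcorner %.10g", spec$lat0),
    sprintf("cellsize %.10g", spec$resolution_deg),
    sprintf("NODATA_value %g", nodata)
  )
  m <- mat
  m[is.na(m)] <- nodata
  rows <- vapply(rev(seq_len(nrow(m))), function(i)
    paste(formatC(m[i, ], format = "f", digits = digits), collapse = " "), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[[`, "", 1))
  val <- as.numeric(vapply(hdr, `[[`, "", 2))
  names(val) <- key
  n_rows <- as.integer(val[["nrows"]]); n_cols <- as.integer(val[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != n_rows * n_cols) stop("ASCII grid body size mismatch")
  m <- matrix(body, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m <- m[rev(seq_len(n_rows)), , drop = FALSE]
  m[m == val[["nodata_value"]]] <- NA
  list(
    spec = grid_spec(val[["cellsize"]], val[["yllcorner"]],
                     val[["xllcorner"]], n_rows, n_cols),
    data = m
  )
}
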