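#' Bathymetry grid
#'
#' Wraps a regular lon/lat elevation grid. Elevation follows the bathymetric
#' raster convention (negative below sea level, meters); seabed depth is its
#' negation. Cells with elevation >= 0 are land and are masked from every
#' computation.
#'
#' @param spec a `grid_spec`.
#' @param elevation numeric `n_rows x n_cols` matrix, row 1 = southernmost.
#' @return An object of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(spec, elevation) {
  stopifnot(inherits(spec, "grid_spec"),
            nrow(elevation) == spec$n_rows, ncol(elevation) == spec$n_cols)
  structure(list(spec = spec, elevation = elevation),
            class = "bathymetry_grid")
}

#' @rdname bathymetry_grid
#' @param bathy a `bathymetry_grid`.
#' @return `seabed_depth_m()`: matrix of positive-down depths (`NA` on land);
#'   `ocean_mask()`: logical matrix, `TRUE` over ocean.
#' @export
seabed_depth_m <- function(bathy) {
  d <- -bathy$elevation
  d[d <= 0] <- NA
  d
}

#' @rdname bathymetry_grid
#' @export
ocean_mask <- function(bathy) {
  !is.na(bathy$elevation) & bathy$elevation < 0
}

#' Read / write bathymetry as ESRI ASCII raster
#' @param path `.asc` file path.
#' @inheritParams bathymetry_grid
#' @export
read_bathymetry <- function(path) {
  g <- read_ascii_grid(path)
  bathymetry_grid(g$spec, g$data)
}

#' @rdname read_bathymetry
#' @param bathy a `bathymetry_grid`.
#' @export
write_bathymetry <- function(bathy, path) {
  write_ascii_grid(bathy$elevation, bathy$spec, path, digits = 2)
}

#' Ecoregion map
#'
#' A set of labelled, non-overlapping polygons tiling the ocean, each coastal
#' (within 200 nautical miles / the shelf) or offshore (open-ocean,
#' "pelagic" ecoregions in the source typology).
#'
#' @param label character vector of unique ecoregion names.
#' @param class `"coastal"` or `"offshore"` per ecoregion.
#' @param geoms list of geometries (see [geometry]).
#' @return An object of class `ecoregion_map`.
#' @export
ecoregion_map <- function(label, class, geoms) {
  stopifnot(length(label) == length(class), length(label) == length(geoms),
            !anyDuplicated(label), all(class %in% c("coastal", "offshore")))
  structure(list(label = as.character(label), class = as.character(class),
                 geoms = lapply(geoms, repair_geom)),
            class = "ecoregion_map")
}

#' Read / write ecoregions as GeoJSON
#'
#' Features carry `label` and `class` properties.
#' @param path GeoJSON file path.
#' @export
read_ecoregions <- function(path) {
  f <- read_geojson_features(path)
  ecoregion_map(
    label = vapply(f$properties, function(p) as.character(p$label), ""),
    class = vapply(f$properties, function(p) as.character(p$class), ""),
    geoms = f$geoms
  )
}

#' @rdname read_ecoregions
#' @param ecoregions an `ecoregion_map`.
#' @export
write_ecoregions <- function(ecoregions, path) {
  props <- data.frame(label = ecoregions$label, class = ecoregions$class,
                      stringsAsFactors = FALSE)
  write_geojson_features(ecoregions$geoms, props, path)
}

#' Rasterize ecoregions onto a grid
#'
#' Each cell takes the label of the ecoregion polygon containing its center
#' (cells are half-open, so a center is unambiguous); cells whose center is
#' covered by no polygon get `NA`.
#'
#' @param ecoregions an `ecoregion_map`.
#' @param spec a `grid_spec`.
#' @return character matrix of ecoregion labels.
#' @export
rasterize_ecoregions <- function(ecoregions, spec) {
  lats <- cell_center_lats(spec)
  lons <- cell_center_lons(spec)
  xs <- rep(lons, each = spec$n_rows)
  ys <- rep(lats, times = spec$n_cols)
  lab <- rep(NA_character_, length(xs))
  for (i in seq_along(ecoregions$label)) {
    bb <- geom_bbox(ecoregions$geoms[[i]])
    cand <- which(is.na(lab) &
                    xs >= bb["xmin"] & xs <= bb["xmax"] &
                    ys >= bb["ymin"] & ys <= bb["ymax"])
    if (!length(cand)) next
    hit <- point_in_geom(xs[cand], ys[cand], ecoregions$geoms[[i]])
    lab[cand[hit]] <- ecoregions$label[i]
  }
  matrix(lab, nrow = spec$n_rows, ncol = spec$n_cols)
}

#' Enumerate 3D realms and their areas
#'
#' Builds the 3D typology (ecoregion x depth band x domain) over a
#' bathymetry grid. Benthic band membership is the band containing a cell's
#' seabed depth; a pelagic band occurs in every cell whose seabed depth
#' exceeds the band's shallow bound (the surface-to-seabed column rule).
#' Realms with empty intersection are omitted rather than reported with zero
#' area.
#'
#' @param bathy a `bathymetry_grid`.
#' @param ecoregions an `ecoregion_map`, or a pre-rasterized label matrix.
#' @param benthic,pelagic depth schemes.
#' @param const `geodesy_constants`.
#' @return data frame with columns `ecoregion`, `band`, `domain`,
#'   `area_km2`, each row a 3D realm of positive area.
#' @export
enumerate_realms3d <- function(bathy, ecoregions,
                               benthic = default_benthic_scheme(),
                               pelagic = default_pelagic_scheme(),
                               const = geodesy_constants()) {
  spec <- bathy$spec
  eco <- if (inherits(ecoregions, "ecoregion_map"))
    rasterize_ecoregions(ecoregions, spec) else ecoregions
  stopifnot(all(dim(eco) == c(spec$n_rows, spec$n_cols)))
  depth <- seabed_depth_m(bathy)
  areas <- cell_area_grid(spec, const)
  ocean <- ocean_mask(bathy) & !is.na(eco)

  bband <- classify_benthic(as.vector(depth), benthic)
  zone_b <- ifelse(ocean, paste(eco, bband, sep = "\r"), NA)
  tot_b <- zonal_sum(as.numeric(ocean), zone_b, areas)
  out <- split_zone_table(tot_b, "benthic")

  for (i in seq_len(nrow(pelagic$bands))) {
    in_band <- ocean & !is.na(depth) & depth > pelagic$bands$shallow_m[i]
    tot_p <- zonal_sum(as.numeric(in_band), ifelse(in_band, eco, NA), areas)
    if (length(tot_p))
      out <- rbind(out, data.frame(
        ecoregion = names(tot_p), band = pelagic$bands$name[i],
        domain = "pelagic", area_km2 = as.numeric(tot_p),
        stringsAsFactors = FALSE))
  }
  out <- out[out$area_km2 > 0, , drop = FALSE]
  order_realms(out, benthic, pelagic)
}

split_zone_table <- function(totals, domain) {
  if (!length(totals))
    return(data.frame(ecoregion = character(), band = character(),
                      domain = character(), area_km2 = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(names(totals), "\r", fixed = TRUE)
  data.frame(
    ecoregion = vapply(parts, `[[`, "", 1),
    band = vapply(parts, `[[`, "", 2),
    domain = domain,
    area_km2 = as.numeric(totals),
    stringsAsFactors = FALSE
  )
}

order_realms <- function(df, benthic, pelagic) {
  band_order <- c(benthic$bands$name, pelagic$bands$name)
  df <- df[order(df$domain, match(df$band, band_order), df$ecoregion), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
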