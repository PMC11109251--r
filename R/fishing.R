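#' Gear depth catalog
#'
#' Maps gear labels to an operating mode and, for pelagic gears, an operating
#' depth range. Benthic gears work at the seabed; pelagic gears within their
#' depth range capped by local bathymetry; unspecified gears (e.g. AIS gear
#' classes that do not discriminate bottom from midwater activity) cannot be
#' attributed to a depth and are reported separately.
#'
#' @param name gear labels.
#' @param mode `"benthic"`, `"pelagic"` or `"unspecified"` per gear.
#' @param depth_min_m,depth_max_m operating range in meters for pelagic
#'   gears (`NA` otherwise); `0 <= depth_min_m < depth_max_m`.
#' @return data frame of class `gear_catalog`.
#' @export
gear_catalog <- function(name, mode, depth_min_m = NA_real_,
                         depth_max_m = NA_real_) {
  stopifnot(!anyDuplicated(name),
            all(mode %in% c("benthic", "pelagic", "unspecified")))
  df <- data.frame(name = as.character(name), mode = as.character(mode),
                   depth_min_m = as.numeric(depth_min_m),
                   depth_max_m = as.numeric(depth_max_m),
                   stringsAsFactors = FALSE)
  pel <- df$mode == "pelagic"
  if (any(pel & (is.na(df$depth_min_m) | is.na(df$depth_max_m))))
    stop("pelagic gears need a depth range")
  if (any(pel & !(df$depth_min_m >= 0 & df$depth_min_m < df$depth_max_m),
          na.rm = TRUE))
    stop("pelagic gear range must satisfy 0 <= depth_min_m < depth_max_m")
  class(df) <- c("gear_catalog", "data.frame")
  df
}

#' Default gear depth catalog
#'
#' Shipped as `inst/extdata/gear_catalog.csv`; operating ranges are
#' literature-style defaults meant to be reviewed and edited for any real
#' application. The unspecified gears mirror AIS gear classes that pool
#' bottom and midwater activity ("trawlers", "purse seines", generic
#' "fishing").
#'
#' @return a `gear_catalog`.
#' @export
default_gear_catalog <- function() {
  read_gear_catalog(system.file("extdata", "gear_catalog.csv",
                                package = "realms3d", mustWork = TRUE))
}

#' @rdname default_gear_catalog
#' @param path CSV with columns name, mode, depth_min_m, depth_max_m.
#' @export
read_gear_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gear_catalog(df$name, df$mode, df$depth_min_m, df$depth_max_m)
}

#' Fishing event tables
#'
#' Point records of fishing activity: location, calendar year, fishing hours
#' and a gear label joined from the vessel registry. GFW-style column names
#' (`geartype`, `mmsi`, `cell_ll_lat`, ...) can be renamed through `mapping`.
#'
#' @param path CSV file path.
#' @param mapping named character vector renaming source columns to
#'   `lon`, `lat`, `year`, `hours`, `gear`, `vessel_id`.
#' @return data frame with those six columns.
#' @export
read_fishing_events <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping))
    for (k in names(mapping)) names(df)[names(df) == mapping[[k]]] <- k
  need <- c("lon", "lat", "year", "hours", "gear")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$vessel_id)) df$vessel_id <- NA_character_
  if (any(df$hours < 0)) stop("negative fishing hours")
  df[, c("lon", "lat", "year", "hours", "gear", "vessel_id")]
}

#' @rdname read_fishing_events
#' @param events an event data frame.
#' @export
write_fishing_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
}

# Row/column of the grid cell containing each point, half-open cells
# [west, east) x [south, north); NA outside the grid.
event_cell_index <- function(lon, lat, spec) {
  col <- floor((lon - spec$lon0) / spec$resolution_deg) + 1
  row <- floor((lat - spec$lat0) / spec$resolution_deg) + 1
  ok <- col >= 1 & col <= spec$n_cols & row >= 1 & row <= spec$n_rows
  idx <- ifelse(ok, (col - 1) * spec$n_rows + row, NA)
  as.integer(idx)
}

#' Depth realms impacted by fishing events
#'
#' Under the impact rule every depth realm in the vertical column of an
#' activity, surface to seabed, is impacted: exactly one benthic band (the
#' band of the seabed depth) and every pelagic band shallower than the
#' seabed. Events over land (or outside the grid) are excluded and counted.
#'
#' @param events event data frame (see [read_fishing_events()]).
#' @param bathy a `bathymetry_grid`.
#' @param benthic,pelagic depth schemes.
#' @return list with `benthic` (character vector, one band per event, `NA`
#'   for excluded events), `pelagic` (list of band vectors), and
#'   `n_excluded_land`.
#' @export
impacted_realms <- function(events, bathy,
                            benthic = default_benthic_scheme(),
                            pelagic = default_pelagic_scheme()) {
  depth <- seabed_depth_m(bathy)
  idx <- event_cell_index(events$lon, events$lat, bathy$spec)
  d <- ifelse(is.na(idx), NA, depth[idx])
  bb <- classify_benthic(d, benthic)
  pel <- lapply(d, function(di) {
    if (is.na(di)) character(0)
    else pelagic$bands$name[pelagic$bands$shallow_m < di]
  })
  list(benthic = bb, pelagic = pel, seabed_depth_m = d,
       n_excluded_land = sum(is.na(d)))
}

#' Depth realms targeted by a fishing gear
#'
#' Benthic gears target the benthic band of the seabed depth. Pelagic gears
#' target the pelagic bands intersecting the open interval
#' `(depth_min, min(depth_max, seabed depth))`; a range touching a band only
#' at a boundary point does not select it. If the gear's minimum depth meets
#' or exceeds the seabed (a catalog inconsistency for that location) a
#' warning is raised and the deepest pelagic band of the column applies
#' rather than an empty set. Unspecified gears return the `"unspecified"`
#' flag.
#'
#' @param seabed_depth_m positive seabed depth at the event location, m.
#' @param gear one row of a `gear_catalog` (or a gear name plus `catalog`).
#' @param catalog a `gear_catalog` used when `gear` is a name.
#' @param benthic,pelagic depth schemes.
#' @return character vector of band names, or `"unspecified"`.
#' @export
targeted_realms <- function(seabed_depth_m, gear, catalog = NULL,
                            benthic = default_benthic_scheme(),
                            pelagic = default_pelagic_scheme()) {
  if (is.character(gear)) {
    i <- match(gear, catalog$name)
    if (is.na(i)) return("unspecified")
    gear <- catalog[i, ]
  }
  stopifnot(is.finite(seabed_depth_m), seabed_depth_m > 0)
  if (gear$mode == "unspecified") return("unspecified")
  if (gear$mode == "benthic")
    return(classify_benthic(seabed_depth_m, benthic))
  lo <- gear$depth_min_m
  hi <- min(gear$depth_max_m, seabed_depth_m)
  if (lo >= hi) {
    warning(sprintf(
      "gear '%s' operating range (%g-%g m) does not overlap the water column (seabed %g m); assigning the deepest pelagic band of the column",
      gear$name, gear$depth_min_m, gear$depth_max_m, seabed_depth_m))
    col <- pelagic$bands$name[pelagic$bands$shallow_m < seabed_depth_m]
    return(col[length(col)])
  }
  sel <- pmax(pelagic$bands$shallow_m, lo) < pmin(pelagic$bands$deep_m, hi)
  pelagic$bands$name[sel]
}

#' Fishing pressure per 3D realm
#'
#' Sums fishing hours per (ecoregion, band, domain, gear, year) and divides
#' by the 3D realm's area to get pressure in hours per km2. Under
#' `attribution = "impacted"` every event contributes its full hours to its
#' one benthic realm and to each pelagic realm in its surface-to-seabed
#' column. Under `"targeted"` contributions follow [targeted_realms()]:
#' benthic gears to the seabed band, pelagic gears to every band their
#' capped depth range intersects (full hours to each by default, or split
#' evenly with `split_hours = TRUE`), unknown or unspecified gears to an
#' `"unspecified"` pseudo-realm with no area (pressure `NA`).
#'
#' Events over land or outside the grid are excluded; their count is
#' attached as the `n_excluded_land` attribute. Unknown gear labels are
#' treated as unspecified and counted in `n_unknown_gear`.
#'
#' @param events event data frame.
#' @param bathy a `bathymetry_grid`.
#' @param ecoregions an `ecoregion_map` or label matrix.
#' @param catalog a `gear_catalog`.
#' @param benthic,pelagic depth schemes.
#' @param realm_areas optional [enumerate_realms3d()] table.
#' @param attribution `"impacted"` or `"targeted"`.
#' @param split_hours under `"targeted"`, divide a pelagic event's hours
#'   evenly across its targeted bands instead of counting them fully in each.
#' @param const `geodesy_constants`.
#' @return data frame (PressureTable) with columns `ecoregion`, `band`,
#'   `domain`, `gear`, `year`, `effort_hours`, `realm_area_km2`,
#'   `pressure_hr_per_km2`.
#' @export
pressure_by_realm <- function(events, bathy, ecoregions, catalog,
                              benthic = default_benthic_scheme(),
                              pelagic = default_pelagic_scheme(),
                              realm_areas = NULL,
                              attribution = c("impacted", "targeted"),
                              split_hours = FALSE,
                              const = geodesy_constants()) {
  attribution <- match.arg(attribution)
  spec <- bathy$spec
  eco <- if (inherits(ecoregions, "ecoregion_map"))
    rasterize_ecoregions(ecoregions, spec) else ecoregions
  if (is.null(realm_areas))
    realm_areas <- enumerate_realms3d(bathy, eco, benthic, pelagic, const)
  depth <- seabed_depth_m(bathy)
  idx <- event_cell_index(events$lon, events$lat, spec)
  d <- ifelse(is.na(idx), NA, depth[idx])
  eco_ev <- ifelse(is.na(idx), NA, eco[idx])
  valid <- !is.na(d) & !is.na(eco_ev)
  n_land <- sum(!valid)

  gear_mode <- catalog$mode[match(events$gear, catalog$name)]
  n_unknown <- sum(is.na(gear_mode) & valid)
  gear_mode[is.na(gear_mode)] <- "unspecified"

  contrib <- list()
  add <- function(eco_v, band_v, dom_v, gear_v, year_v, hours_v) {
    if (!length(hours_v)) return(invisible(NULL))
    contrib[[length(contrib) + 1L]] <<- data.frame(
      ecoregion = eco_v, band = band_v, domain = dom_v, gear = gear_v,
      year = year_v, hours = hours_v, stringsAsFactors = FALSE)
  }

  bband <- classify_benthic(d, benthic)
  if (attribution == "impacted") {
    v <- which(valid)
    add(eco_ev[v], bband[v], "benthic", events$gear[v], events$year[v],
        events$hours[v])
    for (i in seq_len(nrow(pelagic$bands))) {
      w <- v[d[v] > pelagic$bands$shallow_m[i]]
      if (length(w))
        add(eco_ev[w], pelagic$bands$name[i], "pelagic", events$gear[w],
            events$year[w], events$hours[w])
    }
  } else {
    for (j in which(valid)) {
      mode_j <- gear_mode[j]
      if (mode_j == "unspecified") {
        add(eco_ev[j], "unspecified", "unspecified", events$gear[j],
            events$year[j], events$hours[j])
      } else if (mode_j == "benthic") {
        add(eco_ev[j], bband[j], "benthic", events$gear[j], events$year[j],
            events$hours[j])
      } else {
        bands <- targeted_realms(d[j], catalog[match(events$gear[j],
                                                     catalog$name), ],
                                 benthic = benthic, pelagic = pelagic)
        h <- if (split_hours) events$hours[j] / length(bands) else events$hours[j]
        add(rep(eco_ev[j], length(bands)), bands, "pelagic",
            events$gear[j], events$year[j], rep(h, length(bands)))
      }
    }
  }

  if (!length(contrib)) {
    out <- data.frame(ecoregion = character(), band = character(),
                      domain = character(), gear = character(),
                      year = integer(), effort_hours = numeric(),
                      realm_area_km2 = numeric(),
                      pressure_hr_per_km2 = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_excluded_land") <- n_land
    attr(out, "n_unknown_gear") <- n_unknown
    return(out)
  }
  all_c <- do.call(rbind, contrib)
  agg <- stats::aggregate(hours ~ ecoregion + band + domain + gear + year,
                          data = all_c, FUN = sum)
  names(agg)[names(agg) == "hours"] <- "effort_hours"
  agg <- merge(agg, realm_areas, all.x = TRUE,
               by = c("ecoregion", "band", "domain"))
  names(agg)[names(agg) == "area_km2"] <- "realm_area_km2"
  agg$pressure_hr_per_km2 <- agg$effort_hours / agg$realm_area_km2
  agg <- agg[order(agg$domain, agg$band, agg$ecoregion, agg$gear, agg$year), ]
  rownames(agg) <- NULL
  attr(agg, "n_excluded_land") <- n_land
  attr(agg, "n_unknown_gear") <- n_unknown
  agg
}

#' Inter-annual mean and confidence interval
#'
#' Student-t interval on the mean of yearly values:
#' `mean +/- t(df = n - 1, (1 + confidence)/2) * sd / sqrt(n)`.
#'
#' @param yearly numeric vector of per-year values (n >= 2 for a CI).
#' @param confidence confidence level, e.g. 0.95.
#' @return list with `mean`, `ci_low`, `ci_high`, `n` (`ci_*` `NA` if n < 2).
#' @export
interannual_stats <- function(yearly, confidence = 0.95) {
  n <- length(yearly)
  m <- mean(yearly)
  if (n < 2) return(list(mean = m, ci_low = NA_real_, ci_high = NA_real_, n = n))
  half <- stats::qt((1 + confidence) / 2, df = n - 1) * stats::sd(yearly) / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Share of fishing hours by gear mode
#'
#' Fraction of total fishing hours attributable to benthic, pelagic, and
#' unspecified gear modes (the depth-disaggregation level of the fleet).
#' Unknown gear labels count as unspecified.
#'
#' @param events event data frame.
#' @param catalog a `gear_catalog`.
#' @return named numeric vector `benthic`/`pelagic`/`unspecified` summing to
#'   1, or all `NA` when total hours are zero.
#' @export
gear_disaggregation_report <- function(events, catalog) {
  mode <- catalog$mode[match(events$gear, catalog$name)]
  mode[is.na(mode)] <- "unspecified"
  tot <- sum(events$hours)
  out <- c(benthic = 0, pelagic = 0, unspecified = 0)
  if (tot == 0) return(out * NA_real_)
  agg <- tapply(events$hours, mode, sum)
  out[names(agg)] <- agg / tot
  out
}
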