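#' Synthetic seascape parameters
#'
#' Defaults describe a 100 x 100 cell, 0.05-degree equatorial seascape with a
#' land margin on its western edge, a shelf-to-hadal depth gradient spanning
#' all eight benthic bands, two coastal and two offshore ecoregions,
#' protected-area targets echoing the shallow bias of the global network
#' (euphotic best covered, abyssal least), three years of fishing events with
#' shallow-dominated trawling and deep-dominated drifting longlines, and 45%
#' of fishing hours under depth-ambiguous ("unspecified") gear labels.
#'
#' @param seed integer RNG seed; every random draw in the generator flows
#'   from it.
#' @param resolution_deg,lat0,lon0,n_rows,n_cols grid layout (see
#'   [grid_spec()]).
#' @param land_cols number of land columns on the western margin.
#' @param max_depth_m deepest seabed depth, m.
#' @param noise_amp relative amplitude of the smooth bathymetric noise
#'   (fraction of local depth; 0 gives a strictly monotone shelf profile).
#' @param n_coastal,n_offshore number of coastal / offshore ecoregions
#'   (latitudinal bands).
#' @param protection_targets named vector of per-benthic-band target
#'   protection fractions (names = benthic band names; fractions in [0, 1]).
#' @param category_mix named probability vector over IUCN categories used to
#'   label protected-area polygons.
#' @param coverage_heterogeneity log-normal sd (on the log scale) of the
#'   per-(band x ecoregion) multiplier applied to the band's target fraction,
#'   emulating the strong between-ecoregion spread of real protection
#'   coverage; 0 gives every ecoregion the band target exactly.
#' @param overlap_rate fraction of protected-area polygons that receive an
#'   overlapping duplicate with a low-priority category, to exercise
#'   flattening.
#' @param n_events_per_year fishing events per year.
#' @param years calendar years of fishing activity.
#' @param gear_niches data frame of per-gear sampling niches: `gear`,
#'   `share` (of events), `pref_min_m`, `pref_max_m` (preferred seabed depth
#'   range) and `decay` (intensity decay per km of depth outside the
#'   preferred range; 0 = uniform).
#' @param unspecified_hours_fraction exact fraction of total fishing hours
#'   carried by unspecified-mode gears.
#' @param hours_median median of the log-normal fishing-hours distribution.
#' @return list of class `seascape_params`.
#' @export
seascape_params <- function(seed = 1L,
                            resolution_deg = 0.05, lat0 = -2.5, lon0 = 0,
                            n_rows = 100L, n_cols = 100L,
                            land_cols = 4L,
                            max_depth_m = 7500,
                            noise_amp = 0.08,
                            n_coastal = 3L, n_offshore = 2L,
                            protection_targets = c(
                              euphotic = 0.15, upper_mesophotic = 0.10,
                              lower_mesophotic = 0.07, rariphotic = 0.07,
                              upper_bathyal = 0.10, lower_bathyal = 0.09,
                              abyssal = 0.058, hadal = 0.08),
                            category_mix = c(
                              Ia = 0.05, Ib = 0.05, II = 0.10, III = 0.05,
                              IV = 0.15, V = 0.10, VI = 0.30, Unknown = 0.20),
                            coverage_heterogeneity = 1.2,
                            overlap_rate = 0.3,
                            n_events_per_year = 2000L,
                            years = 2018:2020,
                            gear_niches = default_gear_niches(),
                            unspecified_hours_fraction = 0.45,
                            hours_median = 2) {
  stopifnot(all(protection_targets >= 0), all(protection_targets <= 1),
            overlap_rate >= 0, overlap_rate <= 1,
            unspecified_hours_fraction >= 0, unspecified_hours_fraction < 1,
            abs(sum(category_mix) - 1) < 1e-9,
            land_cols >= 1, land_cols < n_cols)
  p <- as.list(environment())
  class(p) <- "seascape_params"
  p
}

#' @rdname seascape_params
#' @export
default_gear_niches <- function() {
  data.frame(
    gear = c("bottom_trawl", "set_longline", "pot", "midwater_trawl",
             "drifting_longlines", "trawlers", "purse_seines", "fishing"),
    share = c(0.20, 0.08, 0.05, 0.10, 0.12, 0.25, 0.10, 0.10),
    pref_min_m = c(0, 0, 0, 200, 2000, 0, 500, 0),
    pref_max_m = c(300, 1000, 200, 2000, 7500, 500, 4000, 7500),
    decay = c(2, 1.5, 3, 1, 1, 1, 0.5, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate bathymetry
#'
#' A monotone west-to-east shelf-to-abyss profile whose depth anchors give
#' each of the eight benthic bands a similar share of ocean columns, plus a
#' smooth seeded noise field (sinusoidal modes, relative amplitude
#' `noise_amp`). Elevation is negative over ocean, positive over the western
#' land margin, rounded to centimeters so file round-trips are lossless.
#'
#' @param params a `seascape_params`.
#' @return a `bathymetry_grid`.
#' @export
simulate_bathymetry <- function(params) {
  set.seed(params$seed)
  spec <- grid_spec(params$resolution_deg, params$lat0, params$lon0,
                    params$n_rows, params$n_cols)
  n_ocean <- params$n_cols - params$land_cols
  anchors <- c(2, 30, 60, 150, 300, 1000, 3500, 6000, params$max_depth_m)
  frac <- (seq_len(n_ocean) - 0.5) / n_ocean
  base <- stats::approx(seq(0, 1, length.out = length(anchors)), anchors,
                        xout = frac)$y
  depth <- matrix(rep(base, each = params$n_rows), nrow = params$n_rows)
  if (params$noise_amp > 0) {
    n_modes <- 4L
    fr <- stats::runif(n_modes, 0.5, 2.5)
    fc <- stats::runif(n_modes, 0.5, 2.5)
    ph <- stats::runif(n_modes, 0, 2 * pi)
    amp <- stats::runif(n_modes, 0.5, 1)
    r <- matrix(rep(seq_len(params$n_rows) / params$n_rows, n_ocean),
                nrow = params$n_rows)
    cc <- matrix(rep(seq_len(n_ocean) / n_ocean, each = params$n_rows),
                 nrow = params$n_rows)
    s <- 0
    for (k in seq_len(n_modes))
      s <- s + amp[k] * sin(2 * pi * (fr[k] * r + fc[k] * cc) + ph[k])
    s <- s / sum(amp)
    depth <- depth * (1 + params$noise_amp * s)
  }
  depth <- pmax(depth, 0.5)
  elev <- matrix(10, nrow = params$n_rows, ncol = params$n_cols)
  elev[, (params$land_cols + 1):params$n_cols] <- -depth
  bathymetry_grid(spec, round(elev, 2))
}

#' Simulate ecoregions
#'
#' A coastal/offshore split at the easternmost column still holding seabed
#' shallower than 200 m (so coastal ecoregions contain every cell above the
#' 200 m isobath, including the land margin), each side divided into
#' latitudinal bands. The rectangles tile the grid exactly.
#'
#' @param params a `seascape_params`.
#' @param bathy the simulated `bathymetry_grid`.
#' @return list with `map` (an `ecoregion_map`) and `labels` (the
#'   generator's own cell-label matrix, used for ground truth).
#' @export
simulate_ecoregions <- function(params, bathy) {
  spec <- bathy$spec
  depth <- seabed_depth_m(bathy)
  shallow_cols <- which(apply(depth, 2, function(col) any(!is.na(col) & col < 200)))
  col_split <- max(shallow_cols)  # last column with any sub-200 m seabed
  lat_edges <- function(n) {
    cuts <- round(seq(0, spec$n_rows, length.out = n + 1))
    cbind(cuts[-length(cuts)] + 1L, cuts[-1])
  }
  labels_m <- matrix(NA_character_, spec$n_rows, spec$n_cols)
  lab <- character(); cls <- character(); geoms <- list()
  add_region <- function(name, class, rows, cols) {
    lab <<- c(lab, name); cls <<- c(cls, class)
    geoms[[length(geoms) + 1L]] <<- list(ring_rect(
      spec$lon0 + (cols[1] - 1) * spec$resolution_deg,
      spec$lat0 + (rows[1] - 1) * spec$resolution_deg,
      spec$lon0 + cols[2] * spec$resolution_deg,
      spec$lat0 + rows[2] * spec$resolution_deg))
    labels_m[rows[1]:rows[2], cols[1]:cols[2]] <<- name
  }
  le <- lat_edges(params$n_coastal)
  for (i in seq_len(params$n_coastal))
    add_region(sprintf("coastal_%d", i), "coastal", le[i, ], c(1L, col_split))
  le <- lat_edges(params$n_offshore)
  for (i in seq_len(params$n_offshore))
    add_region(sprintf("offshore_%d", i), "offshore", le[i, ],
               c(col_split + 1L, spec$n_cols))
  list(map = ecoregion_map(lab, cls, geoms), labels = labels_m)
}

#' Simulate protected areas with known coverage
#'
#' Within each benthic band and ecoregion, ocean cells are drawn in seeded
#' random order until the target fraction of that realm's area is reached
#' (achieved coverage is within one cell-area quantum of the target). The
#' realm target is the band's target times a log-normal multiplier
#' (`coverage_heterogeneity`), truncated to 0.95, reproducing the
#' between-ecoregion spread of real coverage. Selected cells
#' are merged into row-run rectangles, each labelled with an IUCN category
#' drawn from `category_mix` (Ia/Ib rectangles are MPAs; others MPA or OECM
#' at random). A fraction `overlap_rate` of rectangles get an exactly
#' overlapping duplicate with a low-priority category (V/VI/Unknown, OECM) so
#' flattening has real work to do without altering the ground-truth
#' footprint.
#'
#' @param params a `seascape_params`.
#' @param bathy the simulated `bathymetry_grid`.
#' @param eco_labels generator cell-label matrix from [simulate_ecoregions()].
#' @return list with `pas` (a `protected_area_set`), `coverage_truth` (data
#'   frame keyed by ecoregion/band/domain/group with the achieved
#'   `coverage_pct`), and the selection masks `sel_all`, `sel_strict`.
#' @export
simulate_protected_areas <- function(params, bathy, eco_labels) {
  set.seed(params$seed + 1L)
  spec <- bathy$spec
  depth <- seabed_depth_m(bathy)
  areas <- cell_area_grid(spec)
  ocean <- ocean_mask(bathy)
  benthic <- default_benthic_scheme()
  bband <- matrix(classify_benthic(as.vector(depth)), nrow = spec$n_rows)

  sel <- matrix(FALSE, spec$n_rows, spec$n_cols)
  ecos <- sort(unique(eco_labels[ocean]))
  for (band in names(params$protection_targets)) {
    frac <- params$protection_targets[[band]]
    if (frac > 1) stop("unreachable protection target for band ", band)
    if (frac == 0) next
    band_cells <- ocean & !is.na(bband) & bband == band
    if (!any(band_cells))
      stop("protection target for absent band: ", band)
    for (e in ecos) {
      cells <- which(band_cells & eco_labels == e)
      if (!length(cells)) next
      mult <- if (params$coverage_heterogeneity > 0)
        stats::rlnorm(1, 0, params$coverage_heterogeneity) else 1
      frac_e <- min(frac * mult, 0.95)
      target_area <- frac_e * sum(areas[cells])
      ord <- if (length(cells) > 1) sample(cells) else cells
      k <- which(cumsum(areas[ord]) >= target_area - 1e-12)[1]
      if (is.na(k)) next
      sel[ord[seq_len(k)]] <- TRUE
    }
  }

  # merge selected cells into row-run rectangles
  rect <- list()
  for (r in seq_len(spec$n_rows)) {
    cols <- which(sel[r, ])
    if (!length(cols)) next
    breaks <- c(0, which(diff(cols) > 1), length(cols))
    for (b in seq_len(length(breaks) - 1L)) {
      c1 <- cols[breaks[b] + 1L]; c2 <- cols[breaks[b + 1L]]
      rect[[length(rect) + 1L]] <- c(r, c1, c2)
    }
  }
  n_rect <- length(rect)
  cats <- sample(names(params$category_mix), n_rect, replace = TRUE,
                 prob = params$category_mix)
  kinds <- ifelse(cats %in% c("Ia", "Ib"), "MPA",
                  sample(c("MPA", "OECM"), n_rect, replace = TRUE))
  cell_rect <- function(rc) {
    ring_rect(spec$lon0 + (rc[2] - 1) * spec$resolution_deg,
              spec$lat0 + (rc[1] - 1) * spec$resolution_deg,
              spec$lon0 + rc[3] * spec$resolution_deg,
              spec$lat0 + rc[1] * spec$resolution_deg)
  }
  geoms <- lapply(rect, function(rc) list(cell_rect(rc)))
  id <- sprintf("pa_%04d", seq_len(n_rect))
  dup <- which(stats::runif(n_rect) < params$overlap_rate)
  if (length(dup)) {
    id <- c(id, sprintf("pa_dup_%04d", dup))
    cats <- c(cats, sample(c("V", "VI", "Unknown"), length(dup), replace = TRUE))
    kinds <- c(kinds, rep("OECM", length(dup)))
    geoms <- c(geoms, geoms[dup])
  }
  pas <- protected_area_set(id, cats, kinds, geoms, repair = FALSE)

  # strict (Ia/Ib MPA) footprint per cell
  sel_strict <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (i in seq_len(n_rect)) {
    if (cats[i] %in% c("Ia", "Ib") && kinds[i] == "MPA") {
      rc <- rect[[i]]
      sel_strict[rc[1], rc[2]:rc[3]] <- TRUE
    }
  }

  truth <- tally_coverage_truth(sel, sel_strict, depth, eco_labels, bband,
                                areas, ocean)
  list(pas = pas, coverage_truth = truth, sel_all = sel,
       sel_strict = sel_strict)
}

tally_coverage_truth <- function(sel, sel_strict, depth, eco, bband, areas,
                                 ocean) {
  pelagic <- default_pelagic_scheme()
  rows <- list()
  emit <- function(e, band, dom, grp, prot, tot) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ecoregion = e, band = band, domain = dom, group = grp,
      protected_area_km2 = prot, realm_area_km2 = tot,
      coverage_pct = 100 * prot / tot, stringsAsFactors = FALSE)
  }
  for (e in sort(unique(eco[ocean]))) {
    in_e <- ocean & eco == e
    for (band in unique(bband[in_e & !is.na(bband)])) {
      cells <- in_e & !is.na(bband) & bband == band
      for (grp in c("all", "Ia_Ib")) {
        m <- if (grp == "all") sel else sel_strict
        emit(e, band, "benthic", grp, sum(areas[cells & m]), sum(areas[cells]))
      }
    }
    for (i in seq_len(nrow(pelagic$bands))) {
      cells <- in_e & !is.na(depth) & depth > pelagic$bands$shallow_m[i]
      if (!any(cells)) next
      for (grp in c("all", "Ia_Ib")) {
        m <- if (grp == "all") sel else sel_strict
        emit(e, pelagic$bands$name[i], "pelagic", grp,
             sum(areas[cells & m]), sum(areas[cells]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate fishing events with known per-realm effort
#'
#' Events are placed at seeded random cell centers with per-gear sampling
#' weights decaying with the distance between the cell's seabed depth and the
#' gear's preferred depth range (`decay` per km; 0 = bathymetry-blind).
#' Hours are log-normal; after sampling, unspecified-gear hours are rescaled
#' so they carry exactly `unspecified_hours_fraction` of total hours.
#' Per-event effort is tallied into the impacted benthic and pelagic realms
#' by direct enumeration, independent of the pipeline's attribution code.
#'
#' @param params a `seascape_params`.
#' @param bathy the simulated `bathymetry_grid`.
#' @param eco_labels generator cell-label matrix.
#' @param catalog a `gear_catalog` giving each gear's mode.
#' @return list with `events` (data frame) and `effort_truth` (data frame of
#'   impacted-attribution effort hours per ecoregion/band/domain/gear/year).
#' @export
simulate_fishing_events <- function(params, bathy, eco_labels,
                                    catalog = default_gear_catalog()) {
  set.seed(params$seed + 2L)
  spec <- bathy$spec
  depth <- seabed_depth_m(bathy)
  ocean_cells <- which(ocean_mask(bathy) & !is.na(eco_labels))
  d_cells <- depth[ocean_cells]
  lon_c <- cell_center_lons(spec)
  lat_c <- cell_center_lats(spec)
  cell_col <- (ocean_cells - 1L) %/% spec$n_rows + 1L
  cell_row <- (ocean_cells - 1L) %% spec$n_rows + 1L

  niches <- params$gear_niches
  ev <- list()
  vessel_pool <- sprintf("v%05d", seq_len(200))
  for (g in seq_len(nrow(niches))) {
    lo <- niches$pref_min_m[g]; hi <- niches$pref_max_m[g]
    dist_km <- pmax(0, pmax(lo - d_cells, d_cells - hi)) / 1000
    w <- exp(-niches$decay[g] * dist_km)
    n_g <- round(niches$share[g] * params$n_events_per_year)
    if (n_g == 0) next
    for (yr in params$years) {
      pick <- sample(seq_along(ocean_cells), n_g, replace = TRUE, prob = w)
      ev[[length(ev) + 1L]] <- data.frame(
        lon = lon_c[cell_col[pick]], lat = lat_c[cell_row[pick]],
        year = yr, hours = stats::rlnorm(n_g, log(params$hours_median), 1),
        gear = niches$gear[g],
        vessel_id = sample(vessel_pool, n_g, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev)

  mode <- catalog$mode[match(events$gear, catalog$name)]
  mode[is.na(mode)] <- "unspecified"
  f <- params$unspecified_hours_fraction
  u <- sum(events$hours[mode == "unspecified"])
  s <- sum(events$hours[mode != "unspecified"])
  if (u > 0 && f > 0) {
    events$hours[mode == "unspecified"] <-
      events$hours[mode == "unspecified"] * (f * s / ((1 - f) * u))
  }

  # ground-truth impacted-attribution tally, direct per-event enumeration
  bounds_b <- c(0, 30, 60, 150, 300, 1000, 3500, 6000, Inf)
  names_b <- c("euphotic", "upper_mesophotic", "lower_mesophotic",
               "rariphotic", "upper_bathyal", "lower_bathyal", "abyssal",
               "hadal")
  bounds_p <- c(0, 200, 1000, 3500, 6000)
  names_p <- c("epipelagic", "mesopelagic", "bathypelagic", "abyssopelagic",
               "hadopelagic")
  idx <- event_cell_index(events$lon, events$lat, spec)
  d_ev <- depth[idx]
  e_ev <- eco_labels[idx]
  contrib <- list(data.frame(
    ecoregion = e_ev, band = names_b[findInterval(d_ev, bounds_b,
                                                  left.open = TRUE)],
    domain = "benthic", gear = events$gear, year = events$year,
    hours = events$hours, stringsAsFactors = FALSE))
  for (i in seq_along(names_p)) {
    in_col <- d_ev > bounds_p[i]
    if (any(in_col))
      contrib[[length(contrib) + 1L]] <- data.frame(
        ecoregion = e_ev[in_col], band = names_p[i], domain = "pelagic",
        gear = events$gear[in_col], year = events$year[in_col],
        hours = events$hours[in_col], stringsAsFactors = FALSE)
  }
  truth <- stats::aggregate(hours ~ ecoregion + band + domain + gear + year,
                            data = do.call(rbind, contrib), FUN = sum)
  names(truth)[names(truth) == "hours"] <- "effort_hours"
  list(events = events, effort_truth = truth)
}

#' Simulate a full seascape with ground truth
#'
#' Runs all generators under a single seed and also tallies the per-realm
#' areas by direct cell enumeration.
#'
#' @param params a `seascape_params`.
#' @param catalog a `gear_catalog`.
#' @return list of class `seascape`: `params`, `bathy`, `ecoregions`
#'   (`ecoregion_map`), `eco_labels`, `pas`, `events`, `catalog`, and
#'   `truth` (list: `realm_areas`, `coverage`, `effort`).
#' @export
simulate_seascape <- function(params = seascape_params(),
                              catalog = default_gear_catalog()) {
  bathy <- simulate_bathymetry(params)
  eco <- simulate_ecoregions(params, bathy)
  prot <- simulate_protected_areas(params, bathy, eco$labels)
  fish <- simulate_fishing_events(params, bathy, eco$labels, catalog)

  # per-realm areas, direct tally
  spec <- bathy$spec
  depth <- seabed_depth_m(bathy)
  areas <- cell_area_grid(spec)
  ocean <- ocean_mask(bathy) & !is.na(eco$labels)
  bband <- matrix(classify_benthic(as.vector(depth)), nrow = spec$n_rows)
  ra <- list()
  for (e in sort(unique(eco$labels[ocean]))) {
    in_e <- ocean & eco$labels == e
    for (band in sort(unique(bband[in_e & !is.na(bband)])))
      ra[[length(ra) + 1L]] <- data.frame(
        ecoregion = e, band = band, domain = "benthic",
        area_km2 = sum(areas[in_e & !is.na(bband) & bband == band]),
        stringsAsFactors = FALSE)
    psch <- default_pelagic_scheme()
    for (i in seq_len(nrow(psch$bands))) {
      cells <- in_e & !is.na(depth) & depth > psch$bands$shallow_m[i]
      if (any(cells))
        ra[[length(ra) + 1L]] <- data.frame(
          ecoregion = e, band = psch$bands$name[i], domain = "pelagic",
          area_km2 = sum(areas[cells]), stringsAsFactors = FALSE)
    }
  }
  structure(list(
    params = params, bathy = bathy, ecoregions = eco$map,
    eco_labels = eco$labels, pas = prot$pas, events = fish$events,
    catalog = catalog,
    truth = list(realm_areas = do.call(rbind, ra),
                 coverage = prot$coverage_truth,
                 effort = fish$effort_truth,
                 sel_all = prot$sel_all, sel_strict = prot$sel_strict)
  ), class = "seascape")
}

#' Write a seascape fixture directory
#'
#' Emits the same formats the pipeline readers consume: `bathymetry.asc`
#' (ESRI ASCII grid), `ecoregions.geojson`, `protected_areas.geojson`,
#' `fishing_events.csv`, `gear_catalog.csv` and `params.yaml`.
#'
#' @param seascape a [simulate_seascape()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_seascape <- function(seascape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bathymetry(seascape$bathy, file.path(dir, "bathymetry.asc"))
  write_ecoregions(seascape$ecoregions, file.path(dir, "ecoregions.geojson"))
  write_protected_areas(seascape$pas, file.path(dir, "protected_areas.geojson"))
  write_fishing_events(seascape$events, file.path(dir, "fishing_events.csv"))
  utils::write.csv(seascape$catalog, file.path(dir, "gear_catalog.csv"),
                   row.names = FALSE)
  p <- seascape$params
  p$gear_niches <- lapply(seq_len(nrow(p$gear_niches)), function(i)
    as.list(p$gear_niches[i, ]))
  writeLines(yaml::as.yaml(unclass(p)), file.path(dir, "params.yaml"))
  invisible(dir)
}
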