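#' Protected-area sets
#'
#' A collection of possibly-overlapping protected-area polygons, each with an
#' IUCN management category (used as a protection-level proxy) and a kind
#' (MPA or OECM). Categories reported as not applicable / not reported / not
#' assigned are expected to be pre-merged into `"Unknown"`.
#'
#' @param id character vector of unique record ids.
#' @param category IUCN category per record: Ia, Ib, II, III, IV, V, VI or
#'   Unknown.
#' @param kind `"MPA"` or `"OECM"` per record.
#' @param geoms list of geometries (see [geometry]); point-plus-reported-area
#'   records without true boundaries are not representable and must be
#'   excluded upstream.
#' @param repair run geometry repair on ingest (default `TRUE`).
#' @return An object of class `protected_area_set`.
#' @export
protected_area_set <- function(id, category, kind, geoms, repair = TRUE) {
  stopifnot(length(id) == length(category), length(id) == length(kind),
            length(id) == length(geoms))
  if (anyDuplicated(id)) stop("record ids must be unique")
  bad <- setdiff(unique(category), iucn_categories())
  if (length(bad)) stop("unknown IUCN categories: ", paste(bad, collapse = ", "))
  if (!all(kind %in% c("MPA", "OECM"))) stop("kind must be MPA or OECM")
  if (repair) geoms <- lapply(geoms, repair_geom)
  structure(list(id = as.character(id), category = as.character(category),
                 kind = as.character(kind), geoms = geoms),
            class = "protected_area_set")
}

#' @rdname protected_area_set
#' @export
iucn_categories <- function() {
  c("Ia", "Ib", "II", "III", "IV", "V", "VI", "Unknown")
}

#' Default protection priority order
#'
#' IUCN categories ordered from the most exclusive biodiversity protection
#' (Ia) to integrated human use (VI), with Unknown last. Where overlapping
#' designations compete, the earlier category in this order wins.
#'
#' @return character vector, highest protection first.
#' @export
default_priority_order <- function() iucn_categories()

#' @export
length.protected_area_set <- function(x) length(x$id)

#' @export
print.protected_area_set <- function(x, ...) {
  cat(sprintf("<protected_area_set: %d records (%s)>\n", length(x$id),
              paste(names(table(x$category)), table(x$category),
                    sep = ":", collapse = " ")))
  invisible(x)
}

subset_pa <- function(pas, keep) {
  protected_area_set(pas$id[keep], pas$category[keep], pas$kind[keep],
                     pas$geoms[keep], repair = FALSE)
}

#' Read / write protected areas as GeoJSON
#'
#' Features carry `id`, `category` and `kind` properties; WDPA-style column
#' names can be supplied through `mapping` (e.g.
#' `c(id = "WDPAID", category = "IUCN_CAT")`).
#'
#' @param path GeoJSON file path.
#' @param mapping named character vector renaming source properties to
#'   `id`/`category`/`kind`.
#' @export
read_protected_areas <- function(path, mapping = NULL) {
  f <- read_geojson_features(path)
  get <- function(p, key) {
    src <- if (!is.null(mapping) && key %in% names(mapping)) mapping[[key]] else key
    v <- p[[src]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  cat_raw <- vapply(f$properties, get, "", "category")
  cat_norm <- ifelse(cat_raw %in% c(NA, "Not Applicable", "Not Reported",
                                    "Not Assigned"), "Unknown", cat_raw)
  protected_area_set(
    id = vapply(f$properties, get, "", "id"),
    category = cat_norm,
    kind = vapply(f$properties, get, "", "kind"),
    geoms = f$geoms
  )
}

#' @rdname read_protected_areas
#' @param pas a `protected_area_set`.
#' @export
write_protected_areas <- function(pas, path) {
  props <- data.frame(id = pas$id, category = pas$category, kind = pas$kind,
                      stringsAsFactors = FALSE)
  write_geojson_features(pas$geoms, props, path)
}

#' Flatten overlapping protected areas to the highest protection level
#'
#' Overlapping designations are resolved so that every covered point is
#' attributed to the highest-priority category among its covering records:
#' polygons are merged into one layer per category, and every
#' higher-priority layer is subtracted in turn from each category's merged
#' layer. The output holds one record per
#' surviving category, with pairwise-disjoint geometries whose union equals
#' the union of the inputs.
#'
#' @param pas a `protected_area_set`.
#' @param order priority order (highest protection first); must cover every
#'   category present.
#' @param simplify_tol optional vertex-snapping tolerance in degrees applied
#'   before flattening (mirrors upstream layer simplification); `NULL` skips.
#' @return a `protected_area_set` with one disjoint record per category.
#' @export
flatten_by_priority <- function(pas, order = default_priority_order(),
                                simplify_tol = NULL) {
  missing_cat <- setdiff(unique(pas$category), order)
  if (length(missing_cat))
    stop("priority order lacks categories: ", paste(missing_cat, collapse = ", "))
  geoms <- pas$geoms
  if (!is.null(simplify_tol))
    geoms <- lapply(geoms, function(g)
      lapply(g, function(r) list(x = round(r$x / simplify_tol) * simplify_tol,
                                 y = round(r$y / simplify_tol) * simplify_tol)))
  layers <- list()
  for (cat in order) {
    idx <- which(pas$category == cat)
    if (!length(idx)) next
    layers[[cat]] <- Reduce(function(a, b) clip_geoms(a, b, "union"),
                            geoms[idx])
  }
  out_cat <- character()
  out_geom <- list()
  for (i in seq_along(layers)) {
    residual <- layers[[i]]
    for (j in seq_len(i - 1L)) {
      if (!length(residual)) break
      residual <- clip_geoms(residual, layers[[j]], "minus")
    }
    if (length(residual)) {
      out_cat <- c(out_cat, names(layers)[i])
      out_geom <- c(out_geom, list(residual))
    }
  }
  protected_area_set(
    id = paste0("flat_", out_cat), category = out_cat,
    kind = rep("MPA", length(out_cat)), geoms = out_geom, repair = FALSE
  )
}

#' Rasterize a flattened protection layer
#'
#' Each cell is labelled with the category of the (disjoint) flattened
#' polygon containing its center, `NA` where unprotected. Cell membership is
#' a center test: partial coverage resolves to whether the center is covered,
#' so areas are exact to one cell-area quantum. If a center lies exactly on a
#' shared boundary, the higher-priority category wins.
#'
#' @param flat a flattened (disjoint) `protected_area_set`.
#' @param spec a `grid_spec`.
#' @param order priority order used for boundary ties.
#' @return character matrix of categories (`NA` = unprotected).
#' @export
rasterize_protection <- function(flat, spec, order = default_priority_order()) {
  lats <- cell_center_lats(spec)
  lons <- cell_center_lons(spec)
  xs <- rep(lons, each = spec$n_rows)
  ys <- rep(lats, times = spec$n_cols)
  out <- rep(NA_character_, length(xs))
  # lowest priority first so higher priority overwrites on shared boundaries
  for (cat in rev(order)) {
    i <- which(flat$category == cat)
    if (!length(i)) next
    g <- flat$geoms[[i]]
    bb <- geom_bbox(g)
    cand <- which(xs >= bb["xmin"] & xs <= bb["xmax"] &
                    ys >= bb["ymin"] & ys <= bb["ymax"])
    if (!length(cand)) next
    hit <- point_in_geom(xs[cand], ys[cand], g)
    out[cand[hit]] <- cat
  }
  matrix(out, nrow = spec$n_rows, ncol = spec$n_cols)
}

#' Protection coverage per 3D realm
#'
#' For each benthic band, the protected area is the summed area of protected
#' ocean cells whose seabed depth falls in the band; for each pelagic band,
#' of protected cells whose seabed depth exceeds the band's shallow bound
#' (surface-to-seabed column rule). Coverage is
#' `protected area / realm area * 100`.
#'
#' Category groups reported: `"all"` (any category, MPA + OECM),
#' `"Ia_Ib"` (strict-protection grid, when supplied), and one group per
#' individual category present.
#'
#' @param prot_grid category-per-cell matrix from [rasterize_protection()]
#'   for the full flattened set.
#' @param bathy a `bathymetry_grid`.
#' @param ecoregions an `ecoregion_map` or pre-rasterized label matrix.
#' @param benthic,pelagic depth schemes.
#' @param strict_grid optional category matrix for the Ia/Ib-MPA-only layer.
#' @param realm_areas optional precomputed [enumerate_realms3d()] table.
#' @param const `geodesy_constants`.
#' @param per_category also emit one group per individual category.
#' @return data frame (CoverageTable) with columns `ecoregion`, `band`,
#'   `domain`, `group`, `protected_area_km2`, `realm_area_km2`,
#'   `coverage_pct`.
#' @export
coverage_by_realm <- function(prot_grid, bathy, ecoregions,
                              benthic = default_benthic_scheme(),
                              pelagic = default_pelagic_scheme(),
                              strict_grid = NULL, realm_areas = NULL,
                              const = geodesy_constants(),
                              per_category = FALSE) {
  spec <- bathy$spec
  eco <- if (inherits(ecoregions, "ecoregion_map"))
    rasterize_ecoregions(ecoregions, spec) else ecoregions
  if (is.null(realm_areas))
    realm_areas <- enumerate_realms3d(bathy, eco, benthic, pelagic, const)
  depth <- seabed_depth_m(bathy)
  areas <- cell_area_grid(spec, const)
  ocean <- ocean_mask(bathy) & !is.na(eco)

  groups <- list(all = ocean & !is.na(prot_grid))
  if (!is.null(strict_grid)) groups$Ia_Ib <- ocean & !is.na(strict_grid)
  if (per_category)
    for (cat in intersect(iucn_categories(), unique(as.vector(prot_grid))))
      groups[[cat]] <- ocean & !is.na(prot_grid) & prot_grid == cat

  bband <- matrix(classify_benthic(as.vector(depth), benthic),
                  nrow = spec$n_rows)
  out <- NULL
  for (gname in names(groups)) {
    mask <- groups[[gname]]
    prot <- realm_protected_areas(mask, depth, eco, bband, pelagic, areas)
    tab <- merge(realm_areas, prot, all.x = TRUE,
                 by = c("ecoregion", "band", "domain"))
    tab$protected_area_km2[is.na(tab$protected_area_km2)] <- 0
    tab$group <- gname
    out <- rbind(out, tab)
  }
  out$coverage_pct <- 100 * out$protected_area_km2 / out$area_km2
  out$coverage_pct <- pmin(pmax(out$coverage_pct, 0), 100)
  names(out)[names(out) == "area_km2"] <- "realm_area_km2"
  out <- order_realms(out[, c("ecoregion", "band", "domain", "group",
                              "protected_area_km2", "realm_area_km2",
                              "coverage_pct")], benthic, pelagic)
  out
}

realm_protected_areas <- function(mask, depth, eco, bband, pelagic, areas) {
  zone_b <- ifelse(mask, paste(eco, bband, sep = "\r"), NA)
  prot_b <- zonal_sum(as.numeric(mask), zone_b, areas)
  out <- split_zone_table(prot_b, "benthic")
  for (i in seq_len(nrow(pelagic$bands))) {
    sel <- mask & !is.na(depth) & depth > pelagic$bands$shallow_m[i]
    tot <- zonal_sum(as.numeric(sel), ifelse(sel, eco, NA), areas)
    if (length(tot))
      out <- rbind(out, data.frame(
        ecoregion = names(tot), band = pelagic$bands$name[i],
        domain = "pelagic", area_km2 = as.numeric(tot),
        stringsAsFactors = FALSE))
  }
  names(out)[names(out) == "area_km2"] <- "protected_area_km2"
  out
}

#' One-call protection assessment
#'
#' Flattens a raw protected-area set (full set, and the strict Ia/Ib MPA
#' subset), rasterizes both, and computes the coverage table.
#'
#' @inheritParams coverage_by_realm
#' @param pas a raw (possibly overlapping) `protected_area_set`.
#' @param order priority order for flattening.
#' @param simplify_tol see [flatten_by_priority()].
#' @return see [coverage_by_realm()].
#' @export
protection_coverage <- function(pas, bathy, ecoregions,
                                benthic = default_benthic_scheme(),
                                pelagic = default_pelagic_scheme(),
                                order = default_priority_order(),
                                simplify_tol = NULL,
                                realm_areas = NULL,
                                const = geodesy_constants(),
                                per_category = FALSE) {
  spec <- bathy$spec
  flat_all <- flatten_by_priority(pas, order, simplify_tol)
  grid_all <- rasterize_protection(flat_all, spec, order)
  strict_idx <- pas$kind == "MPA" & pas$category %in% c("Ia", "Ib")
  grid_strict <- if (any(strict_idx)) {
    flat_s <- flatten_by_priority(subset_pa(pas, strict_idx), order, simplify_tol)
    rasterize_protection(flat_s, spec, order)
  } else {
    matrix(NA_character_, spec$n_rows, spec$n_cols)
  }
  coverage_by_realm(grid_all, bathy, ecoregions, benthic, pelagic,
                    strict_grid = grid_strict, realm_areas = realm_areas,
                    const = const, per_category = per_category)
}
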