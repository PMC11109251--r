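# Independent brute-force oracles used across tests. These re-derive results
# by direct enumeration and must stay independent of the package's vectorized
# code paths.

# Benthic band of one depth by linear scan over the band table.
oracle_benthic_band <- function(depth, scheme) {
  for (i in seq_len(nrow(scheme$bands))) {
    if (depth > scheme$bands$shallow_m[i] && depth <= scheme$bands$deep_m[i])
      return(scheme$bands$name[i])
  }
  NA_character_
}

# Per-(ecoregion, band, domain) areas by an explicit cell-by-cell loop.
oracle_realm_areas <- function(bathy, eco_labels, benthic, pelagic) {
  spec <- bathy$spec
  acc <- list()
  add <- function(key, a) acc[[key]] <<- (acc[[key]] %||% 0) + a
  for (r in seq_len(spec$n_rows)) {
    lat <- spec$lat0 + (r - 0.5) * spec$resolution_deg
    a <- cell_area_km2(lat, spec)
    for (cc in seq_len(spec$n_cols)) {
      el <- bathy$elevation[r, cc]
      if (is.na(el) || el >= 0 || is.na(eco_labels[r, cc])) next
      d <- -el
      b <- oracle_benthic_band(d, benthic)
      add(paste(eco_labels[r, cc], b, "benthic", sep = "|"), a)
      for (i in seq_len(nrow(pelagic$bands)))
        if (pelagic$bands$shallow_m[i] < d)
          add(paste(eco_labels[r, cc], pelagic$bands$name[i], "pelagic",
                    sep = "|"), a)
    }
  }
  if (!length(acc)) return(data.frame())
  parts <- strsplit(names(acc), "|", fixed = TRUE)
  df <- data.frame(
    ecoregion = vapply(parts, `[[`, "", 1),
    band = vapply(parts, `[[`, "", 2),
    domain = vapply(parts, `[[`, "", 3),
    area_km2 = unlist(acc, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  df[order(df$ecoregion, df$domain, df$band), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Max-priority category at sample points, directly from the raw records.
oracle_point_category <- function(pas, order, px, py) {
  out <- rep(NA_character_, length(px))
  rank <- match(pas$category, order)
  for (i in order(rank)) {
    hit <- point_in_geom(px, py, pas$geoms[[i]])
    out[is.na(out) & hit] <- pas$category[i]
  }
  out
}

# Random overlapping protected-area set for flattening stress tests.
random_pa_set <- function(n = 10, seed = 1) {
  set.seed(seed)
  geoms <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- runif(1, 0, 8); cy <- runif(1, 0, 8)
    w <- runif(1, 0.5, 3); h <- runif(1, 0.5, 3)
    geoms[[i]] <- if (runif(1) < 0.5)
      list(ring_rect(cx, cy, cx + w, cy + h))
    else
      list(ring_ellipse(cx, cy, w / 2, h / 2, n_vertices = 24))
  }
  protected_area_set(
    id = sprintf("r%03d", seq_len(n)),
    category = sample(iucn_categories(), n, replace = TRUE),
    kind = sample(c("MPA", "OECM"), n, replace = TRUE),
    geoms = geoms, repair = FALSE
  )
}

# Tiny flat-bottom seascape: uniform depth, one ecoregion, optional mask.
flat_seascape <- function(depth_m = 3000, n = 10, resolution = 0.1) {
  spec <- grid_spec(resolution, 0, 0, n, n)
  bathy <- bathymetry_grid(spec, matrix(-depth_m, n, n))
  eco <- matrix("eco_a", n, n)
  list(spec = spec, bathy = bathy, eco = eco)
}
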