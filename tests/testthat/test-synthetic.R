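test_that("bathymetry generation is deterministic and spans all benthic bands", {
  p <- seascape_params(seed = 5)
  b1 <- simulate_bathymetry(p)
  b2 <- simulate_bathymetry(p)
  expect_identical(b1$elevation, b2$elevation)
  bands <- classify_benthic(as.vector(seabed_depth_m(b1)))
  expect_setequal(unique(stats::na.omit(bands)),
                  default_benthic_scheme()$bands$name)
  expect_true(any(b1$elevation >= 0))  # land margin present
})

test_that("zero noise gives a strictly monotone shelf profile", {
  p <- seascape_params(seed = 5, noise_amp = 0)
  b <- simulate_bathymetry(p)
  d <- seabed_depth_m(b)
  ocean_cols <- (p$land_cols + 1):p$n_cols
  for (r in c(1, 50, 100))
    expect_true(all(diff(d[r, ocean_cols]) > 0))
})

test_that("ecoregions tile the ocean and contain the shelf", {
  p <- seascape_params(seed = 9)
  bathy <- simulate_bathymetry(p)
  eco <- simulate_ecoregions(p, bathy)
  expect_equal(length(eco$map$label), p$n_coastal + p$n_offshore)
  ocean <- ocean_mask(bathy)
  expect_false(anyNA(eco$labels[ocean]))  # every ocean cell assigned
  # coastal polygons contain all cells shallower than 200 m
  d <- seabed_depth_m(bathy)
  shallow <- !is.na(d) & d < 200
  coastal_labels <- eco$map$label[eco$map$class == "coastal"]
  expect_true(all(eco$labels[shallow] %in% coastal_labels))
  # generator labels agree with polygon rasterization
  expect_equal(rasterize_ecoregions(eco$map, bathy$spec), eco$labels)
})

test_that("protected-area generation hits its per-realm targets within one cell", {
  p <- seascape_params(seed = 12, coverage_heterogeneity = 0,
                       overlap_rate = 0)
  bathy <- simulate_bathymetry(p)
  eco <- simulate_ecoregions(p, bathy)
  prot <- simulate_protected_areas(p, bathy, eco$labels)
  areas <- cell_area_grid(bathy$spec)
  quantum <- max(areas)
  tr <- prot$coverage_truth
  ben_all <- tr[tr$domain == "benthic" & tr$group == "all", ]
  for (i in seq_len(nrow(ben_all))) {
    target <- p$protection_targets[[ben_all$band[i]]]
    achieved_km2 <- ben_all$protected_area_km2[i]
    expect_lte(abs(achieved_km2 - target * ben_all$realm_area_km2[i]), quantum)
  }
})

test_that("flattening is the identity on non-overlapping generated sets", {
  p <- seascape_params(seed = 4, overlap_rate = 0)
  bathy <- simulate_bathymetry(p)
  eco <- simulate_ecoregions(p, bathy)
  prot <- simulate_protected_areas(p, bathy, eco$labels)
  flat <- flatten_by_priority(prot$pas)
  a_in <- sum(vapply(prot$pas$geoms, geom_area, 0))
  a_out <- sum(vapply(flat$geoms, geom_area, 0))
  expect_equal(a_out, a_in, tolerance = 1e-9)
})

test_that("generated coverage is recovered by the protection pipeline", {
  sim <- simulate_seascape(seascape_params(seed = 3))
  cov <- protection_coverage(sim$pas, sim$bathy, sim$eco_labels,
                             realm_areas = enumerate_realms3d(
                               sim$bathy, sim$eco_labels))
  m <- merge(cov, sim$truth$coverage,
             by = c("ecoregion", "band", "domain", "group"))
  expect_equal(nrow(m), nrow(cov))
  expect_equal(m$coverage_pct.x, m$coverage_pct.y, tolerance = 1e-9)
})

test_that("unspecified gears carry exactly the configured hour fraction", {
  sim <- simulate_seascape(seascape_params(seed = 10))
  rep <- gear_disaggregation_report(sim$events, sim$catalog)
  expect_equal(rep[["unspecified"]], 0.45, tolerance = 1e-12)
  expect_equal(sum(rep), 1)
})

test_that("bathymetry-blind gear spreads effort evenly over equal-area realms", {
  niches <- data.frame(gear = "fishing", share = 1, pref_min_m = 0,
                       pref_max_m = 8000, decay = 0, stringsAsFactors = FALSE)
  p <- seascape_params(seed = 20, n_events_per_year = 4000L, years = 2019L,
                       gear_niches = niches, noise_amp = 0,
                       unspecified_hours_fraction = 0)
  sim <- simulate_seascape(p)
  d <- seabed_depth_m(sim$bathy)
  ocean_n <- sum(!is.na(d))
  # events per cell-count share ~ uniform: compare benthic effort share with
  # the band's share of ocean cells
  bands <- classify_benthic(as.vector(d))
  eff <- aggregate(effort_hours ~ band,
                   data = sim$truth$effort[sim$truth$effort$domain == "benthic", ],
                   FUN = sum)
  eff$share <- eff$effort_hours / sum(eff$effort_hours)
  cell_share <- table(bands) / ocean_n
  for (i in seq_len(nrow(eff)))
    expect_lt(abs(eff$share[i] - cell_share[[eff$band[i]]]), 0.05)
})

test_that("whole seascapes are reproducible and file round-trips are lossless", {
  p <- seascape_params(seed = 17, n_events_per_year = 100L)
  s1 <- simulate_seascape(p)
  s2 <- simulate_seascape(p)
  expect_identical(s1$bathy$elevation, s2$bathy$elevation)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$truth$coverage, s2$truth$coverage)

  dir <- withr::local_tempdir()
  write_seascape(s1, dir)
  b <- read_bathymetry(file.path(dir, "bathymetry.asc"))
  expect_equal(b$elevation, s1$bathy$elevation)
  ev <- read_fishing_events(file.path(dir, "fishing_events.csv"))
  expect_equal(ev$hours, s1$events$hours, tolerance = 1e-12)
  pas <- read_protected_areas(file.path(dir, "protected_areas.geojson"))
  expect_equal(pas$category, s1$pas$category)
  cat2 <- read_gear_catalog(file.path(dir, "gear_catalog.csv"))
  expect_equal(cat2$name, s1$catalog$name)
})

test_that("unreachable protection targets raise", {
  p <- seascape_params(seed = 1)
  p$protection_targets <- c(euphotic = 1.5)
  bathy <- simulate_bathymetry(p)
  eco <- simulate_ecoregions(p, bathy)
  expect_error(simulate_protected_areas(p, bathy, eco$labels), "unreachable")
})
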