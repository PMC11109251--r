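square <- function(x0, y0, side = 1) list(ring_rect(x0, y0, x0 + side, y0 + side))

test_that("flattening keeps only the highest protection level", {
  pas <- protected_area_set(c("a", "b"), c("VI", "Ia"), c("MPA", "MPA"),
                            list(square(0, 0), square(0, 0)))
  flat <- flatten_by_priority(pas)
  expect_equal(flat$category, "Ia")
  expect_equal(geom_area(flat$geoms[[1]]), 1, tolerance = 1e-9)
})

test_that("disjoint polygons pass through flattening unchanged", {
  pas <- protected_area_set(c("a", "b"), c("II", "V"), c("MPA", "OECM"),
                            list(square(0, 0), square(5, 5)))
  flat <- flatten_by_priority(pas)
  expect_setequal(flat$category, c("II", "V"))
  areas <- vapply(flat$geoms, geom_area, 0)
  expect_equal(sort(areas), c(1, 1), tolerance = 1e-9)
})

test_that("partial overlap leaves the lower category a residual", {
  pas <- protected_area_set(c("a", "b"), c("Ib", "II"), c("MPA", "MPA"),
                            list(square(0, 0), square(0.5, 0)))
  flat <- flatten_by_priority(pas)
  a_ib <- geom_area(flat$geoms[[which(flat$category == "Ib")]])
  a_ii <- geom_area(flat$geoms[[which(flat$category == "II")]])
  expect_equal(a_ib, 1.0, tolerance = 1e-9)
  expect_equal(a_ii, 0.5, tolerance = 1e-9)
  # dense point-sampling oracle: each sample belongs to its max-priority cover
  set.seed(1)
  px <- runif(4000, -0.2, 1.8); py <- runif(4000, -0.2, 1.2)
  want <- oracle_point_category(pas, default_priority_order(), px, py)
  got <- oracle_point_category(flat, default_priority_order(), px, py)
  expect_gte(mean((is.na(want) & is.na(got)) |
                    (!is.na(want) & !is.na(got) & want == got)), 0.999)
})

test_that("flattening conserves union area, is idempotent and order-invariant", {
  for (seed in 1:5) {
    pas <- random_pa_set(n = 8, seed = seed)
    flat <- flatten_by_priority(pas)
    union_all <- Reduce(function(a, b)
      polyclip::polyclip(a, b, "union", eps = 1e-12, x0 = 0, y0 = 0),
      pas$geoms)
    a_union <- geom_area(union_all)
    a_flat <- sum(vapply(flat$geoms, geom_area, 0))
    expect_equal(a_flat, a_union, tolerance = 1e-9)

    flat2 <- flatten_by_priority(flat)
    expect_equal(sort(flat2$category), sort(flat$category))
    expect_equal(sum(vapply(flat2$geoms, geom_area, 0)), a_flat,
                 tolerance = 1e-9)

    perm <- sample(length(pas$id))
    flat_p <- flatten_by_priority(protected_area_set(
      pas$id[perm], pas$category[perm], pas$kind[perm], pas$geoms[perm],
      repair = FALSE))
    expect_equal(sort(flat_p$category), sort(flat$category))
    for (cat in flat$category) {
      i <- which(flat$category == cat); j <- which(flat_p$category == cat)
      expect_equal(geom_area(flat_p$geoms[[j]]), geom_area(flat$geoms[[i]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("flattening requires a complete priority order", {
  pas <- protected_area_set("a", "VI", "MPA", list(square(0, 0)))
  expect_error(flatten_by_priority(pas, order = c("Ia", "Ib")), "lacks")
})

test_that("rasterization matches a point-in-polygon loop at cell centers", {
  set.seed(21)
  spec <- grid_spec(0.1, 0, 0, 50, 50)
  pas <- protected_area_set(
    sprintf("p%d", 1:6),
    c("Ia", "III", "VI", "II", "Unknown", "V"),
    rep("MPA", 6),
    lapply(1:6, function(i) {
      x0 <- runif(1, 0, 4); y0 <- runif(1, 0, 4)
      square(x0, y0, side = runif(1, 0.5, 1.5))
    }), repair = FALSE)
  flat <- flatten_by_priority(pas)
  grid <- rasterize_protection(flat, spec)
  lats <- cell_center_lats(spec); lons <- cell_center_lons(spec)
  for (r in seq(1, 50, by = 3)) for (cc in seq(1, 50, by = 3)) {
    want <- oracle_point_category(pas, default_priority_order(),
                                  lons[cc], lats[r])
    expect_identical(grid[r, cc], want)
  }
  # whole-grid polygon labels every cell; empty set labels none
  all_poly <- protected_area_set("w", "IV", "MPA", list(square(-1, -1, 7)))
  expect_true(all(rasterize_protection(flatten_by_priority(all_poly),
                                       spec) == "IV"))
})

test_that("coverage follows the protected-share formula per realm", {
  fs <- flat_seascape(depth_m = 3000, n = 10)
  a <- cell_area_grid(fs$spec)
  # protect the 10 cells of the first row (any category): coverage is that
  # row's share of total area (10% up to the tiny latitude area gradient)
  prot <- matrix(NA_character_, 10, 10); prot[1, ] <- "VI"
  cov <- coverage_by_realm(prot, fs$bathy, fs$eco,
                           strict_grid = matrix(NA_character_, 10, 10))
  want_pct <- 100 * sum(a[1, ]) / sum(a)
  expect_equal(want_pct, 10, tolerance = 1e-3)
  ben_all <- cov[cov$domain == "benthic" & cov$group == "all", ]
  expect_equal(ben_all$band, "lower_bathyal")
  expect_equal(ben_all$coverage_pct, want_pct, tolerance = 1e-9)
  ben_s <- cov[cov$domain == "benthic" & cov$group == "Ia_Ib", ]
  expect_equal(ben_s$coverage_pct, 0)
  # pelagic column realms inherit the same protected cells
  pel_all <- cov[cov$domain == "pelagic" & cov$group == "all", ]
  expect_equal(pel_all$coverage_pct, rep(want_pct, 3), tolerance = 1e-9)
})

test_that("coverage is monotone under added protection and strict <= all", {
  sim <- simulate_seascape(seascape_params(seed = 13, n_rows = 40L,
                                           n_cols = 40L,
                                           n_events_per_year = 10L))
  ra <- enumerate_realms3d(sim$bathy, sim$eco_labels)
  cov1 <- protection_coverage(sim$pas, sim$bathy, sim$eco_labels,
                              realm_areas = ra)
  expect_true(all(cov1$coverage_pct >= 0 & cov1$coverage_pct <= 100))
  wide <- merge(cov1[cov1$group == "all", c("ecoregion", "band", "domain",
                                            "coverage_pct")],
                cov1[cov1$group == "Ia_Ib", c("ecoregion", "band", "domain",
                                              "coverage_pct")],
                by = c("ecoregion", "band", "domain"))
  expect_true(all(wide$coverage_pct.y <= wide$coverage_pct.x + 1e-12))

  # add one more protected polygon: no realm's coverage decreases
  spec <- sim$bathy$spec
  extra <- protected_area_set(
    c(sim$pas$id, "extra"), c(sim$pas$category, "Ia"),
    c(sim$pas$kind, "MPA"),
    c(sim$pas$geoms, list(list(ring_rect(
      spec$lon0 + 0.5, spec$lat0 + 0.5,
      spec$lon0 + 1.2, spec$lat0 + 1.2)))), repair = FALSE)
  cov2 <- protection_coverage(extra, sim$bathy, sim$eco_labels,
                              realm_areas = ra)
  m <- merge(cov1, cov2, by = c("ecoregion", "band", "domain", "group"))
  expect_true(all(m$coverage_pct.y >= m$coverage_pct.x - 1e-12))
})

test_that("protected areas round-trip through GeoJSON with category normalization", {
  pas <- protected_area_set(c("a", "b"), c("Ia", "Unknown"), c("MPA", "OECM"),
                            list(square(0, 0), square(2, 2)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_protected_areas(pas, path)
  pas2 <- read_protected_areas(path)
  expect_equal(pas2$id, pas$id)
  expect_equal(pas2$category, pas$category)
  expect_equal(pas2$kind, pas$kind)
  expect_equal(geom_area(pas2$geoms[[1]]), 1, tolerance = 1e-9)
})
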