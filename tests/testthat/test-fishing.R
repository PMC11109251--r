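events_df <- function(lon, lat, year = 2019, hours = 1, gear = "bottom_trawl",
                      vessel_id = "v1") {
  data.frame(lon = lon, lat = lat, year = year, hours = hours, gear = gear,
             vessel_id = vessel_id, stringsAsFactors = FALSE)
}

test_that("impacted realms follow the surface-to-seabed column", {
  fs <- flat_seascape(depth_m = 3000, n = 10)
  ev <- events_df(0.05, 0.05)
  imp <- impacted_realms(ev, fs$bathy)
  expect_equal(imp$benthic, "lower_bathyal")
  expect_equal(imp$pelagic[[1]], c("epipelagic", "mesopelagic", "bathypelagic"))

  fs2 <- flat_seascape(depth_m = 100)
  imp2 <- impacted_realms(events_df(0.05, 0.05), fs2$bathy)
  expect_equal(imp2$benthic, "lower_mesophotic")
  expect_equal(imp2$pelagic[[1]], "epipelagic")

  fs3 <- flat_seascape(depth_m = 7000)
  imp3 <- impacted_realms(events_df(0.05, 0.05), fs3$bathy)
  expect_equal(imp3$benthic, "hadal")
  expect_equal(length(imp3$pelagic[[1]]), 5)
})

test_that("land and off-grid events are excluded and counted", {
  spec <- grid_spec(0.1, 0, 0, 4, 4)
  elev <- matrix(-500, 4, 4); elev[1, 1] <- 5
  bathy <- bathymetry_grid(spec, elev)
  ev <- events_df(c(0.05, 0.15, 99), c(0.05, 0.15, 0.05))
  imp <- impacted_realms(ev, bathy)
  expect_equal(imp$n_excluded_land, 2)
  expect_true(is.na(imp$benthic[1]))
  expect_equal(imp$benthic[2], "upper_bathyal")
})

test_that("targeted realms respect gear depth ranges capped by bathymetry", {
  catalog <- default_gear_catalog()
  mid <- catalog[catalog$name == "midwater_trawl", ]  # pelagic 30-350 m
  expect_equal(targeted_realms(400, mid), c("epipelagic", "mesopelagic"))
  expect_equal(targeted_realms(150, mid), "epipelagic")
  expect_equal(targeted_realms(3000, catalog[catalog$name == "bottom_trawl", ]),
               "lower_bathyal")
  expect_equal(targeted_realms(500, "trawlers", catalog), "unspecified")
  expect_equal(targeted_realms(500, "no_such_gear", catalog), "unspecified")
  # range touching a band only at its boundary point does not select it
  g200 <- gear_catalog("g", "pelagic", 0, 200)[1, ]
  expect_equal(targeted_realms(5000, g200), "epipelagic")
  # catalog inconsistency: gear entirely below the seabed
  deep <- gear_catalog("dg", "pelagic", 500, 900)[1, ]
  expect_warning(out <- targeted_realms(300, deep), "does not overlap")
  expect_equal(out, "mesopelagic")  # deepest band of the 300 m column
})

test_that("targeted pelagic bands are a subset of impacted bands", {
  sim <- simulate_seascape(seascape_params(seed = 8, n_events_per_year = 200L))
  catalog <- sim$catalog
  imp <- impacted_realms(sim$events, sim$bathy)
  pel_gears <- catalog$name[catalog$mode == "pelagic"]
  idx <- which(sim$events$gear %in% pel_gears & !is.na(imp$benthic))
  for (j in idx[seq_len(min(200, length(idx)))]) {
    tg <- suppressWarnings(
      targeted_realms(imp$seabed_depth_m[j], sim$events$gear[j], catalog))
    expect_true(all(tg %in% imp$pelagic[[j]]))
  }
})

test_that("pressure is effort divided by realm area", {
  fs <- flat_seascape(depth_m = 3000, n = 10)
  catalog <- default_gear_catalog()
  ev <- events_df(0.05, 0.05, hours = 10)
  pt <- pressure_by_realm(ev, fs$bathy, fs$eco, catalog)
  ben <- pt[pt$domain == "benthic", ]
  expect_equal(ben$effort_hours, 10)
  expect_equal(ben$pressure_hr_per_km2, 10 / ben$realm_area_km2)
  # empty event table gives an empty table
  pt0 <- pressure_by_realm(ev[0, ], fs$bathy, fs$eco, catalog)
  expect_equal(nrow(pt0), 0)
})

test_that("per-realm effort equals a per-event loop oracle", {
  sim <- simulate_seascape(seascape_params(seed = 14, n_rows = 30L,
                                           n_cols = 30L,
                                           n_events_per_year = 350L))
  pt <- pressure_by_realm(sim$events, sim$bathy, sim$eco_labels, sim$catalog)
  # brute-force loop oracle
  depth <- seabed_depth_m(sim$bathy)
  spec <- sim$bathy$spec
  ben <- default_benthic_scheme(); pel <- default_pelagic_scheme()
  acc <- new.env()
  for (j in seq_len(nrow(sim$events))) {
    cc <- floor((sim$events$lon[j] - spec$lon0) / spec$resolution_deg) + 1
    rr <- floor((sim$events$lat[j] - spec$lat0) / spec$resolution_deg) + 1
    d <- depth[rr, cc]
    if (is.na(d)) next
    e <- sim$eco_labels[rr, cc]
    keys <- paste(e, oracle_benthic_band(d, ben), "benthic",
                  sim$events$gear[j], sim$events$year[j], sep = "|")
    for (i in seq_len(nrow(pel$bands)))
      if (pel$bands$shallow_m[i] < d)
        keys <- c(keys, paste(e, pel$bands$name[i], "pelagic",
                              sim$events$gear[j], sim$events$year[j],
                              sep = "|"))
    for (k in keys)
      assign(k, (if (exists(k, acc)) get(k, acc) else 0) + sim$events$hours[j],
             envir = acc)
  }
  got_keys <- paste(pt$ecoregion, pt$band, pt$domain, pt$gear, pt$year,
                    sep = "|")
  expect_setequal(got_keys, ls(acc))
  for (i in seq_len(nrow(pt)))
    expect_equal(pt$effort_hours[i], get(got_keys[i], acc), tolerance = 1e-12)
})

test_that("hours are conserved under impacted attribution and order-invariant", {
  sim <- simulate_seascape(seascape_params(seed = 15, n_events_per_year = 400L))
  pt <- pressure_by_realm(sim$events, sim$bathy, sim$eco_labels, sim$catalog)
  ben_total <- sum(pt$effort_hours[pt$domain == "benthic"])
  expect_equal(ben_total, sum(sim$events$hours), tolerance = 1e-12)
  expect_equal(attr(pt, "n_excluded_land"), 0)

  set.seed(99)
  shuf <- sim$events[sample(nrow(sim$events)), ]
  pt2 <- pressure_by_realm(shuf, sim$bathy, sim$eco_labels, sim$catalog)
  expect_equal(pt2$effort_hours, pt$effort_hours, tolerance = 1e-12)
  expect_equal(pt2$band, pt$band)
})

test_that("targeted attribution separates unspecified gears and can split hours", {
  fs <- flat_seascape(depth_m = 3000, n = 10)
  catalog <- default_gear_catalog()
  ev <- rbind(events_df(0.05, 0.05, hours = 4, gear = "drifting_longlines"),
              events_df(0.15, 0.05, hours = 6, gear = "trawlers"))
  pt <- pressure_by_realm(ev, fs$bathy, fs$eco, catalog,
                          attribution = "targeted")
  # drifting longlines 0-400 m over 3000 m: epi + mesopelagic, full hours each
  pel <- pt[pt$domain == "pelagic", ]
  expect_setequal(pel$band, c("epipelagic", "mesopelagic"))
  expect_equal(pel$effort_hours, c(4, 4))
  uns <- pt[pt$domain == "unspecified", ]
  expect_equal(uns$effort_hours, 6)
  expect_true(is.na(uns$pressure_hr_per_km2))

  pts <- pressure_by_realm(ev, fs$bathy, fs$eco, catalog,
                           attribution = "targeted", split_hours = TRUE)
  pel_s <- pts[pts$domain == "pelagic", ]
  expect_equal(sum(pel_s$effort_hours), 4)
})

test_that("interannual stats give the t-based confidence interval", {
  s <- interannual_stats(c(2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$ci_high - s$ci_low, 0)
  s2 <- interannual_stats(c(1, 2, 3), confidence = 0.95)
  expect_equal(s2$mean, 2)
  expect_equal(s2$ci_high - s2$mean, 2.48413771175, tolerance = 1e-9)
  expect_equal(s2$mean - s2$ci_low, s2$ci_high - s2$mean)  # symmetric
  s1 <- interannual_stats(5)
  expect_true(is.na(s1$ci_low) && s1$mean == 5)
})

test_that("gear disaggregation reports hour shares by mode", {
  catalog <- default_gear_catalog()
  ev <- rbind(events_df(0, 0, hours = 3, gear = "bottom_trawl"),
              events_df(0, 0, hours = 3, gear = "fishing"))
  expect_equal(gear_disaggregation_report(ev, catalog),
               c(benthic = 0.5, pelagic = 0, unspecified = 0.5))
  ev_b <- events_df(0, 0, hours = 2, gear = "pot")
  expect_equal(gear_disaggregation_report(ev_b, catalog)[["benthic"]], 1)
  ev_0 <- events_df(0, 0, hours = 0)
  expect_true(all(is.na(gear_disaggregation_report(ev_0, catalog))))
})

test_that("gear catalogs validate ranges and read from CSV", {
  expect_error(gear_catalog("g", "pelagic", 100, 50), "depth_min_m")
  expect_error(gear_catalog("g", "pelagic", NA, NA), "depth range")
  cat0 <- default_gear_catalog()
  expect_true(all(c("midwater_trawl", "drifting_longlines", "trawlers") %in%
                    cat0$name))
  expect_true(all(cat0$mode %in% c("benthic", "pelagic", "unspecified")))
})
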