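#!/usr/bin/env Rscript
# Stage 4: attribute fishing events to depth realms and aggregate effort and
# pressure, under both the depth-impacted rule (whole surface-to-seabed
# column) and the depth-targeted rule (gear operating range capped by
# bathymetry).

library(realms3d)

bathy <- read_bathymetry("results/seascape/bathymetry.asc")
ecoregions <- read_ecoregions("results/seascape/ecoregions.geojson")
events <- read_fishing_events("results/seascape/fishing_events.csv")
catalog <- read_gear_catalog("results/seascape/gear_catalog.csv")
realm_areas <- read.csv("results/tables/realm_areas.csv",
                        stringsAsFactors = FALSE)

shares <- gear_disaggregation_report(events, catalog)
cat(sprintf("gear depth-disaggregation of hours: benthic %.1f%%, pelagic %.1f%%, unspecified %.1f%%\n",
            100 * shares[["benthic"]], 100 * shares[["pelagic"]],
            100 * shares[["unspecified"]]))

impacted <- pressure_by_realm(events, bathy, ecoregions, catalog,
                              realm_areas = realm_areas,
                              attribution = "impacted")
write.csv(impacted, "results/tables/pressure_impacted.csv", row.names = FALSE)
targeted <- suppressWarnings(
  pressure_by_realm(events, bathy, ecoregions, catalog,
                    realm_areas = realm_areas, attribution = "targeted"))
write.csv(targeted, "results/tables/pressure_targeted.csv", row.names = FALSE)
cat(sprintf("excluded land events: %d; unknown gears: %d\n",
            attr(impacted, "n_excluded_land"),
            attr(impacted, "n_unknown_gear")))

# band-level annual pressure with inter-annual 95% CI (impacted attribution)
ben <- impacted[impacted$domain == "benthic", ]
yearly <- aggregate(effort_hours ~ band + year, data = ben, FUN = sum)
band_area <- aggregate(area_km2 ~ band,
                       data = realm_areas[realm_areas$domain == "benthic", ],
                       FUN = sum)
cat("benthic fishing pressure by band (hr km-2 yr-1, mean [95% CI] over years):\n")
for (b in band_area$band) {
  yr <- yearly$effort_hours[yearly$band == b] /
    band_area$area_km2[band_area$band == b]
  if (!length(yr)) next
  s <- interannual_stats(yr, 0.95)
  cat(sprintf("  %-17s %8.3f [%.3f, %.3f]\n", b, s$mean, s$ci_low, s$ci_high))
}
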