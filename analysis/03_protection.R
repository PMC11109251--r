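#!/usr/bin/env Rscript
# Stage 3: flatten overlapping protected areas to the highest protection
# level and compute coverage per 3D realm, for all categories (MPAs + OECMs)
# and for strict Ia/Ib MPAs only.

library(realms3d)

bathy <- read_bathymetry("results/seascape/bathymetry.asc")
ecoregions <- read_ecoregions("results/seascape/ecoregions.geojson")
pas <- read_protected_areas("results/seascape/protected_areas.geojson")
realm_areas <- read.csv("results/tables/realm_areas.csv",
                        stringsAsFactors = FALSE)

coverage <- protection_coverage(pas, bathy, ecoregions,
                                realm_areas = realm_areas,
                                per_category = TRUE)
write.csv(coverage, "results/tables/coverage.csv", row.names = FALSE)

flat <- flatten_by_priority(pas)
cat(sprintf("flattened %d records into %d disjoint category layers: %s\n",
            length(pas$id), length(flat$id),
            paste(flat$category, collapse = ", ")))

# band-level coverage (area-weighted across ecoregions), full assessment
ball <- coverage[coverage$group == "all", ]
band_cov <- aggregate(cbind(protected_area_km2, realm_area_km2) ~ band + domain,
                      data = ball, FUN = sum)
band_cov$coverage_pct <- round(100 * band_cov$protected_area_km2 /
                                 band_cov$realm_area_km2, 1)
cat("protection coverage by depth band (all categories, %):\n")
print(band_cov[order(band_cov$domain, -band_cov$coverage_pct),
               c("band", "domain", "coverage_pct")], row.names = FALSE)
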