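#!/usr/bin/env Rscript
# Stage 2: build the 3D realm typology (ecoregion x depth band x domain) and
# its geodesic areas from the bathymetry and ecoregion layers.

library(realms3d)

bathy <- read_bathymetry("results/seascape/bathymetry.asc")
ecoregions <- read_ecoregions("results/seascape/ecoregions.geojson")

realm_areas <- enumerate_realms3d(bathy, ecoregions)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(realm_areas, "results/tables/realm_areas.csv", row.names = FALSE)

cat(sprintf("%d 3D realms (%d benthic, %d pelagic) across %d ecoregions\n",
            nrow(realm_areas), sum(realm_areas$domain == "benthic"),
            sum(realm_areas$domain == "pelagic"),
            length(unique(realm_areas$ecoregion))))
by_band <- aggregate(area_km2 ~ band + domain, data = realm_areas, FUN = sum)
by_band <- by_band[order(by_band$domain, -by_band$area_km2), ]
cat("total area by depth band (km2):\n")
print(by_band, row.names = FALSE)
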