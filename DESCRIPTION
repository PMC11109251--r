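Package: realms3d
Title: Three-Dimensional Ocean Assessment of Protection Coverage and Fishing Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Overlays benthic and pelagic depth realms onto marine ecoregions
    to build a three-dimensional (3D) typology of the ocean, flattens
    overlapping protected-area polygons to the highest IUCN protection level,
    computes per-3D-realm protection coverage from a bathymetry grid,
    attributes fishing events to depth-impacted and depth-targeted realms via
    gear operating-depth ranges, and classifies 3D realms into conservation
    priority profiles from fishing-pressure and coverage thresholds. Includes
    a seeded synthetic-seascape generator (bathymetry, ecoregions, protected
    areas, fishing events) with generator-known ground truth so the whole
    pipeline is testable without global datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    polyclip,
    sp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
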