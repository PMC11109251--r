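---
title: "Methods: three-dimensional ocean assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-dimensional ocean assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(realms3d)
```

## The assessment model

`realms3d` treats the ocean as a stack of depth realms laid over a 2D
ecoregion map. A *3D realm* is the intersection of one ecoregion with one
depth band in one domain (benthic or pelagic); it is the unit at which
protection coverage and fishing pressure are measured and compared.

The core assumptions are:

1. **Depth zonation captures ecological structure.** The eight benthic and
   five pelagic bands follow the standard ecological depth zones (euphotic
   through hadal; epipelagic through hadopelagic). Within-band heterogeneity
   is deliberately ignored.
2. **The seabed depth of a grid cell determines its vertical column.** A
   protected or fished cell of seabed depth *d* involves the benthic band
   containing *d* and every pelagic band whose shallow bound is above *d*.
   This "surface-to-seabed column" rule reflects vertical connectivity:
   disturbing one layer of a column propagates to the others.
3. **IUCN categories proxy protection level**, ordered Ia (strictest) to VI
   and then Unknown. Where designations overlap, only the most protective
   one counts, so coverage is never double-counted.
4. **Fishing effort (hours) proxies pressure** once divided by realm area;
   catch data are out of scope.

## Coordinate, depth and boundary conventions

- Coordinates are geographic lon/lat decimal degrees throughout; no
  reprojection is attempted.
- Bathymetry rasters store *elevation* (negative below sea level, the usual
  raster convention); the package negates on ingest and works with
  positive-down depths in meters. Cells with elevation ≥ 0 are land and are
  excluded everywhere — the ocean mask is the bathymetry sign, standing in
  for a coastline-polygon clip.
- Depth bands are **deep-inclusive half-open intervals** `(shallow, deep]`.
  A 30 m seabed is euphotic; a 200 m column contains only the epipelagic.
  The choice is a convention (either closure would work); fixing one
  guarantees an exhaustive, non-overlapping partition, which the tests
  enforce by property.
- Grid cells are half-open, `[west, east) × [south, north)`, so a point on a
  shared edge belongs to exactly one cell; per-cell quantities (areas,
  rasterized categories, event lookups) are evaluated at cell centers.
- A note on the deepest pelagic bands: some realm typologies pool the
  abysso- and hadopelagic into a single deepest band. The default scheme
  keeps them separate (five bands);
  `default_pelagic_scheme(merge_deepest = TRUE)` gives the four-band
  variant. Similarly, a worked example sometimes quoted for a 3000 m column
  assigns the *upper* bathyal; the band bounds themselves put 3000 m in the
  lower bathyal (1000–3500 m), and this package follows the bounds.

## Grid-cell geometry

Per-cell areas use the cylindrical-strip formula: constant cell height
`resolution° × 60′ × 1852 m` (one nautical mile per arc minute) and
latitude-dependent width `2πR cos(lat)/n_cells` with R = 6378 km, evaluated
at the **cell-center latitude** (the evaluation latitude is unspecified in
strip models; the center minimizes bias within the strip). At 0.004166°
resolution the height is 462.93 m (≈463 m) and the equatorial width
463.82 m.

`n_cells_lon` defaults to `round(360/resolution)` so coarse test grids stay
self-consistent; the classical constant 86,400 (for 15-arc-second grids) can
be passed explicitly. The package also provides the exact
spherical-quadrilateral area `R² Δλ (sin φ₂ − sin φ₁)` as an independent
cross-check; the two agree within 0.5% for |lat| ≤ 85° — the residual ~0.18%
is the nautical-mile height (111,120 m/degree) versus the spherical arc
(111,319 m/degree). The strip model is kept as the primary method for
fidelity to the published constants; neither is ellipsoidal.

## Flattening overlapping protected areas

Records are merged into one layer per IUCN category, then each layer has
every higher-priority layer subtracted in turn, yielding pairwise-disjoint
geometries whose union is exactly the input union. Numerical choices:

- Boolean operations run in a fixed integer coordinate lattice
  (quantum 10⁻¹² degree, shared by every call), so the sum of flattened
  areas matches the union area to ~10⁻¹³ relative — the conservation
  property the tests assert at 10⁻⁹.
- Subtraction is **per layer, sequentially**, not against one accumulated
  union: clipping a layer against a single giant accumulated multipolygon
  can hit degenerate configurations (contours touching at a point with
  collinear coincident edges) where the clipping engine misplaces a vertex.
  Sequential subtraction sidesteps these and matches the layer-by-layer
  procedure used in practice.
- Geometries are repaired on ingest (even-odd resimplification, the vector
  analogue of a zero-width buffer); irreparable geometries raise instead of
  being dropped silently. Point-plus-reported-area records without true
  boundaries are not representable — buffer circles would fabricate
  bathymetric coverage — and must be excluded upstream.
- An optional vertex-snapping tolerance (e.g. 0.01°) mirrors upstream layer
  simplification.
- OECMs carry their reported category (or Unknown) and compete in the same
  priority ordering as MPAs in the "all" assessment; the strict assessment
  uses Ia/Ib MPAs only. Flattening the two groups in a single pass is the
  simplest consistent treatment and is what `protection_coverage()` does.

Rasterization is a **cell-center membership test**, not area-weighted
partial coverage; the error per polygon boundary cell is at most one
cell-area quantum, which is also the tolerance used in the end-to-end
recovery tests.

## Fishing attribution

Two attribution rules are implemented:

- *Impacted*: every realm in the event's surface-to-seabed column receives
  the event's full hours — one benthic realm, one or more pelagic realms.
  Summed benthic effort therefore equals total event hours exactly (a test
  invariant).
- *Targeted*: benthic gears target the seabed band. Pelagic gears target the
  pelagic bands intersecting the open interval
  `(depth_min, min(depth_max, seabed))`; a range touching a band only at a
  boundary point does not select it (consistent with the band closure
  convention). By default an event's full hours count in each targeted band,
  mirroring how multi-band activities are usually tallied;
  `split_hours = TRUE` divides them evenly instead. Gears whose catalog mode
  is "unspecified" — and unknown gear labels — go to an `unspecified`
  pseudo-realm with effort but no pressure.

Degenerate case: a pelagic gear whose minimum depth meets or exceeds the
local seabed depth is a catalog/bathymetry inconsistency. Returning an empty
set would silently drop effort, so the event is assigned the deepest pelagic
band of its column and a warning names the gear and depths.

The shipped gear catalog (`inst/extdata/gear_catalog.csv`) contains
literature-style operating ranges (drifting longlines 0–400 m, midwater
trawl 30–350 m; bottom trawl, set longline, pot, dredge benthic; purse
seines, "trawlers" and generic "fishing" unspecified). These are editable
placeholders: any real application should review them against gear-specific
technical sources.

Inter-annual variability is summarized as `mean ± t(n−1, 0.975)·sd/√n`
across years — the standard small-sample confidence interval for 2–3 years
of data.

## Prioritization

- **Regression.** Ordinary least squares of log₁₀(coverage %) on
  log₁₀(pressure), with the Pearson r and its two-sided test reported
  separately from r² (a correlation and a coefficient of determination are
  different quantities; the package never prints a signed "R²"). Realms with
  zero coverage or pressure are dropped and counted (`n_dropped`), the log
  being undefined there; a configurable pseudo-offset retains them instead.
  Coverage is the response and pressure the predictor by default — the
  question asked is "is protection sited where fishing is?" — and the
  `coverage_field` argument switches between the all-category and strict
  assessments.
- **Categories.** Fishing quartiles use inclusive linear-interpolation
  quantiles (R type 7); values exactly on a quartile boundary fall in the
  lower category, so an all-tied distribution is all category 1. Coverage
  bins follow target progress: 0–10/10–20/20–30/>30% toward the 30% target,
  or 0–2.5/2.5–5/5–10/>10% toward the strict 10% target, right-inclusive.
- **Score.** The 4 × 4 grid is mapped to 1–16 by
  `(fishing_cat − 1) × 4 + (5 − coverage_cat)`: score rises with pressure
  and with protection deficit, 1 = best-covered/least-fished, 16 =
  least-covered/most-fished. Only the 1–16 range and the grid are inherent;
  this particular bijection is a package choice, tested as such.
- **Profiles.** The 2 × 2 collapse uses the median realm-level pressure
  (unweighted by area, matching the quartile computation) and the halfway
  coverage point (20%, or 5% strict). Both comparisons are inclusive
  (≥ median counts as above-median, ≥ halfway as past-halfway), so realms
  sitting exactly on both thresholds are classified as already mitigating
  pressure rather than as priorities — the conservative reading. The four
  profiles always partition the realm set.

## What the synthetic seascape emulates — and what it does not

The generator (`simulate_seascape()`) produces, under one seed: a monotone
west-to-east shelf-to-hadal bathymetry whose anchor depths give each benthic
band a similar share of columns, plus smooth sinusoidal noise (relative
amplitude 0.08 by default); coastal/offshore ecoregions split at the 200 m
isobath's easternmost column and tiled as latitudinal rectangles; protected
areas grown cell-by-cell per (band × ecoregion) to a target fraction;
and fishing events sampled per gear with intensity decaying away from the
gear's preferred seabed-depth range.

Default conditions mirror the reported structure of the global data:
shallow-biased protection (euphotic target 15%, abyssal 5.8%), a category
mix dominated by VI/Unknown with a small Ia/Ib share, shallow-dominated
trawling and deep-dominated drifting longlines, three years of events, and
exactly 45% of fishing hours under depth-ambiguous gear labels (unspecified
hours are rescaled post hoc so the fraction is exact, making the
disaggregation report checkable to machine precision). Per-realm coverage
targets are the band target times a log-normal multiplier (sd 1.2 on the log
scale), reproducing the order-of-magnitude spread of real coverage across
ecoregions; that spread is what lets seascapes populate all four priority
profiles.

What passing tests on this seascape *do* show: the pipeline recovers known
coverage to one cell-area quantum, known effort exactly, and known profiles
exactly; every band, category and profile branch is exercised. What they do
*not* show: realism of bathymetry (no seamounts, trenches, or shelf breaks
beyond the single gradient), spatial autocorrelation of fishing beyond the
depth niche, polygon shapes beyond axis-aligned rectangles in the generator
(arbitrary convex/elliptical shapes are exercised separately in the
flattening tests), or any statement about the real global datasets.

Ground truth is tallied by direct per-cell and per-event enumeration inside
the generator, independent of the pipeline's vectorized paths; effort sums
are compared at 10⁻¹² relative tolerance (double-precision summation order
is the only difference).

## Problem sizes and determinism

Test and acceptance runs use 100 × 100-cell seascapes at 0.05° (with some
30–40-cell variants), 20 seeds for end-to-end recovery, 100 random polygon
sets for the flattening oracle, and n = 50 realms × 20 replicates for
regression recovery — sizes chosen so cell-quantum effects stay below test
tolerances while the full suite runs in about a minute and a half. All
randomness flows from explicit integer seeds through R's default RNG;
rerunning any stage with the same configuration reproduces its outputs
byte for byte (the pipeline tests assert this on the written CSVs).

## Known limitations

- Spherical, not ellipsoidal, geodesy; areas inherit the ~0.2% strip-model
  bias and degrade near the poles.
- Cell-center membership makes coverage accurate to one cell-area quantum;
  very small or sliver MPAs below the grid resolution can be missed.
- The depth-targeted attribution is only as good as the gear catalog, and
  depth-ambiguous gears (a large share of real fleets) remain unattributed
  by construction.
- Ecoregion polygons are assumed non-overlapping; the rasterizer assigns a
  cell to the first polygon containing its center.
- The framework measures *coverage*, not protection *effectiveness*;
  IUCN categories are a proxy, not an assessment of regulation or
  enforcement.
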