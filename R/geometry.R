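#' Polygon geometries
#'
#' Geometries are lists of rings in the `polyclip` convention: each ring is a
#' `list(x =, y =)` of vertex coordinates (lon/lat decimal degrees, not
#' closed). A geometry may hold several rings under even-odd semantics;
#' counter-clockwise rings are exterior boundaries and clockwise rings holes,
#' so the signed ring areas sum to the geometry's net area.
#'
#' @name geometry
#' @keywords internal
NULL

# Quantum of the integer coordinate space used for clipping. A fixed value
# (rather than polyclip's per-call autoscaling) keeps every boolean op in the
# same integer lattice, so residuals partition unions to ~1e-13 relative.
CLIP_EPS <- 1e-12

ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  j <- c(length(x), seq_len(length(x) - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ensure_ccw <- function(ring) {
  if (ring_signed_area(ring) < 0) list(x = rev(ring$x), y = rev(ring$y))
  else ring
}

ensure_cw <- function(ring) {
  if (ring_signed_area(ring) > 0) list(x = rev(ring$x), y = rev(ring$y))
  else ring
}

#' Rectangular and elliptical rings
#'
#' @param xmin,ymin,xmax,ymax rectangle corners, degrees.
#' @return a counter-clockwise ring (`list(x, y)`).
#' @export
ring_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmin < xmax, ymin < ymax)
  list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' @rdname ring_rect
#' @param cx,cy ellipse center; `rx`,`ry` semi-axes, degrees.
#' @param n_vertices number of vertices of the polygonal approximation.
#' @export
ring_ellipse <- function(cx, cy, rx, ry, n_vertices = 48) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  list(x = cx + rx * cos(t), y = cy + ry * sin(t))
}

#' Net area of a geometry (planar degrees^2)
#'
#' Shoelace area summed over rings; holes (clockwise rings) subtract.
#' Planar in degree space - used for flattening conservation checks, not for
#' geodesic areas (those come from the grid-cell model).
#'
#' @param geom a geometry (list of rings).
#' @return numeric area.
#' @export
geom_area <- function(geom) {
  if (length(geom) == 0) return(0)
  sum(vapply(geom, ring_signed_area, 0))
}

geom_bbox <- function(geom) {
  xs <- unlist(lapply(geom, `[[`, "x"))
  ys <- unlist(lapply(geom, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Even-odd point-in-geometry test
#'
#' A point is inside when it falls in an odd number of rings; points on a
#' ring boundary count as inside.
#'
#' @param x,y point coordinates (vectorized).
#' @param geom a geometry (list of rings).
#' @return logical vector.
#' @export
point_in_geom <- function(x, y, geom) {
  if (length(geom) == 0) return(rep(FALSE, length(x)))
  inside <- integer(length(x))
  on_edge <- rep(FALSE, length(x))
  for (ring in geom) {
    p <- sp::point.in.polygon(x, y, ring$x, ring$y)
    inside <- inside + (p == 1L)
    on_edge <- on_edge | p >= 2L
  }
  (inside %% 2L == 1L) | on_edge
}

clip_geoms <- function(a, b, op) {
  polyclip::polyclip(a, b, op = op, fillA = "evenodd", fillB = "evenodd",
                     eps = CLIP_EPS, x0 = 0, y0 = 0)
}

#' Repair a geometry
#'
#' Resolves self-intersections and degenerate rings under the even-odd fill
#' rule (the vector analogue of a zero-width buffer). Raises if the result is
#' empty while the input claimed positive extent.
#'
#' @param geom a geometry.
#' @return a repaired geometry.
#' @export
repair_geom <- function(geom) {
  out <- polyclip::polysimplify(geom, filltype = "evenodd",
                                eps = CLIP_EPS, x0 = 0, y0 = 0)
  if (length(out) == 0 && length(geom) > 0 && abs(geom_area(geom)) > 0)
    stop("geometry could not be repaired")
  out
}

## ---- GeoJSON I/O -----------------------------------------------------------

rings_from_geojson_geometry <- function(g) {
  polys <- switch(g$type,
    Polygon = list(g$coordinates),
    MultiPolygon = g$coordinates,
    stop("unsupported GeoJSON geometry type: ", g$type)
  )
  rings <- list()
  for (poly in polys) {
    for (k in seq_along(poly)) {
      coords <- poly[[k]]
      m <- if (is.matrix(coords)) coords else do.call(rbind, lapply(coords, unlist))
      # drop the closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      ring <- list(x = m[, 1], y = m[, 2])
      rings[[length(rings) + 1L]] <-
        if (k == 1L) ensure_ccw(ring) else ensure_cw(ring)
    }
  }
  rings
}

geojson_geometry_from_rings <- function(geom) {
  # Exterior rings become polygons; each hole is attached to the first
  # exterior ring that contains its first vertex.
  ccw <- Filter(function(r) ring_signed_area(r) >= 0, geom)
  cw <- Filter(function(r) ring_signed_area(r) < 0, geom)
  close_ring <- function(r)
    cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
  polys <- lapply(ccw, function(r) list(close_ring(r)))
  for (hole in cw) {
    placed <- FALSE
    for (i in seq_along(ccw)) {
      if (point_in_geom(hole$x[1], hole$y[1], list(ccw[[i]]))) {
        polys[[i]] <- c(polys[[i]], list(close_ring(hole)))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("hole ring not contained in any exterior ring")
  }
  if (length(polys) == 1L)
    list(type = "Polygon", coordinates = polys[[1]])
  else
    list(type = "MultiPolygon", coordinates = polys)
}

write_geojson_features <- function(geoms, properties, path) {
  features <- lapply(seq_along(geoms), function(i) {
    list(type = "Feature",
         properties = as.list(properties[i, , drop = FALSE]),
         geometry = geojson_geometry_from_rings(geoms[[i]]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

read_geojson_features <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  geoms <- lapply(fc$features, function(f) {
    g <- f$geometry
    g$coordinates <- simplify_coords(g$coordinates)
    rings_from_geojson_geometry(g)
  })
  props <- lapply(fc$features, function(f) f$properties)
  list(geoms = geoms, properties = props)
}

simplify_coords <- function(x) {
  # convert nested lists of [lon, lat] pairs into matrices ring-wise
  if (is.list(x) && length(x) && is.list(x[[1]]) && length(x[[1]]) &&
      is.numeric(x[[1]][[1]]) && length(x[[1]][[1]]) == 1L) {
    do.call(rbind, lapply(x, function(p) c(p[[1]], p[[2]])))
  } else if (is.list(x)) {
    lapply(x, simplify_coords)
  } else {
    x
  }
}
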