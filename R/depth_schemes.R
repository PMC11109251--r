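#' Depth-realm schemes
#'
#' A depth-realm scheme is an ordered set of contiguous depth bands covering
#' the water column (pelagic domain) or the seafloor (benthic domain) from the
#' surface down. Depths are positive-down meters; the deepest band is
#' unbounded below. Bands are deep-inclusive half-open intervals
#' `(shallow_m, deep_m]`, so a 30 m seabed falls in the euphotic, and every
#' positive depth maps to exactly one band.
#'
#' @param domain `"benthic"` or `"pelagic"`.
#' @param names character vector of unique band names, shallowest first.
#' @param bounds numeric vector of band boundaries in meters, length
#'   `length(names) + 1`, starting at 0, strictly increasing; the last entry
#'   may be `Inf` for an unbounded deepest band.
#' @return An object of class `depth_scheme`: a list with `domain` and a
#'   data frame `bands` (columns `name`, `shallow_m`, `deep_m`).
#' @export
depth_scheme <- function(domain = c("benthic", "pelagic"), names, bounds) {
  domain <- match.arg(domain)
  if (length(bounds) != length(names) + 1L)
    stop("need length(names) + 1 boundaries")
  if (bounds[1] != 0) stop("shallowest bound must be 0")
  if (any(diff(bounds) <= 0)) stop("bounds must be strictly increasing")
  if (anyDuplicated(names)) stop("band names must be unique")
  scheme <- list(
    domain = domain,
    bands = data.frame(
      name = as.character(names),
      shallow_m = bounds[-length(bounds)],
      deep_m = bounds[-1],
      stringsAsFactors = FALSE
    )
  )
  class(scheme) <- "depth_scheme"
  scheme
}

#' @export
print.depth_scheme <- function(x, ...) {
  cat(sprintf("<depth_scheme: %s, %d bands>\n", x$domain, nrow(x$bands)))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Default benthic depth-realm scheme
#'
#' Eight seafloor realms: euphotic (0-30 m), upper mesophotic (30-60 m),
#' lower mesophotic (60-150 m), rariphotic (150-300 m), upper bathyal
#' (300-1000 m), lower bathyal (1000-3500 m), abyssal (3500-6000 m), and
#' hadal (below 6000 m).
#'
#' @return A `depth_scheme` with `domain = "benthic"`.
#' @export
default_benthic_scheme <- function() {
  depth_scheme(
    "benthic",
    names = c("euphotic", "upper_mesophotic", "lower_mesophotic",
              "rariphotic", "upper_bathyal", "lower_bathyal",
              "abyssal", "hadal"),
    bounds = c(0, 30, 60, 150, 300, 1000, 3500, 6000, Inf)
  )
}

#' Default pelagic depth-realm scheme
#'
#' Five water-column realms: epipelagic (0-200 m), mesopelagic (200-1000 m),
#' bathypelagic (1000-3500 m), abyssopelagic (3500-6000 m), and hadopelagic
#' (below 6000 m). Some coarser typologies pool the two deepest realms;
#' `merge_deepest = TRUE` returns that four-realm variant
#' (abyssopelagic spanning 3500 m to the bottom).
#'
#' @param merge_deepest merge abysso- and hadopelagic into one band.
#' @return A `depth_scheme` with `domain = "pelagic"`.
#' @export
default_pelagic_scheme <- function(merge_deepest = FALSE) {
  if (merge_deepest) {
    depth_scheme(
      "pelagic",
      names = c("epipelagic", "mesopelagic", "bathypelagic", "abyssopelagic"),
      bounds = c(0, 200, 1000, 3500, Inf)
    )
  } else {
    depth_scheme(
      "pelagic",
      names = c("epipelagic", "mesopelagic", "bathypelagic",
                "abyssopelagic", "hadopelagic"),
      bounds = c(0, 200, 1000, 3500, 6000, Inf)
    )
  }
}

#' Classify seabed depths into benthic bands
#'
#' The benthic realm of a cell is the band whose interval `(shallow, deep]`
#' contains its seabed depth. Non-positive depths are land (or invalid) and
#' return `NA`.
#'
#' @param depth_m numeric vector of seabed depths, positive-down meters.
#' @param scheme a benthic `depth_scheme`.
#' @return character vector of band names (`NA` for non-positive depths).
#' @export
classify_benthic <- function(depth_m, scheme = default_benthic_scheme()) {
  bounds <- c(scheme$bands$shallow_m, scheme$bands$deep_m[nrow(scheme$bands)])
  idx <- findInterval(depth_m, bounds, left.open = TRUE)
  out <- scheme$bands$name[idx]
  out[!is.finite(depth_m) | depth_m <= 0] <- NA_character_
  out
}

#' Pelagic bands present in a surface-to-seabed column
#'
#' Returns every pelagic band occurring between the surface and the seafloor:
#' all bands whose shallow bound is strictly above the seabed depth. The set
#' is nested in depth (a deeper column contains every band of a shallower
#' one).
#'
#' @param seabed_depth_m single positive seabed depth, meters.
#' @param scheme a pelagic `depth_scheme`.
#' @return character vector of band names, shallowest first.
#' @export
pelagic_column <- function(seabed_depth_m, scheme = default_pelagic_scheme()) {
  stopifnot(length(seabed_depth_m) == 1L)
  if (!is.finite(seabed_depth_m) || seabed_depth_m <= 0)
    stop("seabed depth must be positive (non-positive depths are land)")
  scheme$bands$name[scheme$bands$shallow_m < seabed_depth_m]
}

#' Serialize / read a depth scheme as YAML
#'
#' Band bounds are stored in meters; an unbounded deepest band is stored as
#' the string `.inf`.
#'
#' @param scheme a `depth_scheme`.
#' @param path file path for the YAML config.
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()` the
#'   reconstructed `depth_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(
    domain = scheme$domain,
    bands = lapply(seq_len(nrow(scheme$bands)), function(i) {
      list(name = scheme$bands$name[i],
           shallow_m = scheme$bands$shallow_m[i],
           deep_m = scheme$bands$deep_m[i])
    })
  )
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  nm <- vapply(obj$bands, `[[`, "", "name")
  shallow <- vapply(obj$bands, function(b) as.numeric(b$shallow_m), 0)
  deep <- vapply(obj$bands, function(b) as.numeric(b$deep_m), 0)
  depth_scheme(obj$domain, names = nm, bounds = c(shallow, deep[length(deep)]))
}
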