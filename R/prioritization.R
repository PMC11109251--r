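#' Merge coverage and pressure into 3D-realm summaries
#'
#' One row per 3D realm with its area, protection coverage under the full
#' assessment (`all`: every IUCN category, MPAs + OECMs) and the strict
#' assessment (`Ia_Ib`), and total annualized fishing pressure. Pressure is
#' total effort over all gears and years divided by (realm area x number of
#' years).
#'
#' @param coverage a CoverageTable from [coverage_by_realm()].
#' @param pressure a PressureTable from [pressure_by_realm()].
#' @param n_years number of years spanned by the pressure table; defaults to
#'   the number of distinct years present.
#' @return data frame with columns `ecoregion`, `band`, `domain`,
#'   `area_km2`, `coverage_all_pct`, `coverage_strict_pct`,
#'   `pressure_hr_km2_yr`.
#' @export
realm_summaries <- function(coverage, pressure, n_years = NULL) {
  key <- c("ecoregion", "band", "domain")
  cov_all <- coverage[coverage$group == "all",
                      c(key, "realm_area_km2", "coverage_pct")]
  names(cov_all)[names(cov_all) == "coverage_pct"] <- "coverage_all_pct"
  names(cov_all)[names(cov_all) == "realm_area_km2"] <- "area_km2"
  cov_s <- coverage[coverage$group == "Ia_Ib", c(key, "coverage_pct")]
  names(cov_s)[names(cov_s) == "coverage_pct"] <- "coverage_strict_pct"
  out <- merge(cov_all, cov_s, by = key, all.x = TRUE)
  if (is.null(n_years)) {
    yrs <- unique(pressure$year)
    n_years <- max(1L, length(yrs[!is.na(yrs)]))
  }
  pr <- pressure[pressure$domain != "unspecified", ]
  eff <- stats::aggregate(effort_hours ~ ecoregion + band + domain, data = pr,
                          FUN = sum)
  out <- merge(out, eff, by = key, all.x = TRUE)
  out$effort_hours[is.na(out$effort_hours)] <- 0
  out$pressure_hr_km2_yr <- out$effort_hours / (out$area_km2 * n_years)
  out$effort_hours <- NULL
  rownames(out) <- NULL
  out
}

#' Log-log regression of protection coverage on fishing pressure
#'
#' Ordinary least squares of log10(coverage) on log10(pressure) across 3D
#' realms, with the Pearson correlation and its two-sided test. Realms with
#' zero (or missing) coverage or pressure are dropped (log undefined) and
#' counted in `n_dropped`; alternatively a positive `pseudo_offset` is added
#' to both variables so that zeros can be retained.
#'
#' @param summaries a [realm_summaries()] table.
#' @param coverage_field `"all"` or `"strict"`: which coverage enters the
#'   regression as the response.
#' @param pseudo_offset optional positive offset added to coverage (%) and
#'   pressure before the log transform; `NULL` drops zeros instead.
#' @return list of class `loglog_regression` with `slope`, `intercept`, `r`,
#'   `r2`, `p_value`, `n_used`, `n_dropped` (all `NA` except counts when
#'   fewer than 3 usable realms).
#' @export
loglog_regression <- function(summaries, coverage_field = c("all", "strict"),
                              pseudo_offset = NULL) {
  coverage_field <- match.arg(coverage_field)
  cov <- if (coverage_field == "all") summaries$coverage_all_pct
         else summaries$coverage_strict_pct
  press <- summaries$pressure_hr_km2_yr
  if (!is.null(pseudo_offset)) {
    stopifnot(pseudo_offset > 0)
    cov <- cov + pseudo_offset
    press <- press + pseudo_offset
  }
  use <- !is.na(cov) & !is.na(press) & cov > 0 & press > 0
  res <- list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
              r2 = NA_real_, p_value = NA_real_,
              n_used = sum(use), n_dropped = sum(!use))
  class(res) <- "loglog_regression"
  if (sum(use) < 3) return(res)
  x <- log10(press[use]); y <- log10(cov[use])
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  res$slope <- unname(stats::coef(fit)[2])
  res$intercept <- unname(stats::coef(fit)[1])
  res$r <- unname(ct$estimate)
  res$r2 <- res$r^2
  res$p_value <- ct$p.value
  res
}

#' @export
print.loglog_regression <- function(x, ...) {
  cat(sprintf(
    "log10(coverage) ~ log10(pressure): slope %.4f, r %.3f, r2 %.3f, p %.4g (n = %d used, %d dropped)\n",
    x$slope, x$r, x$r2, x$p_value, x$n_used, x$n_dropped))
  invisible(x)
}

#' Quartile categories of fishing pressure
#'
#' Realms are binned by the quartiles (inclusive linear-interpolation
#' quantiles) of the realm-level pressure distribution; category 4 is the
#' highest pressure. A value exactly on a quartile boundary falls in the
#' lower category.
#'
#' @param pressures numeric vector of realm-level pressures (>= 4 values).
#' @return integer vector of categories 1-4.
#' @export
fishing_categories <- function(pressures) {
  stopifnot(length(pressures) >= 4, !any(is.na(pressures)))
  q <- stats::quantile(pressures, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (pressures > q[1]) + (pressures > q[2]) + (pressures > q[3])
}

#' Coverage categories against conservation targets
#'
#' Bins protection coverage by progress towards the 2030 targets: for the
#' full assessment (30% target) the bins are 0-10, 10-20, 20-30 and >30%;
#' for the strict Ia/Ib assessment (10% target) 0-2.5, 2.5-5, 5-10 and >10%.
#' Boundaries are right-inclusive (exactly 10% under `"all"` is category 1);
#' category 4 is the highest coverage.
#'
#' @param coverage_pct numeric vector of coverage percentages in [0, 100].
#' @param assessment `"all"` or `"strict"`.
#' @return integer vector of categories 1-4.
#' @export
coverage_categories <- function(coverage_pct, assessment = c("all", "strict")) {
  assessment <- match.arg(assessment)
  stopifnot(all(coverage_pct >= 0 & coverage_pct <= 100, na.rm = TRUE))
  th <- if (assessment == "all") c(10, 20, 30) else c(2.5, 5, 10)
  1L + (coverage_pct > th[1]) + (coverage_pct > th[2]) + (coverage_pct > th[3])
}

#' Position score in the 4 x 4 pressure-coverage grid
#'
#' Maps the (fishing category, coverage category) pair to a score 1-16 that
#' increases with fishing pressure and with protection deficit:
#' `(fishing_cat - 1) * 4 + (5 - coverage_cat)`. Score 1 = lowest pressure
#' and highest coverage; 16 = highest pressure and lowest coverage. The
#' mapping is a bijection over the 16 cells.
#'
#' @param fishing_cat,coverage_cat integer categories in 1-4 (vectorized).
#' @return integer scores 1-16.
#' @export
grid_score <- function(fishing_cat, coverage_cat) {
  if (any(!fishing_cat %in% 1:4) || any(!coverage_cat %in% 1:4))
    stop("categories must be integers 1-4")
  as.integer((fishing_cat - 1L) * 4L + (5L - coverage_cat))
}

#' Conservation priority profile of a 3D realm
#'
#' The 4 x 4 grid collapsed to 2 x 2 using the median realm-level fishing
#' pressure and the halfway point towards the 2030 coverage target (20% of
#' total protection, or 5% of Ia/Ib coverage). Both threshold comparisons
#' are inclusive: pressure >= median counts as above-median, coverage >=
#' halfway counts as past halfway.
#'
#' @param pressure numeric vector of realm pressures.
#' @param coverage_pct numeric vector of realm coverages (%).
#' @param median_pressure the median realm-level pressure threshold.
#' @param halfway_pct halfway coverage threshold (20 for the full
#'   assessment, 5 for strict).
#' @return character vector: `"highest_priority"`, `"lowest_priority"`,
#'   `"fills_conservation_gaps"` or `"mitigates_fishing_pressure"`.
#' @export
priority_profile <- function(pressure, coverage_pct, median_pressure,
                             halfway_pct) {
  above <- pressure >= median_pressure
  past <- coverage_pct >= halfway_pct
  ifelse(above & !past, "highest_priority",
  ifelse(!above & past, "lowest_priority",
  ifelse(!above & !past, "fills_conservation_gaps",
         "mitigates_fishing_pressure")))
}

#' Priority assessment of a realm summary table
#'
#' Adds fishing and coverage categories, the 1-16 grid score, and the 2 x 2
#' priority profile to a [realm_summaries()] table.
#'
#' @param summaries a [realm_summaries()] table.
#' @param assessment `"all"` (30% target, halfway 20%) or `"strict"`
#'   (10% Ia/Ib target, halfway 5%).
#' @return the input with columns `fishing_cat`, `coverage_cat`, `score`,
#'   `profile` appended.
#' @export
prioritize_realms <- function(summaries, assessment = c("all", "strict")) {
  assessment <- match.arg(assessment)
  cov <- if (assessment == "all") summaries$coverage_all_pct
         else summaries$coverage_strict_pct
  halfway <- if (assessment == "all") 20 else 5
  out <- summaries
  out$fishing_cat <- fishing_categories(summaries$pressure_hr_km2_yr)
  out$coverage_cat <- coverage_categories(cov, assessment)
  out$score <- grid_score(out$fishing_cat, out$coverage_cat)
  out$profile <- priority_profile(
    summaries$pressure_hr_km2_yr, cov,
    stats::median(summaries$pressure_hr_km2_yr), halfway)
  out
}

#' Profile shares by realm count and by ocean area
#'
#' @param profiles character vector of per-realm profiles.
#' @param areas numeric vector of realm areas (km2).
#' @return data frame with `profile`, `realm_share`, `area_share`; both
#'   share columns sum to 1.
#' @export
profile_shares <- function(profiles, areas) {
  stopifnot(length(profiles) == length(areas))
  lv <- c("highest_priority", "lowest_priority", "fills_conservation_gaps",
          "mitigates_fishing_pressure")
  f <- factor(profiles, levels = lv)
  n <- tapply(rep(1, length(f)), f, sum, default = 0)
  a <- tapply(areas, f, sum, default = 0)
  data.frame(profile = lv,
             realm_share = as.numeric(n) / length(profiles),
             area_share = as.numeric(a) / sum(areas),
             stringsAsFactors = FALSE)
}
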