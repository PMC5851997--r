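#' @title Country-level degradation allocation
#' @description Converts per-country degraded-peatland statistics into
#'   land-use-specific degradation fractions and a per-cell degradation
#'   map. Cropland on peat is assumed fully degrading (fraction 1); the
#'   residual reported degraded area is spread uniformly over all other
#'   accountable land-use classes.
#' @name degradation_allocator
NULL

#' Country degradation ratio
#'
#' Fraction of a country's peatland reported as degraded (0 = non-degraded,
#' 1 = fully degraded), clipped into \[0, 1\].
#'
#' @param peat_area Country peatland area (ha), > 0.
#' @param degraded_area Reported degraded peatland area (ha).
#' @return Numeric ratio in \[0, 1\] (vectorized).
#' @export
degradation_ratio <- function(peat_area, degraded_area) {
  if (any(peat_area <= 0)) {
    stop("degradation ratio undefined for zero peat area")
  }
  pmin(pmax(degraded_area / peat_area, 0), 1)
}

#' Allocate country degradation statistics to land-use classes
#'
#' For each country: cropland on peat is fully degrading
#' (`fraction_cl = 1`). Let `c` be the cropland/peatland ratio and `d` the
#' reported degradation ratio. If `d <= c` the cropland area is taken as the
#' better estimate and nothing is spread to other classes. If `d > c` the
#' residual degraded area `(d - c) * peat_area` is spread uniformly over the
#' non-cropland peat area, giving
#' `fraction_other = (d - c) * peat_area / (peat_area - cropland_area)`
#' (applied alike to GL, FL and the mixed classes). Fractions exceeding 1
#' (inconsistent statistics) are clipped with a warning.
#'
#' @param countries Data frame with columns `country`, `peat_area_ha`,
#'   `cropland_on_peat_ha`, `degraded_area_ha`.
#' @return Data frame with one row per country: `country`, `fraction_cl`
#'   (always 1), `fraction_other`, `degraded_reported_ha` (the input
#'   statistic) and `degraded_effective_ha` (cell-level bookkeeping with CL
#'   always fully degraded, i.e. at least the cropland area).
#' @export
#' @examples
#' allocate_degradation(data.frame(
#'   country = "X", peat_area_ha = 100,
#'   cropland_on_peat_ha = 10, degraded_area_ha = 40))$fraction_other  # 1/3
allocate_degradation <- function(countries) {
  req <- c("country", "peat_area_ha", "cropland_on_peat_ha",
           "degraded_area_ha")
  stopifnot(all(req %in% names(countries)))
  p <- countries$peat_area_ha
  cl <- countries$cropland_on_peat_ha
  if (any(p <= 0)) stop("country peat area must be positive")
  if (any(cl < 0) || any(cl > p)) {
    stop("cropland-on-peat area outside [0, peat area]")
  }
  d <- degradation_ratio(p, countries$degraded_area_ha)
  c_ratio <- cl / p
  frac <- numeric(length(p))
  spread <- d > c_ratio
  if (any(spread & p == cl)) {
    stop("country with d > c but no non-cropland peat to allocate to: ",
         paste(countries$country[spread & p == cl], collapse = ", "))
  }
  frac[spread] <- ((d - c_ratio) * p / (p - cl))[spread]
  if (any(frac > 1 + 1e-12)) {
    warning("residual degradation exceeds non-cropland peat area for: ",
            paste(countries$country[frac > 1 + 1e-12], collapse = ", "),
            " (fraction clipped to 1)")
  }
  frac <- pmin(frac, 1)
  data.frame(
    country = countries$country,
    fraction_cl = 1,
    fraction_other = frac,
    degraded_reported_ha = countries$degraded_area_ha,
    degraded_effective_ha = cl + frac * (p - cl),
    stringsAsFactors = FALSE
  )
}

#' Build the per-cell degradation map
#'
#' Fills the degradation column of a classified grid: cropland cells get 1,
#' other accountable cells their country's `fraction_other`, excluded
#' (`NONE`) cells 0. Countries present in the grid but absent from the
#' assignment table default to `fraction_other = 0` with a warning (the
#' conservative non-degraded end of the ratio), or raise an error when
#' `strict = TRUE`.
#'
#' @param cells Classified cell table with columns `landuse` and `country`
#'   (see [classify_grid()]).
#' @param assignments Output of [allocate_degradation()].
#' @param strict Error instead of warn on countries with no assignment.
#' @return `cells` with a `degradation` column in \[0, 1\] appended.
#' @export
build_degradation_map <- function(cells, assignments, strict = FALSE) {
  stopifnot(all(c("landuse", "country") %in% names(cells)))
  idx <- match(cells$country, assignments$country)
  unassigned <- unique(cells$country[is.na(idx) & cells$landuse != "NONE"])
  if (length(unassigned) > 0) {
    msg <- paste("no degradation statistics for country:",
                 paste(unassigned, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, " (defaulting non-cropland degradation to 0)")
  }
  frac_other <- assignments$fraction_other[idx]
  frac_other[is.na(frac_other)] <- 0
  deg <- ifelse(cells$landuse == "NONE", 0,
                ifelse(cells$landuse == "CL", 1, frac_other))
  deg[is.na(cells$landuse)] <- 0
  cells$degradation <- deg
  cells
}
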