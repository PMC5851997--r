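#' Reference per-climate area, emission and carbon-stock table
#'
#' Returns the packaged per-climate aggregates for global peatlands: total
#' peatland area split by land-use column, degrading area, actual emissions
#' (annual mean with min--max range, Gt CO2-eq), and peat carbon stocks
#' (total and degrading, Gt C). These aggregates are the canonical desk-scale
#' input to the nitrogen-budget and trajectory stages, standing in for a full
#' global map run.
#'
#' The `oceanic` row carries values below the reporting resolution (printed
#' as "<0.1") and is stored as zero.
#'
#' @return A data frame with one row per reporting climate zone and columns
#'   `climate`, `zone` (emission-factor zone the row maps to),
#'   `area_total_mha`, `area_cl_mha`, `area_gl_mha`, `area_fl_mha`,
#'   `area_gl_fl_mha`, `area_cl_gl_fl_mha`, `area_degrading_mha`,
#'   `emission_min_gt`, `emission_mean_gt`, `emission_max_gt` (Gt CO2-eq
#'   a-1), `peat_c_gt`, `degrading_c_gt` (Gt C).
#' @seealso [global_peat_totals()] for the independently printed totals row,
#'   [climate_budgets()] for the derived nitrogen budgets.
#' @export
#' @examples
#' fix <- global_peat_aggregates()
#' sum(fix$emission_mean_gt)  # global actual emission, Gt CO2-eq per year
global_peat_aggregates <- function() {
  data.frame(
    climate = c("tropical", "temperate", "boreal", "polar", "oceanic"),
    zone = c("TROPICAL", "TEMPERATE", "BOREAL_POLAR", "BOREAL_POLAR",
             "TEMPERATE"),
    area_total_mha = c(58.7, 18.5, 360.9, 25.0, 0),
    area_cl_mha = c(8.5, 3.5, 6.8, 0.1, 0),
    area_gl_mha = c(11.3, 5.0, 85.6, 14.9, 0),
    area_fl_mha = c(34.6, 8.9, 249.5, 9.7, 0),
    area_gl_fl_mha = c(1.6, 0.7, 17.9, 0.1, 0),
    area_cl_gl_fl_mha = c(2.7, 0.6, 1.1, 0.3, 0),
    area_degrading_mha = c(24.2, 10.6, 15.5, 0.7, 0),
    emission_min_gt = c(0.04, 0.10, 0.16, 0, 0),
    emission_mean_gt = c(1.48, 0.16, 0.26, 0.01, 0),
    emission_max_gt = c(2.79, 0.21, 0.36, 0.02, 0),
    peat_c_gt = c(119.2, 21.9, 427.0, 29.6, 0),
    degrading_c_gt = c(49.1, 12.5, 18.3, 0.8, 0),
    stringsAsFactors = FALSE
  )
}

#' Printed totals accompanying the reference table
#'
#' The totals row of the reference table as printed. Because the per-climate
#' rows are themselves rounded, summing them does not always reproduce these
#' totals exactly (e.g. the emission minima sum to 0.30 vs the printed 0.31,
#' and the degrading stocks to 80.7 vs 80.8); both views are kept available.
#'
#' @return A list with elements `area_mha`, `degrading_area_mha`,
#'   `emission_gt` (named min/mean/max, Gt CO2-eq a-1), `peat_c_gt`,
#'   `degrading_c_gt`.
#' @export
global_peat_totals <- function() {
  list(
    area_mha = 463.2,
    degrading_area_mha = 50.9,
    emission_gt = c(min = 0.31, mean = 1.91, max = 3.38),
    peat_c_gt = 597.8,
    degrading_c_gt = 80.8
  )
}

#' Reference equivalence points between peat emissions and the mineral sink
#'
#' Reported equivalence years (minimum, mean, maximum) for the
#' business-as-usual degradation case, used as a horizon input for
#' annualizing avoidable nitrogen release. These depend on the exact
#' calibrated mineral-soil saturation equation, which this package
#' approximates with a pluggable saturating form (see [mineral_sink()]), so
#' they are carried as reference constants rather than recomputed.
#'
#' @return Named numeric vector `c(min = 140, mean = 238, max = 1021)` years.
#' @export
reference_equivalence_years <- function() {
  c(min = 140, mean = 238, max = 1021)
}

#' Per-climate carbon and nitrogen budgets
#'
#' Attaches a median C/N ratio to every reporting climate row of the
#' reference table and derives nitrogen stocks and avoidable nitrogen
#' releases as C / (C/N). Tropical peat uses its own median; temperate,
#' boreal, polar and oceanic rows share the northern-peat median.
#'
#' @param fixture Per-climate table in the shape of [global_peat_aggregates()].
#' @param cn_tropical Median C/N of tropical peat (mass ratio).
#' @param cn_northern Median C/N of temperate + boreal + polar peat.
#' @return The fixture with columns `median_cn`, `n_stock_gt`
#'   (total peat N, Gt) and `n_release_gt` (avoidable N in degrading peat,
#'   Gt) appended.
#' @export
#' @examples
#' b <- climate_budgets()
#' sum(b$n_release_gt)  # total avoidable N release, Gt
climate_budgets <- function(fixture = global_peat_aggregates(),
                            cn_tropical = 29.7, cn_northern = 49.0) {
  stopifnot(cn_tropical > 0, cn_northern > 0)
  fixture$median_cn <- ifelse(fixture$climate == "tropical",
                              cn_tropical, cn_northern)
  fixture$n_stock_gt <- nitrogen_from_carbon(fixture$peat_c_gt,
                                             fixture$median_cn)
  fixture$n_release_gt <- nitrogen_from_carbon(fixture$degrading_c_gt,
                                               fixture$median_cn)
  fixture
}
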