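#' @title Carbon/nitrogen stoichiometric budgets
#' @description C/N sample filtering and medians, nitrogen stocks and
#'   avoidable releases derived from carbon stocks, and the nitrogen
#'   requirement of mineral-soil carbon sequestration.
#' @name stock_nitrogen_budget
NULL

#' Filter C/N samples with the mineral-soil exclusion rules
#'
#' Removes records that are (a) flagged as Histosols, (b) have C/N ratios
#' below 5 or above 100 (assumed analytical errors), or (c) have soil
#' organic C concentration above 200 mg g-1 (organic soils not classified
#' as Histosols). The three rules are independent OR-ed exclusions; a
#' record violating several is counted under each.
#'
#' @param samples Data frame with columns `histosol` (logical), `cn`
#'   (C/N mass ratio) and `organic_c_mg_g` (mg C per g soil).
#' @return List with `samples` (retained rows), `excluded` (named counts
#'   per rule: `histosol`, `cn_range`, `concentration`) and `n_excluded`
#'   (total rows removed).
#' @export
filter_cn_samples <- function(samples) {
  stopifnot(all(c("histosol", "cn", "organic_c_mg_g") %in% names(samples)))
  r_hist <- samples$histosol %in% TRUE
  r_cn <- !is.na(samples$cn) & (samples$cn < 5 | samples$cn > 100)
  r_conc <- !is.na(samples$organic_c_mg_g) & samples$organic_c_mg_g > 200
  drop <- r_hist | r_cn | r_conc
  list(
    samples = samples[!drop, , drop = FALSE],
    excluded = c(histosol = sum(r_hist), cn_range = sum(r_cn),
                 concentration = sum(r_conc)),
    n_excluded = sum(drop)
  )
}

#' Median C/N ratio of a sample set
#'
#' Standard sample median (mean of the middle pair for even n).
#'
#' @param samples Data frame with a `cn` column, or a numeric vector of
#'   C/N ratios. Must be non-empty.
#' @return The median C/N (dimensionless).
#' @export
median_cn <- function(samples) {
  x <- if (is.data.frame(samples)) samples$cn else samples
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("cannot take the median of an empty sample set")
  stats::median(x)
}

#' Nitrogen stock implied by a carbon stock and a C/N ratio
#'
#' @param c_stock Carbon stock (Gt C), vectorized.
#' @param cn C/N mass ratio, > 0.
#' @return Nitrogen stock (Gt N) = `c_stock / cn`.
#' @export
#' @examples
#' nitrogen_from_carbon(119.2, 29.7)  # ~4.0 Gt N in tropical peat
nitrogen_from_carbon <- function(c_stock, cn) {
  if (any(cn <= 0)) stop("C/N ratio must be positive")
  c_stock / cn
}

#' Total avoidable nitrogen release from degrading peat
#'
#' Sums per-climate degrading carbon stocks divided by their zone median
#' C/N ratios.
#'
#' @param budgets Per-climate budget table with columns `degrading_c_gt`
#'   and `median_cn` (see [climate_budgets()]).
#' @return Total avoidable N release (Gt N).
#' @export
#' @examples
#' total_n_release(climate_budgets())  # ~2.3 Gt N
total_n_release <- function(budgets) {
  stopifnot(all(c("degrading_c_gt", "median_cn") %in% names(budgets)))
  if (anyNA(budgets$median_cn) || anyNA(budgets$degrading_c_gt)) {
    stop("budgets must cover every climate zone with degrading stock")
  }
  sum(nitrogen_from_carbon(budgets$degrading_c_gt, budgets$median_cn))
}

#' Mineral-soil sequestration parameters
#'
#' Defaults describe management-induced carbon sequestration on all
#' agricultural land: 4923 Mha (1563 Mha arable + 3360 Mha meadow and
#' pasture), mean soil C content 1.35%, organic-matter median C/N 10.7,
#' a maximum additional storage of 24--64 Gt C reached within 63 years
#' (after a prudential +/- 1/5 margin on the calibrated bounds).
#'
#' @param area_mha Agricultural area (Mha).
#' @param arable_mha,pasture_mha Components of `area_mha` (informational).
#' @param soil_c_pct Mean topsoil C content (% mass).
#' @param cn Median C/N of mineral-soil organic matter.
#' @param seq_max_gt Length-2 range (min, max) of maximum additional C
#'   storage (Gt C).
#' @param horizon_yr Years over which the maximum is reached.
#' @param prudential_margin Fractional margin already applied on both ends
#'   of the calibrated range (informational).
#' @return List of parameters with class `mineral_soil_params`.
#' @export
mineral_soil_params <- function(area_mha = 4923,
                                arable_mha = 1563, pasture_mha = 3360,
                                soil_c_pct = 1.35, cn = 10.7,
                                seq_max_gt = c(24, 64), horizon_yr = 63,
                                prudential_margin = 1 / 5) {
  stopifnot(area_mha > 0, soil_c_pct > 0, cn > 0, horizon_yr > 0,
            length(seq_max_gt) == 2, all(seq_max_gt > 0),
            seq_max_gt[1] <= seq_max_gt[2])
  structure(list(area_mha = area_mha, arable_mha = arable_mha,
                 pasture_mha = pasture_mha, soil_c_pct = soil_c_pct,
                 cn = cn, seq_max_gt = seq_max_gt, horizon_yr = horizon_yr,
                 prudential_margin = prudential_margin),
            class = "mineral_soil_params")
}

#' Nitrogen requirement of mineral-soil carbon sequestration
#'
#' Building new soil organic matter at the mineral-soil C/N ratio
#' immobilizes `seq_c / cn` Gt N in total, or, averaged over the
#' sequestration horizon, `total / horizon * 1000` Mt N per year.
#'
#' @param seq_c Carbon to be sequestered (Gt C), vectorized.
#' @param params A [mineral_soil_params()].
#' @return Data frame with columns `seq_c_gt`, `total_n_gt`,
#'   `annual_n_mt`.
#' @export
#' @examples
#' mineral_n_requirement(c(24, 64))  # ~2.2 and ~6.0 Gt N
mineral_n_requirement <- function(seq_c, params = mineral_soil_params()) {
  stopifnot(inherits(params, "mineral_soil_params"), all(seq_c >= 0))
  total <- seq_c / params$cn
  data.frame(seq_c_gt = seq_c, total_n_gt = total,
             annual_n_mt = total / params$horizon_yr * 1000)
}

#' Nitrogen cost ratio of mineral-soil sequestration vs peat restoration
#'
#' Compares the nitrogen immobilized per unit carbon stored in mineral soil
#' (`1 / cn_mineral`) with the nitrogen released per unit carbon emitted
#' from degrading peat (`n_release / degrading_c`). Values above 1 mean
#' restoring peatlands is that many times less nitrogen costly than
#' sequestering the same carbon in mineral soils.
#'
#' @param cn_mineral Mineral-soil organic matter C/N ratio.
#' @param n_release_gt Total avoidable N release from degrading peat (Gt N).
#' @param degrading_c_gt Total degrading peat C stock (Gt C), > 0.
#' @return Dimensionless ratio.
#' @export
n_cost_ratio <- function(cn_mineral, n_release_gt, degrading_c_gt) {
  stopifnot(cn_mineral > 0)
  if (any(degrading_c_gt <= 0)) stop("degrading peat C stock must be positive")
  (1 / cn_mineral) / (n_release_gt / degrading_c_gt)
}

#' Annualized avoidable nitrogen release
#'
#' Converts a cumulative avoidable N release into an annual rate over a
#' given horizon (typically the mean equivalence year).
#'
#' @param total_n_gt Cumulative avoidable N (Gt N).
#' @param years Horizon (years), > 0.
#' @return Annual rate (Mt N per year).
#' @export
#' @examples
#' annualized_n_avoidance(2.3, 238)  # ~9.7 Mt N per year
annualized_n_avoidance <- function(total_n_gt, years) {
  if (any(years <= 0)) stop("horizon must be positive")
  total_n_gt / years * 1000
}
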