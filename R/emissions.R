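#' @title Emission-factor aggregation and emission mapping
#' @description Aggregates gas-specific emission factors (CO2, CH4, N2O,
#'   DOC) into CO2-equivalents with explicit min/mean/max ranges (interval
#'   arithmetic, not confidence intervals), combines them for mixed
#'   land-use classes, maps potential and actual emissions over a peat
#'   grid, and summarizes by climate and land use.
#' @name emission_engine
NULL

#' Global warming potential set
#'
#' @param ch4 GWP of methane (mass CO2 per mass CH4), > 0.
#' @param n2o GWP of nitrous oxide (mass CO2 per mass N2O), > 0.
#' @param horizon Label for the horizon the values refer to.
#' @return List with class `gwp_set`. Defaults are the 100-year values
#'   without climate-carbon feedbacks (CH4 28, N2O 265).
#' @export
gwp_set <- function(ch4 = 28, n2o = 265, horizon = "GWP100") {
  stopifnot(ch4 > 0, n2o > 0)
  structure(list(ch4 = ch4, n2o = n2o, horizon = horizon),
            class = "gwp_set")
}

# Normalize a gas rate to the native mass the CO2-eq formula expects:
# CO2 as t CO2, CH4 as t CH4, N2O as t N2O, DOC as t C (all ha-1 yr-1).
.normalize_rate <- function(gas, value, unit) {
  u <- gsub("[ /._-]", "", tolower(unit))
  u <- sub("ha1?yr1?$", "", u)
  u <- sub("haa1?$", "", u)
  key <- paste(gas, u, sep = ":")
  conv <- switch(
    key,
    "CO2:tco2" = 1, "CO2:tc" = 44 / 12,
    "CH4:tch4" = 1, "CH4:kgch4" = 1e-3,
    "N2O:tn2o" = 1, "N2O:kgn2o" = 1e-3,
    "N2O:kgn2on" = 44 / 28 * 1e-3, "N2O:tn2on" = 44 / 28,
    "DOC:tc" = 1, "DOC:kgc" = 1e-3,
    stop("unsupported unit '", unit, "' for gas ", gas)
  )
  value * conv
}

#' Aggregate gas-specific emission factors into CO2-equivalents
#'
#' For every (land use, climate) stratum, converts the four gas rates to
#' native mass units and combines them as
#' `co2eq = CO2 + gwp_CH4 * CH4 + gwp_N2O * N2O + 44/12 * DOC`
#' separately for the min, mean and max layers (interval arithmetic: minima
#' from minima, maxima from maxima). DOC is counted as fully oxidized
#' leached carbon.
#'
#' @param ef Long-format data frame with columns `landuse`, `climate`
#'   (generic zone), `gas` (`CO2`, `CH4`, `N2O`, `DOC`), `min`, `mean`,
#'   `max` and `unit` (e.g. `"t C/ha/yr"`, `"kg CH4/ha/yr"`,
#'   `"kg N2O-N/ha/yr"`). Missing gases count as zero.
#' @param gwp A [gwp_set()].
#' @return Data frame with one row per (landuse, climate):
#'   `co2eq_min/mean/max` in t CO2-eq ha-1 yr-1.
#' @export
aggregate_ef <- function(ef, gwp = gwp_set()) {
  req <- c("landuse", "climate", "gas", "min", "mean", "max", "unit")
  stopifnot(all(req %in% names(ef)), inherits(gwp, "gwp_set"))
  if (any(ef$min < 0 | ef$mean < 0 | ef$max < 0)) {
    stop("negative emission-factor rate")
  }
  if (any(ef$min > ef$mean | ef$mean > ef$max)) {
    stop("emission-factor rows must satisfy min <= mean <= max")
  }
  weight <- function(gas) {
    switch(gas, CO2 = 1, CH4 = gwp$ch4, N2O = gwp$n2o, DOC = 44 / 12,
           stop("unknown gas: ", gas))
  }
  contrib <- vapply(seq_len(nrow(ef)), function(i) {
    w <- weight(ef$gas[i])
    w * .normalize_rate(ef$gas[i],
                        c(ef$min[i], ef$mean[i], ef$max[i]),
                        ef$unit[i])
  }, numeric(3))
  key <- paste(ef$landuse, ef$climate, sep = "|")
  agg <- rowsum(t(contrib), key)
  keys <- strsplit(rownames(agg), "|", fixed = TRUE)
  data.frame(
    landuse = vapply(keys, `[`, "", 1),
    climate = vapply(keys, `[`, "", 2),
    co2eq_min = agg[, 1], co2eq_mean = agg[, 2], co2eq_max = agg[, 3],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Combine member emission factors for a mixed land-use class
#'
#' The mean is the unweighted mean of member means; the range is the
#' envelope (min of member minima, max of member maxima), keeping the
#' conservative explicit-range uncertainty treatment. All members must
#' share a climate zone.
#'
#' @param members Data frame of aggregated rows (as from [aggregate_ef()])
#'   with >= 2 rows and identical `climate`.
#' @return One-row data frame with the combined `co2eq_min/mean/max`.
#' @export
mixed_class_ef <- function(members) {
  stopifnot(nrow(members) >= 2)
  if (length(unique(members$climate)) != 1) {
    stop("mixed-class members span different climate zones")
  }
  data.frame(
    climate = members$climate[1],
    co2eq_min = min(members$co2eq_min),
    co2eq_mean = mean(members$co2eq_mean),
    co2eq_max = max(members$co2eq_max),
    stringsAsFactors = FALSE
  )
}

#' Emission-class lookup table of CO2-eq rates
#'
#' Aggregates the per-gas table and derives the two mixed classes
#' (`MIX_CL_GL_FL` from CL+GL+FL, `MIX_GL_FL` from GL+FL) per climate zone,
#' keyed by emission-class label (e.g. `"CL-tropical"`).
#'
#' @param ef Long-format per-gas table (see [aggregate_ef()]).
#' @param gwp A [gwp_set()].
#' @return Data frame with columns `emission_class`, `landuse`, `climate`,
#'   `co2eq_min/mean/max` (t CO2-eq ha-1 yr-1).
#' @export
build_ef_lookup <- function(ef, gwp = gwp_set()) {
  base <- aggregate_ef(ef, gwp)
  mixes <- list(MIX_CL_GL_FL = c("CL", "GL", "FL"),
                MIX_GL_FL = c("GL", "FL"))
  rows <- lapply(unique(base$climate), function(cz) {
    at <- base[base$climate == cz, ]
    mixed <- lapply(names(mixes), function(nm) {
      mem <- at[at$landuse %in% mixes[[nm]], ]
      if (nrow(mem) < length(mixes[[nm]])) {
        stop("missing member classes for ", nm, " in climate ", cz)
      }
      cbind(landuse = nm, mixed_class_ef(mem))
    })
    rbind(at, do.call(rbind, mixed))
  })
  out <- do.call(rbind, rows)
  out$emission_class <- paste0(out$landuse, "-", tolower(out$climate))
  out[, c("emission_class", "landuse", "climate",
          "co2eq_min", "co2eq_mean", "co2eq_max")]
}

#' Map potential emissions over a peat grid
#'
#' Potential emission of a cell: the flux it would produce if fully drained,
#' i.e. its emission class's CO2-eq rate times its area. Excluded cells
#' (no emission class) and non-peat cells get zero.
#'
#' @param cells Classified cell table with `emission_class`, `cell_area_ha`
#'   and logical `peat` columns.
#' @param ef_lookup Emission-class rate table from [build_ef_lookup()].
#' @return `cells` with `potential_min/mean/max` (t CO2-eq yr-1) appended.
#' @export
potential_emissions <- function(cells, ef_lookup) {
  stopifnot(all(c("emission_class", "cell_area_ha", "peat") %in% names(cells)))
  acct <- !is.na(cells$emission_class) & cells$peat
  idx <- match(cells$emission_class, ef_lookup$emission_class)
  missing <- unique(cells$emission_class[acct & is.na(idx)])
  if (length(missing) > 0) {
    stop("no emission factor for class: ", paste(missing, collapse = ", "))
  }
  for (layer in c("min", "mean", "max")) {
    rate <- ef_lookup[[paste0("co2eq_", layer)]][idx]
    val <- ifelse(acct, rate * cells$cell_area_ha, 0)
    val[is.na(val)] <- 0
    cells[[paste0("potential_", layer)]] <- val
  }
  cells
}

#' Map actual emissions from potential emissions and degradation
#'
#' Cellwise product of the potential emission layers with the degradation
#' fraction, yielding the probabilistic actual-emission map
#' (actual <= potential everywhere). Note the resulting per-class rates are
#' emissions per area of peatland, not per area of disturbed peatland.
#'
#' @param cells Cell table with `potential_min/mean/max` and `degradation`.
#' @return `cells` with `actual_min/mean/max` (t CO2-eq yr-1) appended.
#' @export
actual_emissions <- function(cells) {
  stopifnot(all(c("potential_min", "potential_mean", "potential_max",
                  "degradation") %in% names(cells)))
  if (any(cells$degradation < 0 | cells$degradation > 1, na.rm = TRUE)) {
    stop("degradation fractions outside [0, 1]")
  }
  for (layer in c("min", "mean", "max")) {
    cells[[paste0("actual_", layer)]] <-
      cells[[paste0("potential_", layer)]] * cells$degradation
  }
  cells
}

#' Summarize emissions and areas by reporting climate zone
#'
#' Aggregates a fully mapped cell table into the per-climate overview shape:
#' peatland area by land-use column (Mha), degrading area (Mha), and actual
#' emissions min/mean/max (Gt CO2-eq yr-1), with a computed totals row.
#'
#' @param cells Cell table carrying `climate` (reporting label), `landuse`,
#'   `peat`, `cell_area_ha`, `degradation` and `actual_min/mean/max`.
#' @return Data frame, one row per reporting climate present plus a
#'   `"total"` row.
#' @export
summarize_emissions <- function(cells) {
  req <- c("climate", "landuse", "peat", "cell_area_ha", "degradation",
           "actual_min", "actual_mean", "actual_max")
  stopifnot(all(req %in% names(cells)))
  acct <- cells$peat & !is.na(cells$landuse) & cells$landuse != "NONE"
  p <- cells[acct, , drop = FALSE]
  if (nrow(p) == 0) {
    zero <- data.frame(climate = "total", area_total_mha = 0,
                       area_cl_mha = 0, area_gl_mha = 0, area_fl_mha = 0,
                       area_gl_fl_mha = 0, area_cl_gl_fl_mha = 0,
                       area_degrading_mha = 0, emission_min_gt = 0,
                       emission_mean_gt = 0, emission_max_gt = 0,
                       stringsAsFactors = FALSE)
    return(zero)
  }
  by_cz <- split(p, p$climate)
  rows <- lapply(names(by_cz), function(cz) {
    g <- by_cz[[cz]]
    area_by <- function(lu) sum(g$cell_area_ha[g$landuse == lu]) / 1e6
    data.frame(
      climate = cz,
      area_total_mha = sum(g$cell_area_ha) / 1e6,
      area_cl_mha = area_by("CL"),
      area_gl_mha = area_by("GL"),
      area_fl_mha = area_by("FL"),
      area_gl_fl_mha = area_by("MIX_GL_FL"),
      area_cl_gl_fl_mha = area_by("MIX_CL_GL_FL"),
      area_degrading_mha = sum(g$cell_area_ha * g$degradation) / 1e6,
      emission_min_gt = sum(g$actual_min) / 1e9,
      emission_mean_gt = sum(g$actual_mean) / 1e9,
      emission_max_gt = sum(g$actual_max) / 1e9,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  order_pref <- c("tropical", "temperate", "boreal", "polar", "oceanic")
  out <- out[order(match(out$climate, order_pref)), , drop = FALSE]
  totals <- out[1, , drop = FALSE]
  totals$climate <- "total"
  num <- names(out)[-1]
  totals[num] <- lapply(out[num], sum)
  rbind(out, totals)
}

#' Convert CO2-equivalents to carbon-equivalents
#'
#' Rescales a CO2-eq mass to the mass of carbon it contains (x 12/44).
#' Linear, so it commutes with sums and ranges.
#'
#' @param x CO2-eq quantity (any mass unit).
#' @return The same quantity in CO2-C-eq.
#' @export
#' @examples
#' co2eq_to_ceq(1.91)  # ~0.52
co2eq_to_ceq <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * 12 / 44
}
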