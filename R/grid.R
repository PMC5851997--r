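#' @title Land-use, climate and emission-class grids
#' @description Reclassification of integer land-cover codes into the three
#'   IPCC land-use classes (plus mixed classes), cropland-probability
#'   overlay, Koppen-to-generic-climate reclassification, the 5 x 3 = 15
#'   emission classes, and proportional area rescaling. All operations are
#'   per-cell lookups on an equal-area cell table; no spatial logic.
#' @name grid_model
NULL

.landuse_levels <- c("CL", "GL", "FL", "MIX_CL_GL_FL", "MIX_GL_FL", "NONE")
.zone_levels <- c("TROPICAL", "TEMPERATE", "BOREAL_POLAR")

#' Default land-cover to land-use mapping
#'
#' ESA GLC-style integer classes mapped to IPCC land-use classes:
#' 11/14/20 cropland; 40--110 (forest mosaic), 130, 160, 170 forest land;
#' 120, 140, 150 and 190 (mixed urban) grassland; 30 the CL/GL/FL mixed
#' class; 180 the GL/FL mixed class; 200--230 (bare, water, snow/ice,
#' no-data) unassignable and excluded from accounting.
#'
#' @return Data frame with columns `code` (integer) and `landuse`.
#' @export
default_landcover_mapping <- function() {
  data.frame(
    code = c(11L, 14L, 20L,
             40L, 50L, 60L, 70L, 90L, 100L, 110L, 130L, 160L, 170L,
             120L, 140L, 150L, 190L,
             30L, 180L,
             200L, 210L, 220L, 230L),
    landuse = c(rep("CL", 3), rep("FL", 10), rep("GL", 4),
                "MIX_CL_GL_FL", "MIX_GL_FL", rep("NONE", 4)),
    stringsAsFactors = FALSE
  )
}

#' Reclassify integer land-cover codes into land-use classes
#'
#' @param codes Integer vector of land-cover class codes (one per cell).
#'   NA codes propagate to `"NONE"`.
#' @param mapping Data frame `code` -> `landuse`; defaults to
#'   [default_landcover_mapping()].
#' @return Character vector of land-use classes, one of
#'   `CL, GL, FL, MIX_CL_GL_FL, MIX_GL_FL, NONE`. Codes absent from the
#'   mapping become `"NONE"` with a warning listing them.
#' @export
#' @examples
#' reclassify_landcover(c(190L, 30L, 210L))  # GL, MIX_CL_GL_FL, NONE
reclassify_landcover <- function(codes, mapping = default_landcover_mapping()) {
  if (!is.numeric(codes)) {
    stop("land-cover codes must be numeric integers")
  }
  if (any(codes[!is.na(codes)] %% 1 != 0)) {
    stop("land-cover raster contains non-integer values")
  }
  stopifnot(all(c("code", "landuse") %in% names(mapping)),
            all(mapping$landuse %in% .landuse_levels))
  idx <- match(codes, mapping$code)
  unknown <- unique(codes[is.na(idx) & !is.na(codes)])
  if (length(unknown) > 0) {
    warning("unknown land-cover codes mapped to NONE: ",
            paste(sort(unknown), collapse = ", "))
  }
  out <- mapping$landuse[idx]
  out[is.na(out)] <- "NONE"
  out
}

#' Overlay a cropland-probability layer onto a land-use raster
#'
#' Cells whose cropland probability strictly exceeds the threshold are
#' reassigned to `CL`, superseding their prior class. Cells already excluded
#' from accounting (`NONE`: bare, water, ice) are never resurrected.
#'
#' @param landuse Character vector of land-use classes.
#' @param crop_prob Numeric vector of cropland probabilities in \[0, 1\].
#' @param threshold Discretization threshold; strict comparison. Default 0.5.
#' @return Updated land-use vector.
#' @export
overlay_cropland <- function(landuse, crop_prob, threshold = 0.5) {
  if (length(landuse) != length(crop_prob)) {
    stop("land-use and cropland-probability layers are misaligned")
  }
  bad <- !is.na(crop_prob) & (crop_prob < 0 | crop_prob > 1)
  if (any(bad)) {
    stop("cropland probabilities outside [0, 1]")
  }
  to_cl <- !is.na(crop_prob) & crop_prob > threshold & landuse != "NONE"
  landuse[to_cl] <- "CL"
  landuse
}

#' Default Koppen class to generic climate zone mapping
#'
#' Koppen classes collapsed onto three generic zones used for emission
#' factors (tropical, temperate, boreal+polar; polar and boreal share
#' emission factors but stay separable via the reporting subzone). Group A
#' and hot arid B go to tropical; group C and cold arid B to temperate
#' (subpolar-oceanic Cfc reported as oceanic); group D to boreal; group E to
#' polar. Editable: pass your own table to [reclassify_climate()].
#'
#' @return Data frame with columns `koppen`, `zone`, `subzone` (reporting
#'   subzone: `BOREAL`, `POLAR`, `OCEANIC` or NA).
#' @export
default_koppen_mapping <- function() {
  rbind(
    data.frame(koppen = c("Af", "Am", "Aw", "As", "BWh", "BSh"),
               zone = "TROPICAL", subzone = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(koppen = c("BWk", "BSk",
                          "Csa", "Csb", "Csc", "Cwa", "Cwb", "Cwc",
                          "Cfa", "Cfb"),
               zone = "TEMPERATE", subzone = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(koppen = "Cfc", zone = "TEMPERATE", subzone = "OCEANIC",
               stringsAsFactors = FALSE),
    data.frame(koppen = c("Dsa", "Dsb", "Dsc", "Dsd",
                          "Dwa", "Dwb", "Dwc", "Dwd",
                          "Dfa", "Dfb", "Dfc", "Dfd"),
               zone = "BOREAL_POLAR", subzone = "BOREAL",
               stringsAsFactors = FALSE),
    data.frame(koppen = c("ET", "EF"), zone = "BOREAL_POLAR",
               subzone = "POLAR", stringsAsFactors = FALSE)
  )
}

#' Reclassify Koppen climate classes into generic zones
#'
#' A pure per-cell lookup (the zone split is ecological, not latitudinal).
#'
#' @param koppen Character vector of Koppen class codes (one per cell).
#' @param mapping Data frame `koppen` -> `zone` (+ optional `subzone`);
#'   defaults to [default_koppen_mapping()]. Must cover every class present.
#' @return Data frame with columns `zone` (one of `TROPICAL`, `TEMPERATE`,
#'   `BOREAL_POLAR`) and `subzone` (reporting subzone or NA).
#' @export
reclassify_climate <- function(koppen, mapping = default_koppen_mapping()) {
  stopifnot(all(c("koppen", "zone") %in% names(mapping)),
            all(mapping$zone %in% .zone_levels))
  if (is.null(mapping$subzone)) mapping$subzone <- NA_character_
  idx <- match(koppen, mapping$koppen)
  missing <- unique(koppen[is.na(idx) & !is.na(koppen)])
  if (length(missing) > 0) {
    stop("unmapped Koppen classes: ", paste(sort(missing), collapse = ", "))
  }
  data.frame(zone = mapping$zone[idx], subzone = mapping$subzone[idx],
             stringsAsFactors = FALSE)
}

#' Reporting climate label from zone and subzone
#'
#' Expands the three emission-factor zones back into the five reporting
#' rows (tropical, temperate, boreal, polar, oceanic) used in summaries.
#'
#' @param zone Character vector of generic zones.
#' @param subzone Character vector of reporting subzones (or NA).
#' @return Character vector of lower-case reporting labels.
#' @export
reporting_climate <- function(zone, subzone = NA_character_) {
  subzone <- rep_len(subzone, length(zone))
  out <- character(length(zone))
  out[zone == "TROPICAL"] <- "tropical"
  out[zone == "TEMPERATE"] <- "temperate"
  out[zone == "TEMPERATE" & !is.na(subzone) & subzone == "OCEANIC"] <- "oceanic"
  out[zone == "BOREAL_POLAR"] <- "boreal"
  out[zone == "BOREAL_POLAR" & !is.na(subzone) & subzone == "POLAR"] <- "polar"
  out[is.na(zone)] <- NA_character_
  out
}

#' Build the land-use x climate emission-class raster
#'
#' Crosses the five accountable land-use classes with the three generic
#' climate zones into at most 15 emission classes, e.g. `"CL-tropical"`.
#' Cells with land use `NONE` get NA and are excluded from accounting.
#'
#' @param landuse Character vector of land-use classes.
#' @param zone Character vector of generic climate zones, same length
#'   (aligned grids).
#' @return Character vector of emission-class labels (NA for excluded cells).
#' @export
build_emission_classes <- function(landuse, zone) {
  if (length(landuse) != length(zone)) {
    stop("land-use and climate rasters are misaligned")
  }
  cls <- ifelse(landuse == "NONE" | is.na(landuse) | is.na(zone),
                NA_character_,
                paste0(landuse, "-", tolower(zone)))
  cls
}

#' All 15 possible emission-class labels
#' @return Character vector of length 15.
#' @export
emission_class_levels <- function() {
  as.vector(outer(setdiff(.landuse_levels, "NONE"),
                  tolower(.zone_levels),
                  function(l, z) paste0(l, "-", z)))
}

#' Rescale stratum areas onto a target global total
#'
#' Multiplies every stratum by `target_total / sum(areas)`, preserving all
#' proportions, so the grid total matches an externally stated global area
#' estimate.
#'
#' @param areas Numeric vector (optionally named) of stratum areas, >= 0.
#' @param target_total Target total area, > 0. Same units as `areas`.
#' @return Rescaled vector summing to `target_total`.
#' @export
#' @examples
#' rescale_areas(c(a = 200, b = 300), 463.2)
rescale_areas <- function(areas, target_total) {
  if (any(areas < 0) || anyNA(areas)) stop("areas must be non-negative")
  if (!is.numeric(target_total) || target_total <= 0) {
    stop("target total must be positive")
  }
  total <- sum(areas)
  if (total == 0) stop("total input area is zero; cannot rescale")
  areas * (target_total / total)
}

#' Classify a synthetic or imported world into an accountable peat grid
#'
#' Convenience wrapper running the full grid stage: land-cover
#' reclassification, cropland overlay, climate reclassification, reporting
#' labels and emission classes, on a cell table.
#'
#' @param cells Data frame with columns `cover` (integer land-cover code),
#'   `crop_prob`, `koppen`, plus any pass-through columns (`cell_id`,
#'   `country`, `peat`, `cell_area_ha`).
#' @param landcover_mapping,koppen_mapping Mapping tables; see
#'   [reclassify_landcover()] and [reclassify_climate()].
#' @param cropland_threshold Probability threshold for the CL overlay.
#' @return `cells` with columns `landuse`, `zone`, `subzone`, `climate`
#'   (reporting label) and `emission_class` appended.
#' @export
classify_grid <- function(cells,
                          landcover_mapping = default_landcover_mapping(),
                          koppen_mapping = default_koppen_mapping(),
                          cropland_threshold = 0.5) {
  stopifnot(all(c("cover", "crop_prob", "koppen") %in% names(cells)))
  lu <- reclassify_landcover(cells$cover, landcover_mapping)
  lu <- overlay_cropland(lu, cells$crop_prob, cropland_threshold)
  cz <- reclassify_climate(cells$koppen, koppen_mapping)
  cells$landuse <- lu
  cells$zone <- cz$zone
  cells$subzone <- cz$subzone
  cells$climate <- reporting_climate(cz$zone, cz$subzone)
  cells$emission_class <- build_emission_classes(lu, cz$zone)
  cells
}
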