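#' @title Table and configuration I/O
#' @description Readers and writers for the plain-text interchange formats
#'   the pipeline uses: CSV cell tables (the equal-area raster contract),
#'   CSV mapping and country tables, and YAML emission-factor /
#'   configuration files.
#' @name cli_io
NULL

#' Write a cell table to CSV
#'
#' @param cells Cell table (data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' @param path CSV written by [write_cell_table()] (or any cell table with
#'   at least `cell_id` and `cell_area_ha` columns).
#' @return Data frame.
#' @export
read_cell_table <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "cell_area_ha") %in% names(cells)))
  cells
}

#' Read a country degradation-statistics table from CSV
#'
#' @param path CSV with columns `country`, `peat_area_ha`,
#'   `cropland_on_peat_ha`, `degraded_area_ha`.
#' @return Data frame.
#' @export
read_country_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("country", "peat_area_ha", "cropland_on_peat_ha",
           "degraded_area_ha")
  if (!all(req %in% names(x))) {
    stop("country table must have columns: ", paste(req, collapse = ", "))
  }
  x
}

#' Read an emission-factor table from YAML or CSV
#'
#' YAML files carry a top-level `emission_factors` list (and optionally a
#' `gwp` block); CSV files carry the long-format columns directly
#' (`landuse`, `climate`, `gas`, `min`, `mean`, `max`, `unit`).
#'
#' @param path File path (`.yaml`/`.yml` or `.csv`).
#' @return Long-format emission-factor data frame. If the YAML carries a
#'   `gwp` block it is attached as attribute `"gwp"` (a [gwp_set()]).
#' @export
read_ef_table <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    rows <- y$emission_factors
    if (is.null(rows)) stop("YAML has no 'emission_factors' block")
    ef <- do.call(rbind, lapply(rows, function(r) {
      data.frame(landuse = r$landuse, climate = r$climate, gas = r$gas,
                 min = r$min, mean = r$mean, max = r$max, unit = r$unit,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(y$gwp)) {
      attr(ef, "gwp") <- gwp_set(ch4 = y$gwp$ch4, n2o = y$gwp$n2o,
                                 horizon = y$gwp$horizon %||% "GWP100")
    }
    ef
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged default emission-factor table
#'
#' Loads the emission-factor table shipped with the package
#' (`extdata/ef_wetlands_synthetic.yaml`): per-gas min/mean/max annual
#' fluxes for drained organic soils by land use and generic climate zone.
#' The values are synthetic stand-ins at the scale of the IPCC wetlands
#' emission factors, intended for exercising the pipeline; substitute your
#' own table for real inventory work.
#'
#' @return Long-format emission-factor data frame (see [read_ef_table()]).
#' @export
default_ef_table <- function() {
  path <- system.file("extdata", "ef_wetlands_synthetic.yaml",
                      package = "peatbudget", mustWork = TRUE)
  read_ef_table(path)
}
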