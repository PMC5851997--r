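#' @title Synthetic world and sample generators
#' @description Seed-deterministic generators for every input the pipeline
#'   consumes: an equal-area cell world (peat extent, land cover, cropland
#'   probability, Koppen climate, countries and their degradation
#'   statistics) and C/N sample tables with planted filter violations. They
#'   emulate the statistical structure of the real GIS and soil-profile
#'   sources, not their spatial realism.
#' @name synthetic_data
NULL

.codes_by_group <- list(
  CL = c(11L, 14L, 20L),
  GL = c(120L, 140L, 150L, 190L),
  FL = c(40L, 50L, 60L, 70L, 90L, 100L, 110L, 130L, 160L, 170L),
  MIX_CL_GL_FL = 30L,
  MIX_GL_FL = 180L,
  NONE = c(200L, 210L, 220L, 230L)
)

.koppen_by_band <- list(
  polar = "ET",
  boreal = c("Dfb", "Dfc"),
  temperate = c("Cfa", "Cfb"),
  tropical = c("Af", "Am", "Aw")
)

#' Specification of a synthetic world
#'
#' @param seed Integer RNG seed; all generation is deterministic given it.
#' @param nrow,ncol Grid dimensions (rows are climate bands, pole to
#'   equator).
#' @param n_countries Number of countries (contiguous column blocks).
#' @param cell_area_ha Uniform cell area (equal-area contract), ha.
#' @param climate_bands Named fractions of rows per band (polar, boreal,
#'   temperate, tropical), summing to 1.
#' @param peat_fraction Named per-band probability that a cell is peat.
#' @param landuse_weights Named sampling weights of land-cover groups
#'   (`CL`, `GL`, `FL`, `MIX_CL_GL_FL`, `MIX_GL_FL`, `NONE`), summing
#'   to 1.
#' @param extra_cropland Probability that a non-cropland accountable cell
#'   carries a high cropland probability (so the overlay flips it to CL).
#' @param degradation_targets Per-country target degradation ratios in
#'   \[0, 1\], recycled over countries; the defaults exercise both
#'   allocation branches (targets below and above realized cropland
#'   ratios).
#' @return List of class `world_spec`.
#' @export
world_spec <- function(seed = 42L, nrow = 96L, ncol = 96L,
                       n_countries = 6L, cell_area_ha = 1000,
                       climate_bands = c(polar = 0.10, boreal = 0.40,
                                         temperate = 0.20,
                                         tropical = 0.30),
                       peat_fraction = c(polar = 0.35, boreal = 0.55,
                                         temperate = 0.20,
                                         tropical = 0.25),
                       landuse_weights = c(CL = 0.10, GL = 0.22,
                                           FL = 0.54,
                                           MIX_CL_GL_FL = 0.02,
                                           MIX_GL_FL = 0.04,
                                           NONE = 0.08),
                       extra_cropland = 0.03,
                       degradation_targets = c(0.05, 0.6, 0.3,
                                               0.75, 0.02, 0.45)) {
  stopifnot(nrow >= 4, ncol >= n_countries, n_countries >= 1,
            cell_area_ha > 0,
            abs(sum(climate_bands) - 1) < 1e-9,
            all(names(.koppen_by_band) %in% names(climate_bands)),
            all(peat_fraction >= 0 & peat_fraction <= 1),
            all(landuse_weights >= 0),
            abs(sum(landuse_weights) - 1) < 1e-9,
            extra_cropland >= 0 && extra_cropland <= 1,
            all(degradation_targets >= 0 & degradation_targets <= 1))
  structure(list(seed = as.integer(seed), nrow = as.integer(nrow),
                 ncol = as.integer(ncol),
                 n_countries = as.integer(n_countries),
                 cell_area_ha = cell_area_ha,
                 climate_bands = climate_bands,
                 peat_fraction = peat_fraction,
                 landuse_weights = landuse_weights,
                 extra_cropland = extra_cropland,
                 degradation_targets = degradation_targets),
            class = "world_spec")
}

#' Generate a synthetic world
#'
#' Produces the full input stack on one equal-area cell table: climate
#' bands of Koppen codes, contiguous countries, a peat mask, land-cover
#' codes drawn from the group weights, and a cropland-probability layer
#' constructed so the 0.5 overlay threshold recovers intended cropland.
#' The country statistics table is made consistent with the generated
#' maps: cropland-on-peat areas are computed from the classified grid and
#' degraded areas from the spec's target ratios.
#'
#' @param spec A [world_spec()].
#' @return List of class `peat_world` with elements `cells` (cell table:
#'   `cell_id`, `row`, `col`, `country`, `koppen`, `peat`, `cover`,
#'   `crop_prob`, `cell_area_ha`), `countries` (columns `country`,
#'   `peat_area_ha`, `cropland_on_peat_ha`, `degraded_area_ha`) and
#'   `spec`.
#' @export
generate_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  n <- spec$nrow * spec$ncol
  row <- rep(seq_len(spec$nrow), each = spec$ncol)
  col <- rep(seq_len(spec$ncol), times = spec$nrow)

  # climate bands: split rows by the stated fractions, pole to equator
  band_names <- c("polar", "boreal", "temperate", "tropical")
  band_rows <- round(cumsum(spec$climate_bands[band_names]) * spec$nrow)
  band_of_row <- cut(seq_len(spec$nrow), breaks = c(0, band_rows),
                     labels = band_names)
  band <- as.character(band_of_row)[row]
  koppen <- vapply(band, function(b) {
    pool <- .koppen_by_band[[b]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))

  country <- paste0("C", cut(col, breaks = spec$n_countries,
                             labels = FALSE))
  peat <- stats::runif(n) < spec$peat_fraction[band]

  groups <- names(spec$landuse_weights)
  grp <- sample(groups, n, replace = TRUE, prob = spec$landuse_weights)
  cover <- vapply(grp, function(g) {
    pool <- .codes_by_group[[g]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))

  # cropland probability: high on cropland-coded cells and on a small
  # fraction of other accountable cells (the overlay flips those to CL)
  high <- grp == "CL" |
    (grp != "NONE" & stats::runif(n) < spec$extra_cropland)
  crop_prob <- ifelse(high, stats::runif(n, 0.55, 0.95),
                      stats::runif(n, 0.02, 0.45))

  cells <- data.frame(
    cell_id = seq_len(n), row = row, col = col,
    country = country, koppen = koppen, peat = peat,
    cover = cover, crop_prob = crop_prob,
    cell_area_ha = spec$cell_area_ha,
    stringsAsFactors = FALSE
  )

  # country statistics consistent with the generated maps
  classified <- classify_grid(cells)
  on_peat <- classified$peat & classified$landuse != "NONE"
  ids <- paste0("C", seq_len(spec$n_countries))
  # country statistics refer to accountable peat (excluding bare/water/ice
  # cells, which never enter the degradation accounting)
  peat_area <- vapply(ids, function(cid) {
    sum(cells$cell_area_ha[on_peat & classified$country == cid])
  }, numeric(1))
  crop_area <- vapply(ids, function(cid) {
    sum(classified$cell_area_ha[on_peat & classified$landuse == "CL" &
                                  classified$country == cid])
  }, numeric(1))
  targets <- rep_len(spec$degradation_targets, spec$n_countries)
  countries <- data.frame(
    country = ids,
    peat_area_ha = peat_area,
    cropland_on_peat_ha = crop_area,
    degraded_area_ha = targets * peat_area,
    stringsAsFactors = FALSE
  )
  # a country with no accountable peat has no statistics record
  countries <- countries[countries$peat_area_ha > 0, , drop = FALSE]
  structure(list(cells = cells, countries = countries, spec = spec),
            class = "peat_world")
}

#' Run the full accounting pipeline on a world
#'
#' Classification, degradation allocation and mapping, potential and
#' actual emission mapping, and the per-climate summary, in one call.
#'
#' @param world A `peat_world` from [generate_world()].
#' @param ef Long-format per-gas emission-factor table (default the
#'   packaged table, [default_ef_table()]).
#' @param gwp A [gwp_set()].
#' @return List with `cells` (fully mapped cell table), `assignments`
#'   (per-country degradation fractions) and `summary` (per-climate
#'   overview with totals row).
#' @export
account_world <- function(world, ef = default_ef_table(),
                          gwp = gwp_set()) {
  stopifnot(inherits(world, "peat_world"))
  cells <- classify_grid(world$cells)
  assignments <- allocate_degradation(world$countries)
  cells <- build_degradation_map(cells, assignments)
  lookup <- build_ef_lookup(ef, gwp)
  cells <- potential_emissions(cells, lookup)
  cells <- actual_emissions(cells)
  list(cells = cells, assignments = assignments,
       summary = summarize_emissions(cells))
}

#' Specification of a C/N sample population
#'
#' @param median_cn Target median C/N of the clean subpopulation. The
#'   sampling family is log-normal (strictly positive, right-skewed, as
#'   observed peat and mineral C/N distributions are).
#' @param sdlog Log-scale spread of the clean population.
#' @param conc_range Range of organic C concentrations (mg g-1) for clean
#'   records; must stay at or below the 200 mg g-1 filter bound.
#' @param contamination Either a single rate in \[0, 1\] split equally over
#'   the four violation kinds, or a named vector with entries `histosol`,
#'   `cn_low`, `cn_high`, `conc_high` summing to <= 1. Each contaminated
#'   record violates exactly its own filter rule.
#' @param label Population label stored on the samples.
#' @return List of class `cn_spec`.
#' @export
cn_spec <- function(median_cn = 10.7, sdlog = 0.3,
                    conc_range = c(5, 150), contamination = 0,
                    label = "mineral") {
  stopifnot(median_cn > 0, sdlog > 0,
            length(conc_range) == 2, conc_range[1] >= 0,
            conc_range[2] <= 200, conc_range[1] <= conc_range[2])
  kinds <- c("histosol", "cn_low", "cn_high", "conc_high")
  if (length(contamination) == 1 && is.null(names(contamination))) {
    stopifnot(contamination >= 0, contamination <= 1)
    contamination <- stats::setNames(rep(contamination / 4, 4), kinds)
  } else {
    stopifnot(all(names(contamination) %in% kinds),
              all(contamination >= 0), sum(contamination) <= 1)
    full <- stats::setNames(numeric(4), kinds)
    full[names(contamination)] <- contamination
    contamination <- full
  }
  structure(list(median_cn = median_cn, sdlog = sdlog,
                 conc_range = conc_range, contamination = contamination,
                 label = label),
            class = "cn_spec")
}

#' Generate a C/N sample table
#'
#' Clean records draw C/N from a log-normal centred on the target median
#' and concentrations inside the admissible range; contaminated records
#' are planted violators of the three exclusion rules (Histosol flag, C/N
#' outside \[5, 100\], concentration > 200 mg g-1), so that
#' [filter_cn_samples()] removes exactly the planted set.
#'
#' @param spec A [cn_spec()].
#' @param n Number of samples, >= 1.
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `sample_id`, `population`, `kind`
#'   (`clean` or the violation kind), `histosol`, `organic_c_mg_g`, `cn`.
#' @export
generate_cn_samples <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "cn_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  kinds <- c("clean", names(spec$contamination))
  probs <- c(1 - sum(spec$contamination), spec$contamination)
  kind <- sample(kinds, n, replace = TRUE, prob = probs)
  cn <- stats::rlnorm(n, meanlog = log(spec$median_cn),
                      sdlog = spec$sdlog)
  # keep clean draws inside the admissible C/N window
  cn <- pmin(pmax(cn, 5.01), 99.9)
  conc <- stats::runif(n, spec$conc_range[1], spec$conc_range[2])
  histosol <- kind == "histosol"
  cn[kind == "cn_low"] <- stats::runif(sum(kind == "cn_low"), 0.5, 4.9)
  cn[kind == "cn_high"] <- stats::runif(sum(kind == "cn_high"), 101, 400)
  conc[kind == "conc_high"] <- stats::runif(sum(kind == "conc_high"),
                                            201, 600)
  data.frame(
    sample_id = seq_len(n), population = spec$label, kind = kind,
    histosol = histosol, organic_c_mg_g = conc, cn = cn,
    stringsAsFactors = FALSE
  )
}
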