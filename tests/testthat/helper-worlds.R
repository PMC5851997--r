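# Shared fixtures built in code: a small synthetic world and the
# aggregated reference table.

small_world <- function(seed = 11, nrow = 48, ncol = 48, ...) {
  generate_world(world_spec(seed = seed, nrow = nrow, ncol = ncol, ...))
}

# closed-form expected potential emission (t CO2-eq / yr) from the world
# spec's composition targets and an emission-class rate lookup: an
# analytic oracle independent of the cell-level pipeline
closed_form_potential <- function(spec, lookup, layer = "mean") {
  zone_of_band <- c(polar = "boreal_polar", boreal = "boreal_polar",
                    temperate = "temperate", tropical = "tropical")
  total_area <- spec$nrow * spec$ncol * spec$cell_area_ha
  w <- spec$landuse_weights
  acct <- setdiff(names(w), c("CL", "NONE"))
  w_eff <- w
  w_eff["CL"] <- w["CL"] + spec$extra_cropland * sum(w[acct])
  w_eff[acct] <- w[acct] * (1 - spec$extra_cropland)
  out <- 0
  for (b in names(spec$climate_bands)) {
    peat_area <- total_area * spec$climate_bands[[b]] *
      spec$peat_fraction[[b]]
    for (g in setdiff(names(w), "NONE")) {
      cls <- paste0(g, "-", zone_of_band[[b]])
      rate <- lookup[[paste0("co2eq_", layer)]][
        lookup$emission_class == cls]
      out <- out + peat_area * w_eff[[g]] * rate
    }
  }
  out
}

# independent brute-force re-implementation of the three C/N exclusion
# predicates, used as the filtering oracle
brute_filter_cn <- function(samples) {
  keep <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    keep[i] <- !isTRUE(s$histosol) &&
      s$cn >= 5 && s$cn <= 100 &&
      s$organic_c_mg_g <= 200
  }
  samples[keep, , drop = FALSE]
}
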