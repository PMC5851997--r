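# Synthetic stand-in emission-factor table for drained organic soils.
# Per-gas annual fluxes by land use (CL cropland, GL grassland, FL forest
# land) and generic climate zone, each with an explicit min/mean/max range
# (treated as a uniform band, not a confidence interval). Magnitudes follow
# the IPCC wetlands emission-factor scale; values are stand-ins for
# exercising the pipeline, not inventory-grade numbers.
# Units: CO2 and DOC as t C per ha per year; CH4 as kg CH4 per ha per year;
# N2O as kg N2O-N per ha per year.
gwp:
  ch4: 28
  n2o: 265
  horizon: GWP100
emission_factors:
  # --- cropland ---
  - {landuse: CL, climate: TROPICAL,     gas: CO2, unit: t C/ha/yr,     min: 6.0,  mean: 14.0, max: 22.0}
  - {landuse: CL, climate: TROPICAL,     gas: CH4, unit: kg CH4/ha/yr,  min: 0.0,  mean: 7.0,  max: 14.0}
  - {landuse: CL, climate: TROPICAL,     gas: N2O, unit: kg N2O-N/ha/yr, min: 2.0, mean: 5.0,  max: 8.0}
  - {landuse: CL, climate: TROPICAL,     gas: DOC, unit: t C/ha/yr,     min: 0.4,  mean: 0.82, max: 1.3}
  - {landuse: CL, climate: TEMPERATE,    gas: CO2, unit: t C/ha/yr,     min: 6.5,  mean: 7.9,  max: 9.4}
  - {landuse: CL, climate: TEMPERATE,    gas: CH4, unit: kg CH4/ha/yr,  min: 0.0,  mean: 0.5,  max: 1.0}
  - {landuse: CL, climate: TEMPERATE,    gas: N2O, unit: kg N2O-N/ha/yr, min: 8.0, mean: 13.0, max: 18.0}
  - {landuse: CL, climate: TEMPERATE,    gas: DOC, unit: t C/ha/yr,     min: 0.15, mean: 0.31, max: 0.5}
  - {landuse: CL, climate: BOREAL_POLAR, gas: CO2, unit: t C/ha/yr,     min: 6.5,  mean: 7.9,  max: 9.4}
  - {landuse: CL, climate: BOREAL_POLAR, gas: CH4, unit: kg CH4/ha/yr,  min: 0.0,  mean: 0.5,  max: 1.0}
  - {landuse: CL, climate: BOREAL_POLAR, gas: N2O, unit: kg N2O-N/ha/yr, min: 8.0, mean: 13.0, max: 18.0}
  - {landuse: CL, climate: BOREAL_POLAR, gas: DOC, unit: t C/ha/yr,     min: 0.05, mean: 0.12, max: 0.2}
  # --- grassland ---
  - {landuse: GL, climate: TROPICAL,     gas: CO2, unit: t C/ha/yr,     min: 4.8,  mean: 9.6,  max: 14.3}
  - {landuse: GL, climate: TROPICAL,     gas: CH4, unit: kg CH4/ha/yr,  min: 2.0,  mean: 7.0,  max: 12.0}
  - {landuse: GL, climate: TROPICAL,     gas: N2O, unit: kg N2O-N/ha/yr, min: 2.0, mean: 5.0,  max: 8.0}
  - {landuse: GL, climate: TROPICAL,     gas: DOC, unit: t C/ha/yr,     min: 0.4,  mean: 0.82, max: 1.3}
  - {landuse: GL, climate: TEMPERATE,    gas: CO2, unit: t C/ha/yr,     min: 2.0,  mean: 5.3,  max: 8.0}
  - {landuse: GL, climate: TEMPERATE,    gas: CH4, unit: kg CH4/ha/yr,  min: 5.0,  mean: 16.0, max: 30.0}
  - {landuse: GL, climate: TEMPERATE,    gas: N2O, unit: kg N2O-N/ha/yr, min: 4.0, mean: 8.2,  max: 12.0}
  - {landuse: GL, climate: TEMPERATE,    gas: DOC, unit: t C/ha/yr,     min: 0.15, mean: 0.31, max: 0.5}
  - {landuse: GL, climate: BOREAL_POLAR, gas: CO2, unit: t C/ha/yr,     min: 2.9,  mean: 5.7,  max: 8.6}
  - {landuse: GL, climate: BOREAL_POLAR, gas: CH4, unit: kg CH4/ha/yr,  min: 0.0,  mean: 1.4,  max: 4.0}
  - {landuse: GL, climate: BOREAL_POLAR, gas: N2O, unit: kg N2O-N/ha/yr, min: 4.0, mean: 9.5,  max: 15.0}
  - {landuse: GL, climate: BOREAL_POLAR, gas: DOC, unit: t C/ha/yr,     min: 0.05, mean: 0.12, max: 0.2}
  # --- forest land ---
  - {landuse: FL, climate: TROPICAL,     gas: CO2, unit: t C/ha/yr,     min: 2.0,  mean: 5.3,  max: 9.0}
  - {landuse: FL, climate: TROPICAL,     gas: CH4, unit: kg CH4/ha/yr,  min: 0.0,  mean: 5.0,  max: 10.0}
  - {landuse: FL, climate: TROPICAL,     gas: N2O, unit: kg N2O-N/ha/yr, min: 1.0, mean: 2.4,  max: 4.0}
  - {landuse: FL, climate: TROPICAL,     gas: DOC, unit: t C/ha/yr,     min: 0.4,  mean: 0.82, max: 1.3}
  - {landuse: FL, climate: TEMPERATE,    gas: CO2, unit: t C/ha/yr,     min: 1.0,  mean: 2.6,  max: 4.5}
  - {landuse: FL, climate: TEMPERATE,    gas: CH4, unit: kg CH4/ha/yr,  min: 0.0,  mean: 2.5,  max: 6.0}
  - {landuse: FL, climate: TEMPERATE,    gas: N2O, unit: kg N2O-N/ha/yr, min: 1.0, mean: 2.8,  max: 5.0}
  - {landuse: FL, climate: TEMPERATE,    gas: DOC, unit: t C/ha/yr,     min: 0.15, mean: 0.31, max: 0.5}
  - {landuse: FL, climate: BOREAL_POLAR, gas: CO2, unit: t C/ha/yr,     min: 0.2,  mean: 0.6,  max: 1.2}
  - {landuse: FL, climate: BOREAL_POLAR, gas: CH4, unit: kg CH4/ha/yr,  min: 1.0,  mean: 4.5,  max: 9.0}
  - {landuse: FL, climate: BOREAL_POLAR, gas: N2O, unit: kg N2O-N/ha/yr, min: 0.0, mean: 0.22, max: 0.5}
  - {landuse: FL, climate: BOREAL_POLAR, gas: DOC, unit: t C/ha/yr,     min: 0.05, mean: 0.12, max: 0.2}
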