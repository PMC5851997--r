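---
title: "Methods: peatland greenhouse-gas and nitrogen accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peatland greenhouse-gas and nitrogen accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatbudget)
```

## The accounting model

Drained (degraded) peatlands lose carbon and nitrogen through microbial
peat oxidation (CO~2~), leached dissolved organic carbon (DOC, assumed
fully oxidized downstream), CH~4~ and N~2~O. The package quantifies these
losses with the standard emission-factor approach: a prescribed annual
flux per hectare for every gas, specific to a land-use class (cropland CL,
grassland GL, forest land FL, plus two mixed classes where land cover
cannot be assigned uniquely) crossed with a generic climate zone
(tropical, temperate, boreal+polar), giving 5 × 3 = 15 emission classes.
Peat-fire and mined-peat combustion fluxes are deliberately excluded.

The chain of per-cell lookups is:

1. **Land-use reclassification.** ESA-GLC-style integer codes map onto
   the land-use classes (11/14/20 → CL; the forest-mosaic codes → FL;
   120/140/150 and mixed-urban 190 → GL; 30 → CL/GL/FL mix; 180 → GL/FL
   mix; 200–230 unassignable and excluded). Unknown codes fall back to
   the excluded class with a warning rather than failing, so dialectal
   rasters still run.
2. **Cropland overlay.** A cropland-probability layer is discretized at
   0.5; cells *strictly above* the threshold become CL ("higher
   probability" reads as a strict inequality; a cell at exactly 0.5 keeps
   its class). Excluded cells (water, bare, ice) are never resurrected by
   the overlay, because they were disregarded before the overlay step.
3. **Climate reclassification.** Köppen classes collapse onto the three
   generic zones by a purely ecological per-class lookup (no latitude
   logic). The shipped default maps group A and hot-arid B to tropical,
   group C and cold-arid B to temperate, D to boreal and E to polar;
   polar and boreal share emission factors but remain separable as
   reporting subzones, and subpolar-oceanic Cfc is reported as "oceanic".
   The B-group split is an editable design choice: the generic-zone
   targets are standard, the per-class assignment is not prescribed
   anywhere, so the mapping ships as a replaceable table.
4. **Degradation allocation.** Within each country, cropland on peat is
   assumed fully degrading (fraction 1). With cropland/peat ratio `c` and
   reported country degradation ratio `d`: if `d ≤ c` the cropland area
   is taken as the better estimate and no other class degrades; if
   `d > c` the residual degraded area `(d − c) · peat_area` is spread
   uniformly over all non-cropland accountable peat, mixed classes
   included. This conserves each country's reported degraded area at
   cell level exactly (to 1e−6 relative) whenever `d > c`. Fractions are
   clipped at 1 with a warning when statistics are internally
   inconsistent, and countries missing from the statistics table default
   to 0 outside cropland (the conservative, non-degraded end) with a
   warning.
5. **Emission mapping.** Potential emission per cell = CO~2~-eq rate ×
   area (the flux if the cell were drained); actual emission = potential
   × degradation fraction. Reported per-class rates are therefore per
   area of *peatland*, not per area of disturbed peatland.

### Uncertainty treatment

Emission-factor uncertainty is an explicit min/mean/max **range** treated
as a uniform band, never a confidence interval. Interval arithmetic
propagates it: minima combine with minima, maxima with maxima, so
`min ≤ mean ≤ max` is preserved by aggregation, mixing, mapping and
summarizing (property-tested). Mixed-class factors take the unweighted
mean of member means and the **envelope** of member ranges — the widest
defensible reading of "a combination", consistent with the conservative
range treatment.

CO~2~-equivalents combine the gases as

co2eq = CO2 + gwp~CH4~·CH4 + gwp~N2O~·N2O + (44/12)·DOC,

with DOC counted as fully oxidized leached carbon. The default GWPs
(CH~4~ 28, N~2~O 265; 100-year horizon, no feedbacks) are configuration,
not code, since inventory practice varies; they sit alongside the
emission factors in the packaged YAML. The shipped emission-factor table
(`ef_wetlands_synthetic.yaml`) carries synthetic stand-in values at the
scale of the IPCC wetlands factors — adequate for exercising and testing
the pipeline, replaceable for real inventory work. All exact headline
numbers are instead computed from the packaged per-climate reference
aggregates (`global_peat_aggregates()`), which is why they are reproducible
without any GIS input.

## Carbon/nitrogen budgets

Nitrogen follows carbon through C/N mass ratios: N = C / (C/N). Zone
medians are configured constants — tropical peat 29.7, northern
(temperate + boreal + polar) peat 49.0, mineral-soil organic matter
10.7 — because the underlying soil-profile databases are out of scope;
the *computation path* (filtering and medians) is fully implemented and
exercised on generated sample tables. The mineral-soil filter excludes
records that are Histosols, have C/N outside [5, 100], or have organic C
concentration above 200 mg g⁻¹. The three rules are read as independent
OR-ed exclusions: the sentence defining them is grammatically ambiguous,
but the stated intent (analytical errors *or* unclassified organic soils)
only makes sense if any single violation excludes a record.

Mineral-soil sequestration of `S` Gt C immobilizes `S / 10.7` Gt N
(0.0935 kg N per kg C; reported elsewhere as 0.094 from unrounded
inputs). The nitrogen cost ratio compares that unit cost with the
nitrogen released per unit carbon emitted from degrading peat; from the
printed aggregates it evaluates to ≈3.28 (reported as 3.4 from unrounded
simulation values — recomputation from rounded inputs cannot do better,
and the package reports its own computed value).

## Trajectories, sink curve and scenario

**Peat side.** Each climate class emits at its constant C-eq rate until
its degrading C pool is exhausted, then stops (linear depletion). The
emission factors are constant per-area rates and no decay form is
prescribed, so constant-rate-until-exhaustion is the minimal model whose
end points equal the degrading stocks. The full all-GHG C-eq flux draws
down the carbon pool, matching the units of the cumulative plots
(Gt CO~2~-C-eq with end points at the C stocks).

**Mineral side.** The sequestration curve is a saturating function that
is 0 at t = 0, nondecreasing, reaches its maximum S_max at T_seq = 63
years and stays flat. The exact calibrated equation behind the published
24–64 Gt C / 63 y figures is not reproduced in the source material, so
the default form is exponential saturation normalized to hit S_max
exactly at T_seq (raw exponential within 1% of saturation there), and
the shape is pluggable: any nondecreasing shape on [0, 1] can be dropped
in. S_max layers default to {24, 44, 64} Gt C — the published range and
its midpoint, already including the prudential ±1/5 margin on the
calibrated ends.

**Equivalence points.** The equivalence point is the first year at which
cumulative peat emissions catch up with the cumulative sink, linearly
interpolated between steps; `Inf` flags no crossing within the horizon.
Layers are paired as an **envelope** by default (earliest crossing:
fastest emissions vs smallest sink; latest: slowest vs largest), which
makes the reported range bracket the possible crossings; matched-layer
pairing is available as an option. Because the sink equation is an
approximation, the published equivalence years (238 (140–1021) y
baseline, 104 (67–374) y scenario) are **not** reproduced numerically;
the package instead asserts the properties any valid calibration must
satisfy: the mean crossing exists, exceeds 63 y, is finite, decreases
when emission rates increase, increases with S_max, and moves < 1% when
the time step is halved. With the default sink the mean baseline
crossing is ≈84 y.

**Expansion scenario.** Degraded area grows by a Michaelis–Menten
multiplier `1 + (m − 1)·t/(t + K)` with K = 60 y and asymptote m = 2.
The stated "half saturation, i.e. a doubling within 60 years" is
internally contradictory with the scenario's doubled cumulative totals
(a multiplier reaching 2 at its half-saturation point would approach 3);
the package honors the cumulative totals (asymptotically 2 × the
baseline stocks, 161.6 Gt C and 4.6 Gt N) and places half of the *added*
area at K. Newly added area enters as scaled vintages of the baseline
class mix, each depleting its own pools from its own start date, so the
scenario dominates the baseline everywhere and never exceeds
`multiplier(t) ×` total stock.

## The synthetic world

`generate_world()` emulates the statistical structure the pipeline
assumes, not geography: latitudinal Köppen bands (polar 10%, boreal 40%,
temperate 20%, tropical 30% of rows), per-band peat probabilities
(0.35/0.55/0.20/0.25 — peat-rich high latitudes, a smaller tropical
share), land-cover codes drawn from group weights (10% CL, 22% GL, 54%
FL, 6% mixed, 8% unassignable — a forestry-dominated peat landscape),
countries as contiguous column blocks, and a cropland-probability layer
constructed so the 0.5 threshold recovers intended cropland (plus 3% of
other accountable cells, exercising the overlay). Country statistics are
derived *from the generated maps* (cropland-on-peat computed after
classification; degraded areas from per-country target ratios chosen to
exercise both allocation branches). Everything is deterministic given
the seed. Default grids are 48²–96² cells in tests and 256² in the
analysis scripts and acceptance checks, keeping full-pipeline runs in
seconds.

What it does **not** emulate: spatial autocorrelation, peat-basin
shapes, realistic country-size distributions, or co-variation of climate
and land use. Passing end-to-end tests therefore demonstrates the
correctness of the accounting arithmetic under known composition, not
fidelity to any real landscape. C/N samples are log-normal (strictly
positive, right-skewed, matching observed peat C/N ranges of roughly
12–217) with planted filter violations; clean draws are confined to the
admissible C/N window so the filter removes exactly the planted set.

## Numerical choices and degenerate inputs

- Strict `>` at the cropland threshold; ties keep the prior class.
- Degradation ratios and allocation fractions clip into [0, 1];
  impossible allocations (all peat is cropland yet `d > c`) raise errors.
- `rescale_areas()` preserves pairwise ratios to 1e−9 relative error and
  refuses a zero input total.
- Zero-area, zero-stock and empty-grid cases return zeros rather than
  NaN throughout; empty C/N sample sets are an error for medians.
- Trajectory conservation (cumulative ≤ pools) holds at machine
  precision because the cap is applied analytically (`pmin(rate·t,
  pool)`), not by stepwise integration; dt only discretizes the crossing
  search.
- Time steps: dt = 0.5 y over 1500 y by default; a warning fires when dt
  is too coarse to resolve the expansion schedule (dt > K/10).

## Known limitations

- The mineral-sink functional form approximates an unpublished
  calibration; equivalence years are therefore qualitative (property-
  constrained), not reproductions.
- Emission factors ship as synthetic stand-ins; inventory-grade results
  require substituting the official per-gas tables.
- Rewetting dynamics, restoration transitions, N₂O penalties of
  fertilization, peat fires and radiative-forcing-over-time metrics are
  out of scope.
- The equal-area contract replaces projection handling: the pipeline
  trusts `cell_area_ha` and performs no geodesy.
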