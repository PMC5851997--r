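# peatbudget

Greenhouse-gas and nitrogen accounting for degrading peatlands.

Drained peatlands turn from long-term carbon sinks into sources of CO₂,
CH₄, N₂O and leached dissolved organic carbon (DOC). `peatbudget`
implements a global-inventory-style accounting pipeline for these
emissions and compares the mitigation value of peatland restoration with
carbon sequestration in agricultural mineral soils — including its
nitrogen cost, since building mineral-soil organic matter at a narrow
C/N ratio (~10.7) immobilizes far more nitrogen per unit carbon than
peat (C/N ≈ 30–49) releases.

It is written for ecosystem biogeochemists and carbon-accounting
practitioners who want a tested, inspectable implementation of:

- **Emission classes.** Land-cover codes reclassified to IPCC land-use
  classes (CL, GL, FL + two mixed classes), a cropland-probability
  overlay at a strict 0.5 threshold, and Köppen climate collapsed to
  tropical / temperate / boreal+polar: 5 × 3 = 15 classes on an
  equal-area cell table.
- **Degradation allocation.** Per country, cropland on peat is fully
  degrading; the residual reported degraded area is spread uniformly
  over the other land-use classes, conserving national statistics at
  cell level.
- **Emission maps with ranges.** Potential emissions (EF × area) and
  actual emissions (× degradation fraction), each as min/mean/max
  layers combined by interval arithmetic:
  `co2eq = CO2 + gwp_CH4·CH4 + gwp_N2O·N2O + (44/12)·DOC`.
- **C/N budgets.** Sample filtering (no Histosols, C/N in [5, 100],
  organic C ≤ 200 mg g⁻¹), medians, N = C / (C/N) stocks and releases,
  and the nitrogen demand of mineral-soil sequestration.
- **Trajectories.** Cumulative peat emissions with pool exhaustion
  (constant rate until the class stock is gone) against a saturating
  mineral-soil sink (24–64 Gt C within 63 years), their equivalence
  points, and a Michaelis–Menten doubling scenario for the degraded
  area (K = 60 y).
- **A synthetic world.** Seed-deterministic generators for every input
  layer, so the whole pipeline runs offline and is testable against
  closed-form oracles.

## Worked example

```r
library(peatbudget)

# global budgets from the packaged per-climate reference aggregates
fix <- global_peat_aggregates()
sum(fix$emission_mean_gt)              # 1.91  Gt CO2-eq per year
sum(fix$emission_max_gt)               # 3.38
co2eq_to_ceq(sum(fix$emission_mean_gt))# 0.521 Gt CO2-C-eq per year

b <- climate_budgets()                 # attach zone C/N medians
total_n_release(b)                     # 2.298 Gt N avoidable release
b$n_stock_gt[b$climate == "tropical"]  # 4.013 Gt N in tropical peat

# equivalence between cumulative peat emissions and the mineral sink
ea <- equivalence_analysis(emission_pools(), horizon = 1500, dt = 0.5)
subset(ea$equivalence, case == "baseline" & layer == "mean")$year
#> 84.47  (years; with the package's default sink calibration)

# a full synthetic-world accounting run
acc <- account_world(generate_world(world_spec(seed = 1)))
acc$summary[acc$summary$climate == "total", "emission_mean_gt"]
```

The first block reproduces the headline global numbers: degrading
peatlands emit 1.91 (0.31–3.38) Gt CO₂-eq a⁻¹ and hold 2.3 Gt of
avoidable nitrogen release; doubling the exploited area doubles the
asymptotic cumulative release (`scenario_asymptote(80.8)` → 161.6 Gt C).
The equivalence year says when cumulative peat emissions overtake the
cumulative mineral-soil sink if both run at full capacity.

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write tables
under `results/` (large cell tables under `scratch/`):

```sh
Rscript analysis/01_build_world.R        # synthetic input stack
Rscript analysis/02_account_emissions.R  # classes, degradation, emission maps, summary
Rscript analysis/03_nitrogen_budget.R    # C/N budgets, mineral N demand, filtering demo
Rscript analysis/04_trajectories.R       # trajectories, equivalence, scenario, figure
```

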