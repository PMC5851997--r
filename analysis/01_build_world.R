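#!/usr/bin/env Rscript
# Step 1: generate the synthetic study world.
#
# Builds a seed-deterministic equal-area cell world emulating the input
# stack of a global peatland inventory: a peat mask, ESA-GLC-style land
# cover, a cropland-probability layer, Koppen climate codes, contiguous
# countries and their degradation statistics. Writes the cell table and
# country table under results/.

suppressPackageStartupMessages(library(peatbudget))

dir.create("results", showWarnings = FALSE)
spec <- world_spec(seed = 20260920, nrow = 256, ncol = 256)
world <- generate_world(spec)

cells <- world$cells
peat_share <- sum(cells$cell_area_ha[cells$peat]) / sum(cells$cell_area_ha)
message(sprintf("world: %d cells, %.1f%% peat, %d countries",
                nrow(cells), 100 * peat_share, nrow(world$countries)))
message("per-country statistics (ha):")
print(world$countries, row.names = FALSE)

dir.create("scratch", showWarnings = FALSE)
write_cell_table(cells, "scratch/world_cells.csv")
utils::write.csv(world$countries, "results/world_countries.csv",
                 row.names = FALSE)
message("wrote scratch/world_cells.csv and results/world_countries.csv")
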