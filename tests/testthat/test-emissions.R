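ef_row <- function(landuse, climate, gas, v, unit) {
  data.frame(landuse = landuse, climate = climate, gas = gas,
             min = v[1], mean = v[2], max = v[3], unit = unit)
}

test_that("CO2-eq aggregation applies GWPs, carbon conversion and intervals", {
  zero <- rbind(
    ef_row("CL", "TROPICAL", "CO2", c(0, 0, 0), "t C/ha/yr"),
    ef_row("CL", "TROPICAL", "CH4", c(0, 0, 0), "kg CH4/ha/yr"),
    ef_row("CL", "TROPICAL", "N2O", c(0, 0, 0), "kg N2O-N/ha/yr"),
    ef_row("CL", "TROPICAL", "DOC", c(0, 0, 0), "t C/ha/yr")
  )
  z <- aggregate_ef(zero)
  expect_equal(unlist(z[c("co2eq_min", "co2eq_mean", "co2eq_max")],
                      use.names = FALSE), c(0, 0, 0))

  co2_only <- ef_row("GL", "TEMPERATE", "CO2", c(1, 2, 3), "t C/ha/yr")
  a <- aggregate_ef(co2_only)
  expect_equal(c(a$co2eq_min, a$co2eq_mean, a$co2eq_max),
               c(1, 2, 3) * 44 / 12, tolerance = 1e-12)

  gwp <- gwp_set(ch4 = 28, n2o = 265)
  ch4 <- ef_row("FL", "TROPICAL", "CH4", c(1, 1, 1), "t CH4/ha/yr")
  expect_equal(aggregate_ef(ch4, gwp)$co2eq_mean, 28)
  n2o_n <- ef_row("FL", "TROPICAL", "N2O", c(28, 28, 28), "kg N2O-N/ha/yr")
  expect_equal(aggregate_ef(n2o_n, gwp)$co2eq_mean,
               28e-3 * 44 / 28 * 265, tolerance = 1e-12)

  expect_error(aggregate_ef(ef_row("CL", "TROPICAL", "CO2",
                                   c(-1, 0, 1), "t C/ha/yr")), "negative")
})

test_that("interval ordering min <= mean <= max survives aggregation", {
  set.seed(99)
  for (rep in 1:25) {
    rows <- lapply(c("CO2", "CH4", "N2O", "DOC"), function(g) {
      v <- sort(runif(3, 0, 20))
      unit <- switch(g, CO2 = "t C/ha/yr", CH4 = "kg CH4/ha/yr",
                     N2O = "kg N2O-N/ha/yr", DOC = "t C/ha/yr")
      ef_row("CL", "TROPICAL", g, v, unit)
    })
    a <- aggregate_ef(do.call(rbind, rows))
    expect_lte(a$co2eq_min, a$co2eq_mean)
    expect_lte(a$co2eq_mean, a$co2eq_max)
  }
})

test_that("mixed-class EFs take the member mean and the range envelope", {
  m1 <- data.frame(landuse = "GL", climate = "TROPICAL",
                   co2eq_min = 1, co2eq_mean = 2, co2eq_max = 5)
  m2 <- data.frame(landuse = "FL", climate = "TROPICAL",
                   co2eq_min = 2, co2eq_mean = 4, co2eq_max = 4.5)
  mx <- mixed_class_ef(rbind(m1, m2))
  expect_equal(mx$co2eq_mean, 3)
  expect_equal(mx$co2eq_min, 1)
  expect_equal(mx$co2eq_max, 5)
  # idempotence on identical members
  same <- mixed_class_ef(rbind(m1, m1))
  expect_equal(same[c("co2eq_min", "co2eq_mean", "co2eq_max")],
               m1[c("co2eq_min", "co2eq_mean", "co2eq_max")])
  m3 <- m2; m3$climate <- "TEMPERATE"
  expect_error(mixed_class_ef(rbind(m1, m3)), "climate")

  # envelope contains every member's range
  set.seed(7)
  for (rep in 1:20) {
    mem <- do.call(rbind, lapply(1:3, function(i) {
      v <- sort(runif(3, 0, 30))
      data.frame(landuse = "X", climate = "TROPICAL", co2eq_min = v[1],
                 co2eq_mean = v[2], co2eq_max = v[3])
    }))
    mx <- mixed_class_ef(mem)
    expect_true(all(mx$co2eq_min <= mem$co2eq_min))
    expect_true(all(mx$co2eq_max >= mem$co2eq_max))
  }
})

test_that("potential emissions are rate x area, zero off-account", {
  lookup <- build_ef_lookup(default_ef_table())
  rate <- lookup$co2eq_mean[lookup$emission_class == "CL-tropical"]
  cells <- data.frame(
    emission_class = c("CL-tropical", NA, "CL-tropical"),
    cell_area_ha = c(1, 1, 1),
    peat = c(TRUE, TRUE, FALSE)
  )
  out <- potential_emissions(cells, lookup)
  expect_equal(out$potential_mean, c(rate, 0, 0))
  missing <- data.frame(emission_class = "CL-mars", cell_area_ha = 1,
                        peat = TRUE)
  expect_error(potential_emissions(missing, lookup), "CL-mars")
})

test_that("map totals equal the per-class area x rate tally", {
  w <- small_world(seed = 13)
  lookup <- build_ef_lookup(default_ef_table())
  g <- classify_grid(w$cells)
  g <- potential_emissions(g, lookup)
  acct <- g$peat & !is.na(g$emission_class)
  per_class_area <- tapply(g$cell_area_ha[acct], g$emission_class[acct], sum)
  oracle <- sum(per_class_area *
                  lookup$co2eq_mean[match(names(per_class_area),
                                          lookup$emission_class)])
  expect_equal(sum(g$potential_mean), oracle, tolerance = 1e-9)
})

test_that("actual emissions scale potential by degradation", {
  w <- small_world(seed = 17)
  acc <- account_world(w)
  g <- acc$cells
  expect_true(all(g$actual_mean <= g$potential_mean + 1e-12))
  expect_true(all(g$actual_min <= g$actual_mean + 1e-12))
  expect_true(all(g$actual_mean <= g$actual_max + 1e-12))

  g0 <- g
  g0$degradation <- 0
  expect_true(all(actual_emissions(g0)$actual_mean == 0))
  g1 <- g
  g1$degradation <- 1
  expect_equal(actual_emissions(g1)$actual_mean, g$potential_mean)
})

test_that("per-class actual rates are per area of peatland, not of the
           disturbed part", {
  # one class, half of its peat area degraded: the reported mean rate per
  # peatland area is half the emission factor
  lookup <- build_ef_lookup(default_ef_table())
  rate <- lookup$co2eq_mean[lookup$emission_class == "GL-temperate"]
  cells <- data.frame(
    climate = "temperate", landuse = "GL", peat = TRUE,
    emission_class = "GL-temperate", cell_area_ha = 1,
    degradation = c(1, 0)
  )
  cells <- potential_emissions(cells, lookup)
  cells <- actual_emissions(cells)
  per_area <- sum(cells$actual_mean) / sum(cells$cell_area_ha)
  expect_equal(per_area, 0.5 * rate, tolerance = 1e-12)
})

test_that("summaries reproduce brute-force sums and handle empty grids", {
  w <- small_world(seed = 19)
  acc <- account_world(w)
  g <- acc$cells
  s <- acc$summary
  tot <- s[s$climate == "total", ]
  acct <- g$peat & g$landuse != "NONE"
  expect_equal(tot$emission_mean_gt, sum(g$actual_mean[acct]) / 1e9,
               tolerance = 1e-12)
  expect_equal(tot$area_total_mha, sum(g$cell_area_ha[acct]) / 1e6,
               tolerance = 1e-12)
  expect_equal(tot$area_degrading_mha,
               sum((g$cell_area_ha * g$degradation)[acct]) / 1e6,
               tolerance = 1e-12)
  # totals row equals column sums of the climate rows
  body <- s[s$climate != "total", ]
  expect_equal(tot$emission_max_gt, sum(body$emission_max_gt))
  expect_true(all(s$emission_min_gt <= s$emission_mean_gt + 1e-12))
  expect_true(all(s$emission_mean_gt <= s$emission_max_gt + 1e-12))

  empty <- g[0, ]
  s0 <- summarize_emissions(empty)
  expect_equal(s0$emission_mean_gt, 0)
  expect_equal(s0$area_total_mha, 0)
})

test_that("CO2-eq to C-eq conversion is the 12/44 rescaling and linear", {
  expect_equal(co2eq_to_ceq(44), 12)
  expect_equal(co2eq_to_ceq(0), 0)
  x <- c(1.3, 2.7)
  expect_equal(co2eq_to_ceq(sum(x)), sum(co2eq_to_ceq(x)))
})
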