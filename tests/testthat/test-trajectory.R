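one_pool <- function(pool = 10, rate = 1) {
  data.frame(class = "x", pool_gt = pool, rate_min = rate,
             rate_mean = rate, rate_max = rate)
}

test_that("a pool depletes linearly and caps at its stock", {
  tr <- peat_trajectory(one_pool(10, 1), horizon = 20, dt = 0.5)
  expect_equal(tr$mean[tr$time == 5], 5)
  expect_equal(tr$mean[tr$time == 10], 10)
  expect_equal(tr$mean[tr$time == 20], 10)
  expect_error(peat_trajectory(one_pool(-1, 1), 10, 1), "non-negative")
})

test_that("the tropical mean pool exhausts near the rate quotient", {
  pools <- emission_pools()
  trop <- pools[pools$class == "tropical", ]
  t_exhaust <- trop$pool_gt / trop$rate_mean
  expect_equal(t_exhaust, 49.1 / (1.48 * 12 / 44), tolerance = 1e-12)
  expect_equal(t_exhaust, 121.7, tolerance = 1e-3)
  tr <- peat_trajectory(trop, horizon = 200, dt = 0.1)
  before <- tr$mean[tr$time == 121]
  after <- tr$mean[tr$time == 125]
  expect_lt(before, trop$pool_gt)
  expect_equal(after, trop$pool_gt)
})

test_that("cumulative emission never exceeds the summed pools and ends
           at the degrading stock total", {
  pools <- emission_pools()
  tr <- peat_trajectory(pools, horizon = 2000, dt = 1)
  total <- sum(pools$pool_gt)
  expect_true(all(tr$mean <= total + 1e-9))
  expect_true(all(tr$max <= total + 1e-9))
  # per-class printed stocks sum to 80.7 (printed total 80.8 rounds up)
  expect_equal(total, 80.7)
  expect_equal(tr$mean[nrow(tr)], total)
  expect_true(all(diff(tr$mean) >= -1e-12))
})

test_that("the mineral sink starts at zero, saturates at t_seq, never
           decreases", {
  sk <- mineral_sink(horizon = 200, dt = 0.5)
  expect_equal(sk$mean[1], 0)
  at63 <- sk$mean[sk$time == 63]
  expect_equal(at63, 44, tolerance = 0.01 * 44)
  expect_equal(sk$mean[sk$time >= 63], rep(44, sum(sk$time >= 63)),
               tolerance = 1e-9)
  for (layer in c("min", "mean", "max")) {
    expect_true(all(diff(sk[[layer]]) >= -1e-12))
  }
  # pluggable shape: a linear ramp
  lin <- mineral_sink(c(mean = 44), horizon = 100, dt = 1,
                      shape = function(u) u)
  expect_equal(lin$mean[lin$time == 63], 44)
  expect_equal(lin$mean[lin$time == 21], 44 / 3, tolerance = 1e-9)
})

test_that("equivalence point interpolates the first catch-up crossing", {
  # brute-force timeline oracle: unlimited pool at 0.5 Gt/a against a
  # linear ramp to 44 Gt at 63 y crosses where 0.5 t = 44, i.e. 88 y
  times <- seq(0, 200, by = 0.25)
  peat <- 0.5 * times
  sink <- pmin(times / 63, 1) * 44
  oracle <- NA
  for (i in seq_along(times)[-1]) {
    if (peat[i] >= sink[i] && peat[i - 1] < sink[i - 1]) {
      oracle <- times[i]
      break
    }
  }
  eq <- equivalence_point(peat, sink, times)
  expect_equal(eq, 88, tolerance = 1e-9)
  expect_lte(abs(eq - oracle), 0.25)
  # identical series and a zero sink cross immediately
  expect_equal(equivalence_point(peat, peat, times), 0)
  expect_equal(equivalence_point(peat, numeric(length(peat)), times), 0)
  # never catching up within the horizon
  expect_equal(equivalence_point(peat / 1000, sink, times), Inf)
  expect_error(equivalence_point(peat, sink[-1], times), "length")
})

test_that("Michaelis-Menten multiplier: 1 at zero, half the gain at K,
           asymptote m", {
  expect_equal(mm_multiplier(0), 1)
  expect_equal(mm_multiplier(60, m = 2, K = 60), 1.5)
  expect_equal(mm_multiplier(1e9), 2, tolerance = 1e-6)
  expect_error(mm_multiplier(-1), "non-negative")
})

test_that("expansion scenario dominates the baseline and respects the
           multiplier cap", {
  pools <- emission_pools()
  base <- peat_trajectory(pools, horizon = 600, dt = 0.5)
  sc <- scenario_trajectory(pools, horizon = 600, dt = 0.5)
  expect_true(all(sc$mean >= base$mean - 1e-9))
  expect_true(all(sc$max >= base$max - 1e-9))
  mult <- mm_multiplier(sc$time)
  expect_true(all(sc$mean <= mult * sum(pools$pool_gt) + 1e-9))
  # degenerate scenario (m = 1) is the baseline
  sc1 <- scenario_trajectory(pools, horizon = 300, dt = 0.5, m = 1)
  b1 <- peat_trajectory(pools, horizon = 300, dt = 0.5)
  expect_equal(sc1$mean, b1$mean, tolerance = 1e-12)
  expect_warning(scenario_trajectory(pools, horizon = 100, dt = 10, K = 60),
                 "coarse")
})

test_that("scenario asymptote doubles stocks under a doubling multiplier", {
  expect_equal(scenario_asymptote(80.8), 161.6)
  expect_equal(scenario_asymptote(2.3), 4.6)
  expect_equal(scenario_asymptote(10, m = 1), 10)
})

test_that("equivalence years move the right way with rates and sink size", {
  set.seed(31)
  pools <- emission_pools()
  sink <- mineral_sink(c(mean = 44), horizon = 1200, dt = 0.5)
  base_eq <- equivalence_point(
    peat_trajectory(pools, 1200, 0.5)$mean, sink$mean, sink$time)
  for (rep in 1:10) {
    up <- pools
    scale <- 1 + runif(1, 0.05, 0.8)
    up[c("rate_min", "rate_mean", "rate_max")] <-
      up[c("rate_min", "rate_mean", "rate_max")] * scale
    eq_up <- equivalence_point(
      peat_trajectory(up, 1200, 0.5)$mean, sink$mean, sink$time)
    expect_lte(eq_up, base_eq + 1e-9)
  }
  for (s_max in c(20, 44, 64, 75)) {
    sk <- mineral_sink(c(mean = s_max), horizon = 1200, dt = 0.5)
    eq_s <- equivalence_point(
      peat_trajectory(pools, 1200, 0.5)$mean, sk$mean, sk$time)
    if (s_max > 44) expect_gte(eq_s, base_eq - 1e-9)
    if (s_max < 44) expect_lte(eq_s, base_eq + 1e-9)
  }
})

test_that("halving the time step moves crossings by less than one percent", {
  pools <- emission_pools()
  eq_of_dt <- function(dt) {
    ea <- equivalence_analysis(pools, horizon = 1200, dt = dt,
                               scenario = TRUE)
    ea$equivalence$year
  }
  y1 <- eq_of_dt(0.5)
  y2 <- eq_of_dt(0.25)
  # finiteness must agree between step sizes (the slowest-emission
  # envelope crossing can legitimately lie beyond the horizon)
  expect_equal(is.finite(y1), is.finite(y2))
  finite <- is.finite(y1)
  expect_gte(sum(finite), 4)
  expect_true(all(abs(y2[finite] - y1[finite]) / pmax(y1[finite], 1) < 0.01))
})
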